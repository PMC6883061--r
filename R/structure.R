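#' Construct a structure model
#'
#' A `structure_model` is the package's container for one molecular object: an
#' ordered atom table plus peptide/protofilament topology tags and, for
#' nanoparticles, a ligand map. It deliberately carries everything the
#' downstream analyses need per atom: coordinates, partial charge, LJ
#' parameters and a van der Waals radius.
#'
#' @param atoms A data.frame with one row per atom and columns `atom_id`
#'   (integer), `name`, `element`, `resname`, `resseq` (1-based integer),
#'   `chain`, `segid`, `x`, `y`, `z` (Angstrom), `charge` (e, may be NA),
#'   `epsilon` (kcal/mol, may be NA), `rmin_half` (Angstrom, may be NA),
#'   `radius` (Angstrom, may be NA). A logical `heavy` column is derived from
#'   `element`.
#' @param peptides Optional data.frame describing monomers: columns `chain`,
#'   `segid`, `first_res`, `last_res`, `protofilament` (integer or NA),
#'   `ordinal` (1-based position along the fibril axis within its
#'   protofilament).
#' @param role One of `"fibril"`, `"nanoparticle"`, `"free_peptide"`,
#'   `"complex"`.
#' @param ligand_map For nanoparticles, a named list; each element is
#'   `list(type = <ligand type>, atoms = <integer atom indices>)`.
#'
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, peptides = NULL,
                            role = c("fibril", "nanoparticle", "free_peptide", "complex"),
                            ligand_map = NULL) {
  role <- match.arg(role)
  required <- c("atom_id", "name", "element", "resname", "resseq", "chain",
                "segid", "x", "y", "z", "charge", "epsilon", "rmin_half", "radius")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atoms table is missing columns: ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms)) {
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
      stop("non-finite atom coordinates")
    bad_r <- which(!is.na(atoms$radius) & atoms$radius <= 0)
    if (length(bad_r))
      stop("non-positive vdW radius for atoms: ", paste(head(atoms$atom_id[bad_r]), collapse = ", "))
    au <- toupper(atoms$element) == "AU"
    if (any(au & !is.na(atoms$charge) & atoms$charge != 0))
      stop("gold atoms must carry exactly zero partial charge")
  }
  atoms$heavy <- toupper(atoms$element) != "H"
  rownames(atoms) <- NULL
  if (!is.null(ligand_map) && length(ligand_map)) {
    all_idx <- unlist(lapply(ligand_map, `[[`, "atoms"), use.names = FALSE)
    if (anyDuplicated(all_idx))
      stop("an atom belongs to more than one ligand")
    if (length(all_idx) && (min(all_idx) < 1 || max(all_idx) > nrow(atoms)))
      stop("ligand_map refers to atom indices outside the atom table")
  }
  m <- list(atoms = atoms, peptides = peptides, role = role, ligand_map = ligand_map)
  class(m) <- "structure_model"
  m
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> role=%s, %d atoms", x$role, nrow(x$atoms)))
  if (!is.null(x$peptides) && nrow(x$peptides)) {
    npf <- length(unique(stats::na.omit(x$peptides$protofilament)))
    cat(sprintf(", %d peptides", nrow(x$peptides)))
    if (npf) cat(sprintf(" in %d protofilament(s)", npf))
  }
  if (!is.null(x$ligand_map)) cat(sprintf(", %d ligands", length(x$ligand_map)))
  cat("\n")
  q <- x$atoms$charge
  if (any(!is.na(q))) cat(sprintf("  net charge: %+g e\n", sum(q, na.rm = TRUE)))
  invisible(x)
}

#' Number of atoms in a model
#' @param model A `structure_model`.
#' @return Integer atom count.
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Atom coordinates as an n x 3 matrix
#' @param model A `structure_model`.
#' @return Numeric matrix with columns x, y, z (Angstrom).
#' @export
model_coords <- function(model) {
  cbind(x = model$atoms$x, y = model$atoms$y, z = model$atoms$z)
}

set_model_coords <- function(model, xyz) {
  stopifnot(nrow(xyz) == n_atoms(model), ncol(xyz) == 3L)
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

#' Select atoms by structural fields
#'
#' Deterministic, order-preserving atom selection. All supplied criteria are
#' intersected; each criterion matches against one atom field. Selections are
#' plain integer index vectors, so unions, intersections and complements are
#' the base-R set operations.
#'
#' @param model A `structure_model`.
#' @param chain,segid,element,resname Character vectors of accepted values.
#' @param resseq Integer vector (or range) of accepted residue numbers.
#' @param heavy Logical: `TRUE` restricts to non-hydrogen atoms.
#' @param ligand_type Ligand type label(s); matches atoms owned by ligands of
#'   those types (nanoparticle models only).
#' @param protofilament,peptide Integer protofilament index / peptide ordinals
#'   within that protofilament (fibril models only).
#' @param name Atom name(s), e.g. `"CA"`.
#'
#' @return Sorted integer vector of atom indices (1-based, in atom order).
#' @examples
#' fib <- build_fibril(fibril_spec(n_peptides = 3))
#' beta <- select_atoms(fib, resseq = 12:40)
#' ca18 <- select_atoms(fib, name = "CA", resseq = 18)
#' @export
select_atoms <- function(model, chain = NULL, segid = NULL, resseq = NULL,
                         element = NULL, resname = NULL, heavy = NULL,
                         ligand_type = NULL, protofilament = NULL,
                         peptide = NULL, name = NULL) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain))   keep <- keep & a$chain %in% chain
  if (!is.null(segid))   keep <- keep & a$segid %in% segid
  if (!is.null(resseq))  keep <- keep & a$resseq %in% resseq
  if (!is.null(element)) keep <- keep & toupper(a$element) %in% toupper(element)
  if (!is.null(resname)) keep <- keep & toupper(a$resname) %in% toupper(resname)
  if (!is.null(name))    keep <- keep & a$name %in% name
  if (!is.null(heavy)) {
    stopifnot(is.logical(heavy), length(heavy) == 1L)
    keep <- keep & (a$heavy == heavy)
  }
  if (!is.null(ligand_type)) {
    if (is.null(model$ligand_map))
      stop("model has no ligand_map; 'ligand_type' selection is undefined")
    idx <- unlist(lapply(model$ligand_map,
                         function(l) if (l$type %in% ligand_type) l$atoms else integer(0)),
                  use.names = FALSE)
    lig_keep <- rep(FALSE, nrow(a)); lig_keep[idx] <- TRUE
    keep <- keep & lig_keep
  }
  if (!is.null(protofilament) || !is.null(peptide)) {
    if (is.null(model$peptides))
      stop("model has no peptide table; protofilament/peptide selection is undefined")
    p <- model$peptides
    pk <- rep(TRUE, nrow(p))
    if (!is.null(protofilament)) pk <- pk & p$protofilament %in% protofilament
    if (!is.null(peptide))       pk <- pk & p$ordinal %in% peptide
    p <- p[pk, , drop = FALSE]
    pep_keep <- rep(FALSE, nrow(a))
    for (i in seq_len(nrow(p))) {
      pep_keep <- pep_keep |
        (a$chain == p$chain[i] & a$segid == p$segid[i] &
           a$resseq >= p$first_res[i] & a$resseq <= p$last_res[i])
    }
    keep <- keep & pep_keep
  }
  which(keep)
}

#' Rigid-body translation of a structure model
#' @param model A `structure_model`.
#' @param shift Numeric length-3 translation vector (Angstrom).
#' @return The translated model.
#' @export
translate_model <- function(model, shift) {
  stopifnot(length(shift) == 3L, all(is.finite(shift)))
  xyz <- model_coords(model)
  set_model_coords(model, sweep(xyz, 2, shift, "+"))
}

#' Rigid-body rotation of a structure model about the z axis
#' @param model A `structure_model`.
#' @param angle_deg Rotation angle in degrees (counter-clockwise about +z).
#' @param center Length-3 rotation center (default origin).
#' @return The rotated model.
#' @export
rotate_model_z <- function(model, angle_deg, center = c(0, 0, 0)) {
  R <- rot_z(angle_deg)
  xyz <- sweep(model_coords(model), 2, center)
  set_model_coords(model, sweep(xyz %*% t(R), 2, center, "+"))
}

rot_z <- function(angle_deg) {
  t <- angle_deg * pi / 180
  matrix(c(cos(t), -sin(t), 0,
           sin(t),  cos(t), 0,
           0,       0,      1), 3, 3, byrow = TRUE)
}

#' Concatenate two structure models
#'
#' Atom ids are renumbered sequentially; the second model's ligand map indices
#' are offset accordingly. Used to assemble nanoparticle + fibril complexes
#' that share one trajectory topology.
#'
#' @param a,b `structure_model` objects.
#' @return A combined `structure_model` with `role = "complex"` and an
#'   attribute-free `components` element holding the index ranges of `a` and
#'   `b`.
#' @export
combine_models <- function(a, b) {
  na <- n_atoms(a)
  atoms <- rbind(a$atoms, b$atoms)
  atoms$atom_id <- seq_len(nrow(atoms))
  peptides <- rbind(a$peptides, b$peptides)
  lmap <- c(a$ligand_map,
            lapply(b$ligand_map, function(l) { l$atoms <- l$atoms + na; l }))
  if (!length(lmap)) lmap <- NULL
  m <- structure_model(atoms, peptides = peptides, role = "complex",
                       ligand_map = lmap)
  m$components <- list(seq_len(na), na + seq_len(n_atoms(b)))
  names(m$components) <- make.unique(c(a$role, b$role))
  m
}
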