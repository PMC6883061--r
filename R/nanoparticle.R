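LIGAND_TYPES <- c("Pos-lig", "Neg-lig", "Neu-lig", "Pep-lig")

#' Nanoparticle generator specification
#'
#' Describes a ligated gold-core nanoparticle: an icosahedral Au shell of a
#' nominal diameter whose atoms carry exactly zero partial charge and are
#' bonded at a fixed rigid-bond length, plus a shell of ligands attached at
#' deterministically placed surface sites.
#'
#' @param core_diameter Nominal Au-core diameter in Angstrom (default 22).
#'   The realised vertex diameter is the closest the discrete bond lattice
#'   allows (20.85 A for the defaults), because exact Au-Au bond lengths take
#'   priority over the nominal diameter.
#' @param n_ligands Total number of ligands (default 90).
#' @param composition Named integer vector over `"Pos-lig"`, `"Neg-lig"`,
#'   `"Neu-lig"`, `"Pep-lig"`; must sum to `n_ligands`.
#' @param placement `"homogeneous"` (deterministic spherical Fibonacci
#'   lattice, minority types interleaved proportionally) or `"janus"`
#'   (exactly two types split by the attachment-site z hemisphere).
#' @param au_bond_length Rigid Au-Au bond length in Angstrom (default 2.74).
#' @param rng_seed Integer seed (the builder is deterministic; kept for API
#'   symmetry with the other generators).
#' @return An object of class `np_spec`.
#' @export
np_spec <- function(core_diameter = 22, n_ligands = 90,
                    composition = c("Pos-lig" = 90),
                    placement = c("homogeneous", "janus"),
                    au_bond_length = 2.74, rng_seed = 1L) {
  placement <- match.arg(placement)
  stopifnot(core_diameter > 0, n_ligands >= 1, au_bond_length > 0)
  bad <- setdiff(names(composition), LIGAND_TYPES)
  if (length(bad)) stop("unknown ligand type(s): ", paste(bad, collapse = ", "))
  if (any(composition < 0) || sum(composition) != n_ligands)
    stop("ligand composition must be non-negative and sum to n_ligands (",
         n_ligands, "), got ", sum(composition))
  composition <- composition[composition > 0]
  if (placement == "janus" && length(composition) != 2L)
    stop("janus placement requires exactly two ligand types, got ",
         length(composition))
  s <- list(core_diameter = core_diameter, n_ligands = as.integer(n_ligands),
            composition = composition, placement = placement,
            au_bond_length = au_bond_length, rng_seed = as.integer(rng_seed))
  class(s) <- "np_spec"
  s
}

#' Standard nanoparticle recipes
#'
#' The five shell compositions studied: `Pos` (90 PEG-ammonium), `PosNQ`
#' (80 PEG-ammonium + 10 PEG-NQTrp), `Pep` (90 charge-inverted peptide
#' ligands), `Janus` (45 positive / 45 negative on opposite hemispheres) and
#' `NegNQ` (80 PEG-sulfonate + 10 PEG-NQTrp).
#'
#' @param name One of `"Pos"`, `"PosNQ"`, `"Pep"`, `"Janus"`, `"NegNQ"`.
#' @param ... Further arguments passed to [np_spec()] (e.g. `core_diameter`).
#' @return An `np_spec`.
#' @examples
#' np_recipe("PosNQ")
#' @export
np_recipe <- function(name = c("Pos", "PosNQ", "Pep", "Janus", "NegNQ"), ...) {
  name <- match.arg(name)
  comp <- switch(name,
    Pos   = c("Pos-lig" = 90),
    PosNQ = c("Pos-lig" = 80, "Neu-lig" = 10),
    Pep   = c("Pep-lig" = 90),
    Janus = c("Pos-lig" = 45, "Neg-lig" = 45),
    NegNQ = c("Neg-lig" = 80, "Neu-lig" = 10))
  np_spec(composition = comp, n_ligands = sum(comp),
          placement = if (name == "Janus") "janus" else "homogeneous", ...)
}

icosahedron_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v / sqrt(1 + phi^2)  # unit circumradius
}

icosahedron_faces <- function(v) {
  edge <- 2 / sqrt(1 + (1 + sqrt(5))^2 / 4)  # unit-circumradius edge length
  d <- as.matrix(stats::dist(v))
  faces <- t(utils::combn(12, 3))
  ok <- apply(faces, 1, function(f)
    all(abs(d[f[c(1, 1, 2)], f[c(2, 3, 3)]][c(1, 5, 9)] - edge) < 1e-6))
  faces[ok, , drop = FALSE]
}

# Icosahedral Au shell with every bonded pair at exactly the requested bond
# length: each face is subdivided in its own plane (not projected back to the
# sphere), so all lattice edges are equal by construction.
icosahedral_shell <- function(core_diameter, bond_length) {
  unit_edge <- 1 / 0.95105651629515353  # edge / circumradius of an icosahedron
  nu <- max(1L, as.integer(round((core_diameter / 2) / (0.95105651629515353 * bond_length))))
  scale <- nu * bond_length / unit_edge  # circumradius giving edge nu * b0
  v <- icosahedron_vertices() * scale
  faces <- icosahedron_faces(icosahedron_vertices())
  pts <- vector("list", nrow(faces))
  for (f in seq_len(nrow(faces))) {
    tri <- v[faces[f, ], ]
    ij <- expand.grid(i = 0:nu, j = 0:nu)
    ij <- ij[ij$i + ij$j <= nu, ]
    pts[[f]] <- (outer(ij$i, tri[1, ]) + outer(ij$j, tri[2, ]) +
                   outer(nu - ij$i - ij$j, tri[3, ])) / nu
  }
  p <- do.call(rbind, pts)
  key <- apply(round(p, 6), 1, paste, collapse = ",")
  p <- p[!duplicated(key), , drop = FALSE]
  pr <- neighbor_pairs(p, p, bond_length * 1.1)
  keep <- pr$i < pr$j & pr$d > bond_length * 0.9
  list(coords = p,
       bonds = cbind(pr$i[keep], pr$j[keep]),
       bond_lengths = pr$d[keep],
       nu = nu)
}

fibonacci_directions <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  th <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(th), r * sin(th), z)
}

# Proportional deterministic interleave of ligand types along the Fibonacci
# spiral, so minority species are spread over the whole shell.
interleave_types <- function(composition) {
  pos <- unlist(lapply(seq_along(composition), function(k)
    (seq_len(composition[k]) - 0.5) / composition[k]), use.names = FALSE)
  types <- rep(names(composition), composition)
  types[order(pos, rep(seq_along(composition), composition))]
}

ligand_bead <- function(name, element, offset, charge, radius, epsilon, rmin_half) {
  list(name = name, element = element, offset = offset, charge = charge,
       radius = radius, epsilon = epsilon, rmin_half = rmin_half)
}

# Schematic collinear bead templates (offsets in A along the outward radial
# direction u; the NQTrp ring and peptide side beads use the perpendicular w).
ligand_template <- function(type, u, w) {
  chain_c <- function(name, off) ligand_bead(name, "C", off * u, 0, 2.2, 0.15, 2.2)
  beads <- switch(type,
    "Pos-lig" = list(ligand_bead("S1", "S", 0 * u, 0, 2.0, 0.25, 2.0),
                     chain_c("C1", 3), chain_c("C2", 6),
                     ligand_bead("N1", "N", 9 * u, +1, 1.8, 0.17, 1.85)),
    "Neg-lig" = list(ligand_bead("S1", "S", 0 * u, 0, 2.0, 0.25, 2.0),
                     chain_c("C1", 3), chain_c("C2", 6),
                     ligand_bead("SO3", "S", 9 * u, -1, 2.1, 0.25, 2.1)),
    "Neu-lig" = c(list(ligand_bead("S1", "S", 0 * u, 0, 2.0, 0.25, 2.0),
                       chain_c("C1", 3), chain_c("C2", 6)),
                  lapply(0:5, function(k) {
                    a <- k * pi / 3
                    ligand_bead(paste0("R", k + 1), "C",
                                9.4 * u + 1.4 * (cos(a) * u + sin(a) * w),
                                0, 1.9, 0.12, 1.9)
                  })),
    "Pep-lig" = {
      res <- c("CYS", invert_charge_sequence(
        c("LYS", "LEU", "VAL", "PHE", "PHE", "ALA", "GLU", "ASP")))
      q <- residue_charge(res)
      unlist(lapply(seq_along(res), function(k) {
        ca <- (3 * (k - 1)) * u
        list(ligand_bead(paste0("CA", k), if (k == 1) "S" else "C",
                         ca, 0, 2.0, 0.15, 2.0),
             ligand_bead(paste0("CB", k), "C", ca + 1.8 * w,
                         q[k], 2.2, 0.18, 2.2))
      }), recursive = FALSE)
    },
    stop("unknown ligand type: ", type))
  beads
}

#' Build a ligated gold-core nanoparticle
#'
#' Gold atoms sit on an icosahedral shell whose bonded neighbours are at
#' exactly the rigid bond length and carry exactly zero partial charge.
#' Attachment directions come from a deterministic spherical Fibonacci
#' lattice; each ligand is instantiated from its schematic bead template and
#' extended radially from its site. Janus placement splits the two ligand
#' types by the attachment-site z hemisphere.
#'
#' @param spec An [np_spec()] or a recipe name accepted by [np_recipe()].
#' @return A `structure_model` with `role = "nanoparticle"`, a `ligand_map`
#'   of `n_ligands` entries, and an `au_bonds` element (two-column index
#'   matrix into the atom table).
#' @examples
#' np <- build_nanoparticle(np_recipe("PosNQ"))
#' length(np$ligand_map)           # 90
#' sum(np$atoms$charge)            # +80
#' @export
build_nanoparticle <- function(spec) {
  if (is.character(spec)) spec <- np_recipe(spec)
  stopifnot(inherits(spec, "np_spec"))
  shell <- icosahedral_shell(spec$core_diameter, spec$au_bond_length)
  nau <- nrow(shell$coords)
  au <- data.frame(
    atom_id = 0L, name = "AU", element = "AU", resname = "AUC",
    resseq = 1L, chain = "X", segid = "NP",
    x = shell$coords[, 1], y = shell$coords[, 2], z = shell$coords[, 3],
    charge = 0, epsilon = 0.1, rmin_half = 1.66, radius = 1.66,
    stringsAsFactors = FALSE)
  dirs <- fibonacci_directions(spec$n_ligands)
  types <- if (spec$placement == "janus") {
    ord <- order(dirs[, 3], decreasing = TRUE)
    tt <- character(spec$n_ligands)
    tt[ord[seq_len(spec$composition[1])]] <- names(spec$composition)[1]
    tt[ord[-seq_len(spec$composition[1])]] <- names(spec$composition)[2]
    tt
  } else interleave_types(spec$composition)
  shell_r <- sqrt(max(rowSums(shell$coords^2)))
  rows <- vector("list", spec$n_ligands)
  lmap <- vector("list", spec$n_ligands)
  idx0 <- nau
  for (k in seq_len(spec$n_ligands)) {
    u <- dirs[k, ]
    w <- if (abs(u[3]) < 0.9) c(-u[2], u[1], 0) else c(1, 0, 0)
    w <- w - sum(w * u) * u; w <- w / sqrt(sum(w^2))
    anchor <- (shell_r + 2.4) * u
    beads <- ligand_template(types[k], u, w)
    rows[[k]] <- data.frame(
      atom_id = 0L,
      name = vapply(beads, `[[`, "", "name"),
      element = vapply(beads, `[[`, "", "element"),
      resname = unname(c("Pos-lig" = "POS", "Neg-lig" = "NEG",
                         "Neu-lig" = "NQT", "Pep-lig" = "PEP")[types[k]]),
      resseq = k + 1L, chain = "X", segid = "NP",
      x = anchor[1] + vapply(beads, function(b) b$offset[1], 0),
      y = anchor[2] + vapply(beads, function(b) b$offset[2], 0),
      z = anchor[3] + vapply(beads, function(b) b$offset[3], 0),
      charge = vapply(beads, `[[`, 0, "charge"),
      epsilon = vapply(beads, `[[`, 0, "epsilon"),
      rmin_half = vapply(beads, `[[`, 0, "rmin_half"),
      radius = vapply(beads, `[[`, 0, "radius"),
      stringsAsFactors = FALSE)
    lmap[[k]] <- list(type = types[k],
                      atoms = idx0 + seq_len(length(beads)))
    idx0 <- idx0 + length(beads)
  }
  atoms <- rbind(au, do.call(rbind, rows))
  atoms$atom_id <- seq_len(nrow(atoms))
  names(lmap) <- sprintf("L%03d", seq_len(spec$n_ligands))
  m <- structure_model(atoms, role = "nanoparticle", ligand_map = lmap)
  m$au_bonds <- shell$bonds
  m
}
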