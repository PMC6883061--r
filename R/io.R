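#' Read a structure from PDB or PQR
#'
#' Parsing is delegated to bio3d; the result is repackaged as a
#' [structure_model()]. PQR files supply per-atom partial charges and van der
#' Waals radii; plain PDB files leave both `NA` (analyses that need them raise
#' an explicit "parameters missing" error rather than assuming zeros).
#' Peptide/protofilament topology is reconstructed from `(segid, chain)`
#' groups: segids `FIB1`/`FIB2` mark the two protofilaments. Ligand maps are
#' not persisted by either format.
#'
#' @param path File path.
#' @param format `"pdb"` or `"pqr"`; default guessed from the file extension.
#' @param role Role tag for the model; `"auto"` infers `fibril` when FIB
#'   segids are present, `nanoparticle` when an NP segid is, else
#'   `free_peptide`.
#' @return A `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "pqr"), role = "auto") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pqr$", path, ignore.case = TRUE)) "pqr" else "pdb"
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    if (format == "pqr") bio3d::read.pqr(path) else bio3d::read.pdb(path),
    error = function(e) stop("failed to parse ", format, " file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || !nrow(a))
    stop("failed to parse ", format, " file ", path, ": no ATOM records found")
  element <- a$elesy
  if (is.null(element)) element <- rep(NA_character_, nrow(a))
  miss <- is.na(element) | element == ""
  element[miss] <- guess_element(a$elety[miss])
  chain <- ifelse(is.na(a$chain), " ", a$chain)
  segid <- if (!is.null(a$segid)) ifelse(is.na(a$segid), "", a$segid) else ""
  atoms <- data.frame(
    atom_id = a$eleno, name = a$elety, element = element,
    resname = a$resid, resseq = a$resno, chain = chain, segid = segid,
    x = a$x, y = a$y, z = a$z,
    charge = if (format == "pqr") a$o else NA_real_,
    epsilon = NA_real_, rmin_half = NA_real_,
    radius = if (format == "pqr") a$b else NA_real_,
    stringsAsFactors = FALSE)
  peptides <- infer_peptides(atoms)
  if (role == "auto") {
    role <- if (any(grepl("^FIB", atoms$segid))) "fibril"
            else if (any(atoms$segid == "NP")) "nanoparticle"
            else "free_peptide"
  }
  structure_model(atoms, peptides = peptides, role = role)
}

guess_element <- function(name) {
  e <- sub("^[0-9 ]*([A-Za-z]).*$", "\\1", name)
  two <- toupper(substr(gsub("[^A-Za-z]", "", name), 1, 2))
  e <- ifelse(two %in% c("AU", "CL", "NA", "MG", "ZN", "FE"), two, toupper(e))
  e
}

infer_peptides <- function(atoms) {
  if (!nrow(atoms)) return(NULL)
  key <- paste(atoms$segid, atoms$chain, sep = "\r")
  grp <- split(seq_len(nrow(atoms)), factor(key, levels = unique(key)))
  pf_of <- function(seg) if (grepl("^FIB[0-9]+$", seg)) as.integer(sub("FIB", "", seg)) else NA_integer_
  rows <- lapply(grp, function(idx) {
    data.frame(chain = atoms$chain[idx[1]], segid = atoms$segid[idx[1]],
               first_res = min(atoms$resseq[idx]), last_res = max(atoms$resseq[idx]),
               protofilament = pf_of(atoms$segid[idx[1]]),
               ordinal = NA_integer_, stringsAsFactors = FALSE)
  })
  p <- do.call(rbind, rows)
  rownames(p) <- NULL
  for (pf in unique(p$protofilament)) {
    sel <- if (is.na(pf)) is.na(p$protofilament) else !is.na(p$protofilament) & p$protofilament == pf
    p$ordinal[sel] <- seq_len(sum(sel))
  }
  p
}

#' Write a structure to PDB or PQR
#'
#' Emits standard fixed-width PDB (coordinates to 3 decimals, `TER` after each
#' chain, segid in columns 73-76, element in 77-78) or a PQR-style record with
#' per-atom charge and radius in place of occupancy/B-factor. Strict PDB
#' serials overflow above 99,999 atoms; such models must be split or written
#' as PQR (hybrid-36 numbering is not implemented).
#'
#' @param model A `structure_model`.
#' @param path Output file path.
#' @param format `"pdb"` or `"pqr"` (default from extension).
#' @return Invisibly, `path`.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "pqr")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pqr$", path, ignore.case = TRUE)) "pqr" else "pdb"
  a <- model$atoms
  if (nrow(a) > 99999L && format == "pdb")
    stop("model has >99,999 atoms; strict PDB serials overflow ",
         "(hybrid-36 numbering is not implemented - write PQR instead)")
  con <- file(path, "w"); on.exit(close(con))
  if (!nrow(a)) { writeLines("END", con); return(invisible(path)) }
  name4 <- ifelse(nchar(a$name) < 4L, sprintf(" %-3s", a$name), sprintf("%-4s", a$name))
  chain1 <- substr(ifelse(is.na(a$chain) | a$chain == "", " ", a$chain), 1, 1)
  if (format == "pdb") {
    lines <- sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s%2s",
                     seq_len(nrow(a)), name4, substr(a$resname, 1, 3), chain1,
                     a$resseq, a$x, a$y, a$z,
                     1, ifelse(is.na(a$radius), 0, a$radius),
                     substr(a$segid, 1, 4), toupper(substr(a$element, 1, 2)))
  } else {
    q <- ifelse(is.na(a$charge), 0, a$charge)
    r <- ifelse(is.na(a$radius), 0, a$radius)
    lines <- sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f %7.4f %7.4f      %-4s%2s",
                     seq_len(nrow(a)), name4, substr(a$resname, 1, 3), chain1,
                     a$resseq, a$x, a$y, a$z, q, r,
                     substr(a$segid, 1, 4), toupper(substr(a$element, 1, 2)))
  }
  # TER record after the last atom of every (segid, chain) block
  key <- paste(a$segid, a$chain, sep = "\r")
  last_of_chain <- cumsum(rle(key)$lengths)
  out <- character(nrow(a) + length(last_of_chain))
  pos <- seq_len(nrow(a)) + findInterval(seq_len(nrow(a)) - 1L, last_of_chain)
  out[pos] <- lines
  out[setdiff(seq_along(out), pos)] <- "TER"
  writeLines(c(out, "END"), con)
  invisible(path)
}

#' Read a Lennard-Jones parameter table
#'
#' The table is TSV with columns `residue`, `atom`, `epsilon` (kcal/mol) and
#' `rmin_half` (Angstrom). Lookup is by `(residue, atom name)`; rows with
#' `residue == "*"` act as element-level fallbacks whose `atom` field is an
#' element symbol.
#'
#' @param path TSV file path.
#' @return A data.frame with the four columns above.
#' @export
read_lj_params <- function(path) {
  tbl <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("residue", "atom", "epsilon", "rmin_half")
  if (!all(need %in% names(tbl)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  if (any(tbl$epsilon < 0)) stop("epsilon must be >= 0")
  if (any(tbl$epsilon > 0 & tbl$rmin_half <= 0)) stop("rmin_half must be > 0")
  tbl
}

#' Attach Lennard-Jones parameters to a model
#'
#' @param model A `structure_model`.
#' @param table A parameter table from [read_lj_params()].
#' @param radius_from_rmin If `TRUE`, fill missing vdW radii with `rmin_half`.
#' @return The model with `epsilon`/`rmin_half` columns filled; atoms with no
#'   matching row keep `NA` (energy calls will then error explicitly).
#' @export
apply_lj_params <- function(model, table, radius_from_rmin = FALSE) {
  a <- model$atoms
  key <- paste(toupper(a$resname), a$name)
  tkey <- paste(toupper(table$residue), table$atom)
  hit <- match(key, tkey)
  fb <- match(paste("*", toupper(a$element)), tkey)
  use <- ifelse(is.na(hit), fb, hit)
  ok <- !is.na(use)
  a$epsilon[ok] <- table$epsilon[use[ok]]
  a$rmin_half[ok] <- table$rmin_half[use[ok]]
  if (radius_from_rmin)
    a$radius <- ifelse(is.na(a$radius), a$rmin_half, a$radius)
  model$atoms <- a
  model
}
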