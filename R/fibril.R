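# Residue-level charge table (elementary charges) for the coarse model:
# Asp/Glu -1, Lys/Arg +1, His 0 (neutral tautomer), all others 0.
AA_CHARGE <- c(ASP = -1, GLU = -1, LYS = 1, ARG = 1)

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

CHAIN_IDS <- c(LETTERS, letters, as.character(0:9))

#' Amyloid-beta(1-40) sequence
#' @return Character vector of 40 three-letter residue codes.
#' @export
ab40_sequence <- function() {
  c("ASP", "ALA", "GLU", "PHE", "ARG", "HIS", "ASP", "SER", "GLY", "TYR",
    "GLU", "VAL", "HIS", "HIS", "GLN", "LYS", "LEU", "VAL", "PHE", "PHE",
    "ALA", "GLU", "ASP", "VAL", "GLY", "SER", "ASN", "LYS", "GLY", "ALA",
    "ILE", "ILE", "GLY", "LEU", "MET", "VAL", "GLY", "GLY", "VAL", "VAL")
}

#' Per-residue formal charge
#' @param res Character vector of three-letter residue codes.
#' @return Numeric charges in elementary units.
#' @export
residue_charge <- function(res) {
  res <- toupper(res)
  bad <- setdiff(res, STANDARD_AA)
  if (length(bad)) stop("unknown residue(s): ", paste(unique(bad), collapse = ", "))
  q <- AA_CHARGE[res]
  q[is.na(q)] <- 0
  unname(q)
}

#' Swap a sequence's charged residues for their opposites
#'
#' Lys/Arg become Glu; Glu/Asp become Lys; every other residue is unchanged.
#' This is the charge inversion used to derive the peptide ligand body from
#' the exposed fibril surface sequence Lys-Leu-Val-Phe-Phe-Ala-Glu-Asp.
#'
#' @param seq Character vector of three-letter residue codes (standard 20).
#' @return Character vector of the same length.
#' @examples
#' invert_charge_sequence(c("LYS", "LEU", "VAL", "PHE", "PHE", "ALA", "GLU", "ASP"))
#' @export
invert_charge_sequence <- function(seq) {
  seq <- toupper(seq)
  bad <- setdiff(seq, STANDARD_AA)
  if (length(bad)) stop("unknown residue(s): ", paste(unique(bad), collapse = ", "))
  out <- seq
  out[seq %in% c("LYS", "ARG")] <- "GLU"
  out[seq %in% c("GLU", "ASP")] <- "LYS"
  out
}

#' Fibril generator specification
#'
#' Describes an idealized two-protofilament cross-beta fibril: each peptide is
#' a coarse U-shaped trace (one C-alpha bead plus one pseudo-side-chain bead
#' per residue) stacked along +z with a fixed axial rise and a controllable
#' per-peptide twist about the fibril axis.
#'
#' @param n_peptides Peptides per protofilament (default 29).
#' @param rise Axial rise per peptide in Angstrom (default 4.8, the canonical
#'   cross-beta spacing; 29 peptides then span 13.44 nm).
#' @param imposed_twist Rotation between successive peptides in degrees,
#'   `0 <= twist < 180`.
#' @param sequence Three-letter residue codes of one peptide (default
#'   [ab40_sequence()]).
#' @param noise_sigma Gaussian displacement added independently per
#'   coordinate, Angstrom.
#' @param include_disordered_stub If `TRUE`, residues 1-8 are rebuilt as a
#'   random-walk coil instead of the extended strand (disordered N-terminus).
#' @param charged_termini If `TRUE`, add +1 e to each N-terminal and -1 e to
#'   each C-terminal backbone bead.
#' @param lateral_offset Translation of the second protofilament (Angstrom);
#'   it is the first protofilament rotated 180 degrees about the axis, then
#'   offset by this vector.
#' @param rng_seed Integer seed (stub walks and noise).
#' @return An object of class `fibril_spec`.
#' @export
fibril_spec <- function(n_peptides = 29, rise = 4.8, imposed_twist = 0,
                        sequence = ab40_sequence(), noise_sigma = 0,
                        include_disordered_stub = FALSE,
                        charged_termini = FALSE,
                        lateral_offset = c(0, -20, 0), rng_seed = 1L) {
  stopifnot(n_peptides >= 2, rise > 0,
            imposed_twist >= 0, imposed_twist < 180,
            noise_sigma >= 0, length(lateral_offset) == 3L)
  if (length(sequence) < 2) stop("sequence must have at least 2 residues")
  bad <- setdiff(toupper(sequence), STANDARD_AA)
  if (length(bad)) stop("unknown residue(s): ", paste(unique(bad), collapse = ", "))
  if (n_peptides > length(CHAIN_IDS))
    stop("at most ", length(CHAIN_IDS), " peptides per protofilament are supported")
  s <- list(n_peptides = as.integer(n_peptides), rise = rise,
            imposed_twist = imposed_twist, sequence = toupper(sequence),
            n_residues = length(sequence), noise_sigma = noise_sigma,
            include_disordered_stub = isTRUE(include_disordered_stub),
            charged_termini = isTRUE(charged_termini),
            lateral_offset = lateral_offset, rng_seed = as.integer(rng_seed))
  class(s) <- "fibril_spec"
  s
}

# Untwisted template peptide, all beads in the z = 0 plane so the
# CA(18)->CA(32) vector is exactly perpendicular to the fibril (+z) axis.
# Returns per-bead coordinates plus bookkeeping columns.
fibril_template <- function(spec) {
  n <- spec$n_residues
  h <- ceiling(n / 2)
  ca <- matrix(0, n, 3)
  strand1 <- seq_len(h)
  strand2 <- seq.int(h + 1L, n)
  ca[strand1, 1] <- (strand1 - 1) * 3.8
  ca[strand2, 1] <- (n - strand2) * 3.8
  ca[strand2, 2] <- 10
  side <- ifelse(seq_len(n) %% 2 == 0, 1.8, -1.8)
  cb <- ca + cbind(0, side, 0)
  pos <- matrix(NA_real_, 2 * n, 3)
  pos[seq(1, 2 * n, 2), ] <- ca
  pos[seq(2, 2 * n, 2), ] <- cb
  ctr <- colMeans(pos); ctr[3] <- 0
  sweep(pos, 2, ctr)
}

# Re-place residues 1..8 of one peptide's template as a random-walk coil
# growing backwards from residue 9 (3.8 A backbone steps, 1.8 A side beads).
apply_stub <- function(pos, n_res) {
  if (n_res < 9) return(pos)
  rand_unit <- function() { v <- stats::rnorm(3); v / sqrt(sum(v^2)) }
  for (i in 8:1) {
    ca_next <- pos[2 * i + 1, ]          # CA of residue i+1
    ca <- ca_next + 3.8 * rand_unit()
    pos[2 * i - 1, ] <- ca
    pos[2 * i, ] <- ca + 1.8 * rand_unit()
  }
  pos
}

#' Build an idealized two-protofilament fibril
#'
#' The fibril axis is +z. Peptide `j + 1` of a protofilament is peptide `j`
#' translated by the axial rise and rotated by the imposed twist about the
#' axis; the second protofilament is the first rotated 180 degrees about the
#' axis and offset laterally. Each peptide is a coarse U-shaped trace with one
#' `CA` backbone bead and one `CB` pseudo-side-chain bead per residue; partial
#' charges follow the residue-level table (Asp/Glu -1 e, Lys/Arg +1 e on the
#' side bead, His and all others 0).
#'
#' @param spec A [fibril_spec()].
#' @return A `structure_model` with `role = "fibril"`, segids `FIB1`/`FIB2`
#'   and one chain per peptide.
#' @examples
#' fib <- build_fibril(fibril_spec(n_peptides = 5, imposed_twist = 6.48))
#' diff(range(fib$atoms$z[fib$atoms$name == "CA"])) # (5-1) * 4.8
#' @export
build_fibril <- function(spec) {
  stopifnot(inherits(spec, "fibril_spec"))
  set.seed(spec$rng_seed)
  n_res <- spec$n_residues
  template <- fibril_template(spec)
  base <- list(template,
               sweep(template %*% t(rot_z(180)), 2, spec$lateral_offset, "+"))
  rows <- vector("list", 2L * spec$n_peptides)
  k <- 0L
  for (pf in 1:2) {
    for (j in seq_len(spec$n_peptides)) {
      pos <- base[[pf]]
      if (spec$include_disordered_stub) pos <- apply_stub(pos, n_res)
      pos <- pos %*% t(rot_z((j - 1) * spec$imposed_twist))
      pos[, 3] <- pos[, 3] + (j - 1) * spec$rise
      q <- numeric(2 * n_res)
      q[seq(2, 2 * n_res, 2)] <- residue_charge(spec$sequence)
      if (spec$charged_termini) {
        q[1] <- q[1] + 1
        q[2 * n_res - 1] <- q[2 * n_res - 1] - 1
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        atom_id = 0L,
        name = rep(c("CA", "CB"), n_res),
        element = "C",
        resname = rep(spec$sequence, each = 2),
        resseq = rep(seq_len(n_res), each = 2),
        chain = CHAIN_IDS[j],
        segid = paste0("FIB", pf),
        x = pos[, 1], y = pos[, 2], z = pos[, 3],
        charge = q,
        epsilon = rep(c(0.10, 0.20), n_res),
        rmin_half = rep(c(2.0, 2.4), n_res),
        radius = rep(c(1.9, 2.3), n_res),
        stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$atom_id <- seq_len(nrow(atoms))
  if (spec$noise_sigma > 0) {
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), sd = spec$noise_sigma)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), sd = spec$noise_sigma)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), sd = spec$noise_sigma)
  }
  peptides <- data.frame(
    chain = rep(CHAIN_IDS[seq_len(spec$n_peptides)], 2),
    segid = rep(c("FIB1", "FIB2"), each = spec$n_peptides),
    first_res = 1L, last_res = n_res,
    protofilament = rep(1:2, each = spec$n_peptides),
    ordinal = rep(seq_len(spec$n_peptides), 2),
    stringsAsFactors = FALSE)
  structure_model(atoms, peptides = peptides, role = "fibril")
}
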