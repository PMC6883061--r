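check_energy_params <- function(a, idx, need_lj = TRUE) {
  bad_q <- idx[is.na(a$charge[idx])]
  if (length(bad_q))
    stop("parameters missing: no partial charge for atom(s) ",
         paste(utils::head(bad_q, 8), collapse = ", "),
         if (length(bad_q) > 8) " ..." else "")
  if (need_lj) {
    bad <- idx[is.na(a$epsilon[idx]) | is.na(a$rmin_half[idx])]
    if (length(bad))
      stop("parameters missing: no LJ parameters for atom(s) ",
           paste(utils::head(bad, 8), collapse = ", "),
           if (length(bad) > 8) " ..." else "")
  }
}

residue_key <- function(a, idx) paste(a$segid[idx], a$chain[idx], a$resseq[idx])

#' Coulomb + Lennard-Jones interaction energy between two selections
#'
#' Screened Coulomb energy `332.0636 / eps * sum(q_i q_j / r_ij)` (kcal/mol)
#' over all inter-group pairs (no cutoff unless `coulomb_cutoff` is set in the
#' parameters), plus the Lennard-Jones (12,6) energy
#' `eps_ij * ((rmin_ij / r)^12 - 2 (rmin_ij / r)^6)` truncated without
#' switching at `lj_cutoff`, with Lorentz-Berthelot-style combining
#' `eps_ij = sqrt(eps_i eps_j)`, `rmin_ij = rmin_half_i + rmin_half_j`. Only
#' inter-group pairs are summed: this is an interaction energy, not a total
#' energy, and intra-selection or 1-4 exclusions never enter. Energies are
#' also attributed to the residue of the `group_b` atom of each pair.
#'
#' @param model A `structure_model`.
#' @param group_a,group_b Disjoint nonempty integer atom selections.
#' @param coords Optional frame coordinates (`n_atoms x 3`); defaults to the
#'   model's own.
#' @param params A [nonbonded_params()].
#' @return An object of class `interaction_report`: `coulomb`, `lj`, `total`
#'   (kcal/mol), `per_residue` (data.frame keyed by the `group_b` residues),
#'   `frames_used`, `dielectric`, `lj_cutoff`.
#' @examples
#' # +1 e and -1 e at 3.320636 A in vacuum: exactly -100 kcal/mol Coulomb
#' @export
pair_energy <- function(model, group_a, group_b,
                        coords = model_coords(model),
                        params = nonbonded_params()) {
  if (length(intersect(group_a, group_b)))
    stop("group_a and group_b selections overlap")
  if (!length(group_a) || !length(group_b))
    stop("selections must be nonempty")
  a <- model$atoms
  check_energy_params(a, c(group_a, group_b))
  xa <- coords[group_a, , drop = FALSE]
  xb <- coords[group_b, , drop = FALSE]
  qa <- a$charge[group_a]; qb <- a$charge[group_b]
  # all-pair distances
  d2 <- outer(rowSums(xa^2), rep(1, length(group_b))) +
    outer(rep(1, length(group_a)), rowSums(xb^2)) - 2 * xa %*% t(xb)
  d <- sqrt(pmax(d2, 0))
  if (any(d == 0)) stop("overlapping atoms (r = 0) between the two groups")
  cmat <- (COULOMB_KCAL / params$dielectric) * outer(qa, qb) / d
  if (!is.null(params$coulomb_cutoff)) cmat[d > params$coulomb_cutoff] <- 0
  coul_by_b <- colSums(cmat)
  # LJ within cutoff via the cell list (exact vs brute force)
  pr <- neighbor_pairs(xa, xb, params$lj_cutoff)
  lj_by_b <- numeric(length(group_b))
  if (length(pr$i)) {
    if (any(pr$d == 0)) stop("overlapping atoms (r = 0) between the two groups")
    eps <- sqrt(a$epsilon[group_a[pr$i]] * a$epsilon[group_b[pr$j]])
    rmin <- a$rmin_half[group_a[pr$i]] + a$rmin_half[group_b[pr$j]]
    sr6 <- (rmin / pr$d)^6
    e <- eps * (sr6^2 - 2 * sr6)
    sums <- rowsum(e, pr$j)
    lj_by_b[as.integer(rownames(sums))] <- sums[, 1]
  }
  key <- residue_key(a, group_b)
  per <- data.frame(
    segid = a$segid[group_b], chain = a$chain[group_b],
    resseq = a$resseq[group_b], resname = a$resname[group_b],
    coulomb = coul_by_b, lj = lj_by_b, stringsAsFactors = FALSE)
  per <- stats::aggregate(cbind(coulomb, lj) ~ segid + chain + resseq + resname,
                          data = per, FUN = sum)
  per <- per[order(per$segid, per$chain, per$resseq), ]
  rownames(per) <- NULL
  out <- list(coulomb = sum(cmat), lj = sum(lj_by_b),
              total = sum(cmat) + sum(lj_by_b),
              per_residue = per, frames_used = 1L,
              dielectric = params$dielectric, lj_cutoff = params$lj_cutoff)
  class(out) <- "interaction_report"
  out
}

#' @export
print.interaction_report <- function(x, ...) {
  cat(sprintf("<interaction_report> averaged over %d frame(s), dielectric %g, LJ cutoff %g A\n",
              x$frames_used, x$dielectric, x$lj_cutoff))
  cat(sprintf("  Coulomb: %10.3f kcal/mol\n", x$coulomb))
  cat(sprintf("  LJ     : %10.3f kcal/mol\n", x$lj))
  cat(sprintf("  total  : %10.3f kcal/mol\n", x$total))
  invisible(x)
}

#' Frame-averaged interaction energy over a trajectory
#'
#' Mean of the per-frame [pair_energy()] reports over the trailing
#' `last_n_frames`; errors if the trajectory is shorter (no rescaling).
#'
#' @inheritParams pair_energy
#' @param traj A `trajectory`.
#' @param last_n_frames Trailing frames to average (default 500).
#' @return An `interaction_report` with frame-averaged energies, an averaged
#'   `per_residue` table, and a `per_frame` data.frame (frame, coulomb, lj,
#'   total).
#' @export
trajectory_energy <- function(traj, group_a, group_b,
                              params = nonbonded_params(),
                              last_n_frames = 500L) {
  frames <- last_frame_indices(traj, last_n_frames)
  model <- traj$topology
  reports <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    reports[[k]] <- pair_energy(model, group_a, group_b,
                                coords = frame_coords(traj, frames[k]),
                                params = params)
  }
  per_frame <- data.frame(
    frame = frames,
    coulomb = vapply(reports, `[[`, 0, "coulomb"),
    lj = vapply(reports, `[[`, 0, "lj"),
    total = vapply(reports, `[[`, 0, "total"))
  per <- reports[[1]]$per_residue
  if (length(reports) > 1) {
    for (r in reports[-1]) {
      per$coulomb <- per$coulomb + r$per_residue$coulomb
      per$lj <- per$lj + r$per_residue$lj
    }
    per$coulomb <- per$coulomb / length(reports)
    per$lj <- per$lj / length(reports)
  }
  out <- list(coulomb = mean(per_frame$coulomb), lj = mean(per_frame$lj),
              total = mean(per_frame$total), per_residue = per,
              frames_used = length(frames), dielectric = params$dielectric,
              lj_cutoff = params$lj_cutoff, per_frame = per_frame)
  class(out) <- "interaction_report"
  out
}

#' Per-residue energy decomposition of an interaction report
#'
#' Energies are attributed to the residue of the `group_b` atom in each pair;
#' the residue entries sum to the report totals.
#'
#' @param report An `interaction_report`.
#' @return The per-residue data.frame (`segid`, `chain`, `resseq`, `resname`,
#'   `coulomb`, `lj`).
#' @export
per_residue_decomposition <- function(report) {
  stopifnot(inherits(report, "interaction_report"))
  report$per_residue
}

#' Coulomb electrostatic potential on a regular grid
#'
#' The screened point-charge potential `phi(x) = 14.3996 / eps * sum_i q_i /
#' |x - x_i|` in volts, evaluated on a regular grid; grid points closer than
#' `mask_radius` to any atom are masked `NA`.
#'
#' @param model A `structure_model` with charges.
#' @param box Either `NULL` (model bounding box plus 5 A margin) or a
#'   `list(min = , max = )` of length-3 vectors (Angstrom).
#' @param spacing Grid spacing in Angstrom (> 0).
#' @param params A [nonbonded_params()] (supplies the dielectric).
#' @param mask_radius Masking distance in Angstrom (default 0.5).
#' @return An object of class `potential_grid`: `origin`, `spacing`, `dims`,
#'   `values` (3-D array, volts), `dielectric`.
#' @export
coulomb_grid <- function(model, box = NULL, spacing, params = nonbonded_params(),
                         mask_radius = 0.5) {
  stopifnot(spacing > 0)
  a <- model$atoms
  check_energy_params(a, seq_len(nrow(a)), need_lj = FALSE)
  xyz <- model_coords(model)
  if (is.null(box))
    box <- list(min = apply(xyz, 2, min) - 5, max = apply(xyz, 2, max) + 5)
  ax <- lapply(1:3, function(k) seq(box$min[k], box$max[k], by = spacing))
  dims <- vapply(ax, length, 0L)
  if (any(dims == 0)) stop("empty grid box")
  g <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  phi <- numeric(nrow(g))
  masked <- rep(FALSE, nrow(g))
  q <- a$charge
  for (i in seq_len(nrow(xyz))) {
    d <- sqrt((g[, 1] - xyz[i, 1])^2 + (g[, 2] - xyz[i, 2])^2 +
                (g[, 3] - xyz[i, 3])^2)
    masked <- masked | d < mask_radius
    phi <- phi + q[i] / pmax(d, 1e-12)
  }
  phi <- (COULOMB_VOLT / params$dielectric) * phi
  phi[masked] <- NA_real_
  out <- list(origin = c(box$min[1], box$min[2], box$min[3]),
              spacing = spacing, dims = dims,
              axes = ax, values = array(phi, dim = dims),
              dielectric = params$dielectric)
  class(out) <- "potential_grid"
  out
}

#' @export
print.potential_grid <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("<potential_grid> %d x %d x %d points, spacing %g A, dielectric %g\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing, x$dielectric))
  cat(sprintf("  potential range: %.3f .. %.3f V (%d masked points)\n",
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

#' Write a potential grid as an OpenDX scalar field
#' @param grid A `potential_grid`.
#' @param path Output path (`.dx`).
#' @return Invisibly, `path`.
#' @export
write_grid_dx <- function(grid, path) {
  con <- file(path, "w"); on.exit(close(con))
  d <- grid$dims
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %g 0 0", grid$spacing),
    sprintf("delta 0 %g 0", grid$spacing),
    sprintf("delta 0 0 %g", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # DX convention: x slowest, z fastest
  ord <- as.vector(aperm(array(seq_len(prod(d)), dim = d), c(3, 2, 1)))
  vals <- as.vector(grid$values)[ord]
  vals[is.na(vals)] <- 0
  writeLines(apply(matrix(c(vals, rep(NA, (3 - length(vals) %% 3) %% 3)),
                          ncol = 3, byrow = TRUE), 1,
                   function(r) paste(stats::na.omit(r), collapse = " ")), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
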