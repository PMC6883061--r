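ca_index <- function(model, protofilament, ordinal, resseq) {
  p <- model$peptides
  if (is.null(p)) stop("model has no peptide table")
  row <- which(!is.na(p$protofilament) & p$protofilament == protofilament &
                 p$ordinal == ordinal)
  if (length(row) != 1L)
    stop("peptide ordinal ", ordinal, " not found in protofilament ", protofilament)
  a <- model$atoms
  idx <- which(a$chain == p$chain[row] & a$segid == p$segid[row] &
                 a$resseq == resseq & a$name == "CA")
  if (length(idx) != 1L)
    stop("C-alpha of residue ", resseq, " missing in peptide ordinal ",
         ordinal, " (protofilament ", protofilament, ")")
  idx
}

#' Inter-strand orientation vector of one peptide
#'
#' The displacement from the C-alpha of `to_residue` to the C-alpha of
#' `from_residue` (i.e. pointing 32 -> 18 with the defaults), unnormalized.
#' The angle between this vector in consecutive peptides is the twist angle.
#'
#' @param model A fibril `structure_model` (supplies the topology).
#' @param coords `n_atoms x 3` coordinate matrix for one frame (defaults to
#'   the model's own coordinates).
#' @param protofilament Protofilament index (1 or 2).
#' @param ordinal Peptide ordinal within the protofilament (1-based).
#' @param from_residue,to_residue Residue numbers defining the vector
#'   (defaults 18 and 32).
#' @return Numeric length-3 vector (Angstrom).
#' @export
peptide_vector <- function(model, coords = model_coords(model),
                           protofilament = 1L, ordinal,
                           from_residue = 18L, to_residue = 32L) {
  i_from <- ca_index(model, protofilament, ordinal, from_residue)
  i_to <- ca_index(model, protofilament, ordinal, to_residue)
  coords[i_from, ] - coords[i_to, ]
}

#' Unsigned angle between two peptide vectors
#'
#' Arc-cosine of the clamped normalized dot product, in degrees; symmetric in
#' its arguments and confined to `[0, 180]`. No sign or handedness is
#' resolved.
#'
#' @param v1,v2 Numeric length-3 vectors (must be nonzero).
#' @return Angle in degrees.
#' @examples
#' pair_twist_angle(c(1, 0, 0), c(0, 1, 0)) # 90
#' @export
pair_twist_angle <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero-length vector has no direction")
  acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

#' Percentage of twist angles per band
#'
#' Partitions pooled angles into the three bands `[0, 10)`, `[10, 20)` and
#' `[20, 180]` degrees (boundary ties go upward) and returns percentages that
#' sum to 100.
#'
#' @param angles Nonempty numeric vector of angles in degrees.
#' @return Named numeric vector `c("<10", "10-20", ">=20")` in percent.
#' @examples
#' bin_percentages(c(5, 15, 25, 35)) # 25, 25, 50
#' @export
bin_percentages <- function(angles) {
  if (!length(angles)) stop("empty angle pool")
  n <- length(angles)
  c("<10" = 100 * sum(angles < 10) / n,
    "10-20" = 100 * sum(angles >= 10 & angles < 20) / n,
    ">=20" = 100 * sum(angles >= 20) / n)
}

#' Twist-angle statistics over a trajectory
#'
#' For every retained frame, computes the unsigned angle between the
#' C-alpha(32)->C-alpha(18) vectors of consecutive peptides inside
#' `inner_range` (defaults to ordinals 4..25, i.e. 22 inner peptides of a
#' 29-peptide protofilament, excluding the boundary-affected termini), giving
#' `m = length(inner_range) - 1` pairs per frame. The grand mean over frames
#' and pairs is the twist statistic `theta_twist`; the same pooled angles feed
#' the histogram and the band percentages.
#'
#' @param traj A `trajectory` whose topology is a fibril.
#' @param protofilament Which protofilament to analyse (default 1).
#' @param inner_range Integer vector of consecutive peptide ordinals
#'   (default `4:25`). Ordinals outside the protofilament raise an error;
#'   there is no silent clipping.
#' @param last_n_frames Number of trailing frames to analyse (default 500; at
#'   the default 10 ps frame spacing that is the final 5 ns).
#' @param from_residue,to_residue Residues defining the peptide vector.
#' @param bin_width Histogram bin width in degrees (default 1).
#' @return An object of class `twist_report` with elements `pair_angles`
#'   (frames x pairs matrix, degrees), `frame_means`, `theta_twist`,
#'   `histogram` (breaks + counts), `bin_percentages`, `m`, `residue_pair`,
#'   `frames_used`, `protofilament`.
#' @examples
#' fib <- build_fibril(fibril_spec(imposed_twist = 6.48))
#' tr <- synthesize_trajectory(fib, n_frames = 5)
#' rep <- compute_twist_report(tr, last_n_frames = 5)
#' rep$theta_twist # 6.48
#' @export
compute_twist_report <- function(traj, protofilament = 1L,
                                 inner_range = 4:25, last_n_frames = 500L,
                                 from_residue = 18L, to_residue = 32L,
                                 bin_width = 1) {
  model <- traj$topology
  p <- model$peptides
  if (is.null(p)) stop("trajectory topology has no peptide table")
  npep <- sum(!is.na(p$protofilament) & p$protofilament == protofilament)
  if (!npep) stop("no peptides in protofilament ", protofilament)
  inner_range <- sort(unique(as.integer(inner_range)))
  if (length(inner_range) < 2L)
    stop("inner_range must contain at least two peptide ordinals")
  if (any(diff(inner_range) != 1L))
    stop("inner_range must be consecutive ordinals")
  if (min(inner_range) < 1L || max(inner_range) > npep)
    stop("inner_range ", min(inner_range), "..", max(inner_range),
         " exceeds the protofilament's ", npep, " peptides")
  frames <- last_frame_indices(traj, last_n_frames)
  i_from <- vapply(inner_range, function(o)
    ca_index(model, protofilament, o, from_residue), 0L)
  i_to <- vapply(inner_range, function(o)
    ca_index(model, protofilament, o, to_residue), 0L)
  m <- length(inner_range) - 1L
  ang <- matrix(NA_real_, nrow = length(frames), ncol = m)
  cols_from <- cbind(3 * (i_from - 1) + 1, 3 * (i_from - 1) + 2, 3 * (i_from - 1) + 3)
  cols_to <- cbind(3 * (i_to - 1) + 1, 3 * (i_to - 1) + 2, 3 * (i_to - 1) + 3)
  for (fi in seq_along(frames)) {
    row <- traj$xyz[frames[fi], ]
    v <- matrix(row[cols_from] - row[cols_to], ncol = 3)
    vn <- v / sqrt(rowSums(v^2))
    dots <- rowSums(vn[-nrow(vn), , drop = FALSE] * vn[-1, , drop = FALSE])
    ang[fi, ] <- acos(pmax(-1, pmin(1, dots))) * 180 / pi
  }
  pooled <- as.vector(ang)
  h <- graphics::hist(pooled, breaks = seq(0, 180, by = bin_width),
                      plot = FALSE, right = FALSE, include.lowest = TRUE)
  rep <- list(pair_angles = ang,
              frame_means = rowMeans(ang),
              theta_twist = mean(pooled),
              histogram = list(breaks = h$breaks, counts = h$counts),
              bin_percentages = bin_percentages(pooled),
              m = m,
              residue_pair = c(from = from_residue, to = to_residue),
              frames_used = length(frames),
              protofilament = protofilament)
  class(rep) <- "twist_report"
  rep
}

#' @export
print.twist_report <- function(x, ...) {
  cat(sprintf("<twist_report> protofilament %d, %d frames x %d pairs (%d angles)\n",
              x$protofilament, x$frames_used, x$m, x$frames_used * x$m))
  cat(sprintf("  theta_twist = %.4f deg\n", x$theta_twist))
  bp <- x$bin_percentages
  cat(sprintf("  bands: <10: %.2f%%  10-20: %.2f%%  >=20: %.2f%%\n",
              bp[1], bp[2], bp[3]))
  invisible(x)
}

#' @export
summary.twist_report <- function(object, ...) {
  pooled <- as.vector(object$pair_angles)
  out <- list(theta_twist = object$theta_twist,
              sd = stats::sd(pooled),
              quartiles = stats::quantile(pooled, c(0.25, 0.5, 0.75)),
              bin_percentages = object$bin_percentages,
              n = length(pooled))
  class(out) <- "summary.twist_report"
  out
}

#' @export
print.summary.twist_report <- function(x, ...) {
  cat(sprintf("Twist statistic: %.4f deg (sd %.4f, n = %d)\n",
              x$theta_twist, x$sd, x$n))
  cat(sprintf("Quartiles: %.3f / %.3f / %.3f deg\n",
              x$quartiles[1], x$quartiles[2], x$quartiles[3]))
  bp <- x$bin_percentages
  cat(sprintf("Bands: <10: %.2f%%  10-20: %.2f%%  >=20: %.2f%%\n",
              bp[1], bp[2], bp[3]))
  invisible(x)
}

#' Histogram of pooled twist angles
#' @param x A `twist_report`.
#' @param xmax Right edge of the plotted range in degrees.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.twist_report <- function(x, xmax = 40, ...) {
  br <- x$histogram$breaks
  mid <- (br[-1] + br[-length(br)]) / 2
  keep <- mid <= xmax
  graphics::plot(mid[keep], x$histogram$counts[keep], type = "h",
                 xlab = "twist angle (deg)", ylab = "count", ...)
  graphics::abline(v = x$theta_twist, lty = 2)
  invisible(x)
}
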