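#' Construct a trajectory
#'
#' A trajectory couples one topology (a [structure_model()]) with an ordered
#' set of coordinate frames. Frames are stored bio3d-style as a numeric matrix
#' with one row per frame and columns `x1, y1, z1, x2, ...`.
#'
#' @param topology A `structure_model`.
#' @param xyz Numeric matrix, `n_frames x (3 * n_atoms)`.
#' @param frame_dt Time spacing between frames in ps. The default 10 ps makes
#'   500 frames span 5 ns.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(topology, xyz, frame_dt = 10) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * n_atoms(topology))
    stop("each frame must supply exactly one coordinate triple per topology atom (",
         n_atoms(topology), " atoms, got ", ncol(xyz) / 3, ")")
  stopifnot(frame_dt > 0)
  t <- list(topology = topology, xyz = xyz, frame_dt = frame_dt)
  class(t) <- "trajectory"
  t
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, dt = %g ps (%g ns total)\n",
              nrow(x$xyz), n_atoms(x$topology), x$frame_dt,
              nrow(x$xyz) * x$frame_dt / 1000))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Coordinates of one frame
#' @param traj A `trajectory`.
#' @param i Frame index (1-based).
#' @return Numeric `n_atoms x 3` matrix.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  m <- matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
  colnames(m) <- c("x", "y", "z")
  m
}

last_frame_indices <- function(traj, last_n_frames) {
  nf <- n_frames(traj)
  if (last_n_frames > nf)
    stop("trajectory has ", nf, " frames but ", last_n_frames,
         " were requested; shorter trajectories are not rescaled")
  seq.int(nf - last_n_frames + 1L, nf)
}

#' Synthesize a noisy trajectory around a reference structure
#'
#' Every frame is the reference coordinates plus i.i.d. Gaussian displacement
#' of standard deviation `noise_sigma` per coordinate, optionally with a
#' cumulative rigid-body drift applied to a tagged sub-structure. Useful for
#' exercising frame-averaged analyses with a known ground truth.
#'
#' @param model Reference `structure_model`.
#' @param n_frames Number of frames (>= 1).
#' @param noise_sigma Gaussian coordinate noise, Angstrom (>= 0).
#' @param drift Optional `list(atoms = <indices>, per_frame = <length-3
#'   translation in Angstrom>)`; the translation accumulates frame over frame.
#' @param rng_seed Integer seed; identical seeds give bit-identical
#'   trajectories.
#' @param frame_dt Frame spacing in ps.
#' @return A `trajectory`.
#' @examples
#' fib <- build_fibril(fibril_spec(n_peptides = 4))
#' tr <- synthesize_trajectory(fib, n_frames = 10, noise_sigma = 0.2, rng_seed = 7)
#' @export
synthesize_trajectory <- function(model, n_frames, noise_sigma = 0,
                                  drift = NULL, rng_seed = 1L, frame_dt = 10) {
  stopifnot(n_frames >= 1)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  ref <- as.vector(t(model_coords(model)))  # x1 y1 z1 x2 ...
  nf <- as.integer(n_frames)
  set.seed(rng_seed)
  xyz <- matrix(ref, nrow = nf, ncol = length(ref), byrow = TRUE)
  if (noise_sigma > 0)
    xyz <- xyz + matrix(stats::rnorm(nf * length(ref), sd = noise_sigma),
                        nrow = nf)
  if (!is.null(drift)) {
    stopifnot(is.list(drift), length(drift$per_frame) == 3L)
    cols <- as.vector(rbind(3 * (drift$atoms - 1) + 1,
                            3 * (drift$atoms - 1) + 2,
                            3 * (drift$atoms - 1) + 3))
    step <- rep(drift$per_frame, length(drift$atoms))
    for (f in seq_len(nf))
      xyz[f, cols] <- xyz[f, cols] + (f - 1) * rep(step, 1)
  }
  trajectory(model, xyz, frame_dt = frame_dt)
}

#' Write a trajectory as multi-frame XYZ
#'
#' Plain-text XYZ: per frame an atom-count line, a comment line with the frame
#' index and time, then `element x y z` records to 6 decimals.
#'
#' @param traj A `trajectory`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trajectory_xyz <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  el <- traj$topology$atoms$element
  na <- n_atoms(traj$topology)
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    writeLines(c(sprintf("%d", na),
                 sprintf("frame %d t= %g ps", f, (f - 1) * traj$frame_dt),
                 sprintf("%-2s %12.6f %12.6f %12.6f",
                         el, xyz[, 1], xyz[, 2], xyz[, 3])), con)
  }
  invisible(path)
}

#' Read a multi-frame trajectory
#'
#' Supports plain-text multi-frame XYZ (written by [write_trajectory_xyz()]
#' or any conforming tool) and multi-model PDB (via bio3d).
#'
#' @param path Trajectory file.
#' @param topology The `structure_model` the frames belong to.
#' @param format `"xyz"` or `"pdb"` (default from extension).
#' @param frame_dt Frame spacing in ps.
#' @return A `trajectory`.
#' @export
read_trajectory <- function(path, topology, format = c("auto", "xyz", "pdb"),
                            frame_dt = 10) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    return(trajectory(topology, pdb$xyz, frame_dt = frame_dt))
  }
  lines <- readLines(path)
  na <- n_atoms(topology)
  per_frame <- na + 2L
  if (length(lines) %% per_frame != 0L)
    stop("XYZ file length is not a whole number of ", na, "-atom frames")
  nf <- length(lines) %/% per_frame
  xyz <- matrix(NA_real_, nrow = nf, ncol = 3L * na)
  for (f in seq_len(nf)) {
    block <- lines[((f - 1L) * per_frame + 3L):(f * per_frame)]
    parts <- scan(text = block, what = list(el = "", x = 0, y = 0, z = 0), quiet = TRUE)
    xyz[f, ] <- as.vector(rbind(parts$x, parts$y, parts$z))
  }
  trajectory(topology, xyz, frame_dt = frame_dt)
}
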