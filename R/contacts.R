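#' Count atoms of one group in contact with another
#'
#' Number of atoms in `group_a` (heavy atoms only by default) whose minimum
#' distance to any atom of `group_b` is at or below the cutoff (the boundary
#' is inclusive: a pair at exactly the cutoff counts). Distances are
#' center-to-center. The cell-list search is exact with respect to the
#' brute-force double loop.
#'
#' @param model A `structure_model` supplying the topology.
#' @param group_a,group_b Disjoint integer atom index selections.
#' @param coords Optional `n_atoms x 3` frame coordinates (defaults to the
#'   model's own).
#' @param cutoff Contact distance in Angstrom (default 5).
#' @param heavy_only Count only non-hydrogen atoms of `group_a` (default
#'   `TRUE`).
#' @return Integer contact count.
#' @export
count_contacts <- function(model, group_a, group_b,
                           coords = model_coords(model), cutoff = 5,
                           heavy_only = TRUE) {
  if (length(intersect(group_a, group_b)))
    stop("group_a and group_b selections overlap")
  if (heavy_only) group_a <- group_a[model$atoms$heavy[group_a]]
  if (!length(group_a) || !length(group_b)) return(0L)
  pr <- neighbor_pairs(coords[group_a, , drop = FALSE],
                       coords[group_b, , drop = FALSE], cutoff)
  length(unique(pr$i))
}

#' Per-peptide contact profile over a trajectory
#'
#' Applies [count_contacts()] for every peptide selection against the
#' nanoparticle selection in each trailing frame and returns frame-averaged
#' means and standard deviations.
#'
#' @param traj A `trajectory`.
#' @param peptide_sels Nonempty list of integer atom selections, one per
#'   peptide.
#' @param np_sel Integer atom selection of the nanoparticle.
#' @param params A [nonbonded_params()] (supplies the contact cutoff).
#' @param last_n_frames Trailing frames to average (default 500).
#' @param heavy_only Count heavy atoms only (default `TRUE`).
#' @return A data.frame with one row per peptide: `peptide`, `mean_contacts`,
#'   `sd_contacts`; the per-frame count matrix is attached as attribute
#'   `"counts"` (frames x peptides).
#' @export
binding_profile <- function(traj, peptide_sels, np_sel,
                            params = nonbonded_params(),
                            last_n_frames = 500L, heavy_only = TRUE) {
  if (!length(peptide_sels)) stop("empty peptide list")
  frames <- last_frame_indices(traj, last_n_frames)
  model <- traj$topology
  counts <- matrix(NA_real_, length(frames), length(peptide_sels))
  for (k in seq_along(frames)) {
    xyz <- frame_coords(traj, frames[k])
    counts[k, ] <- vapply(peptide_sels, function(sel)
      count_contacts(model, sel, np_sel, coords = xyz,
                     cutoff = params$contact_cutoff,
                     heavy_only = heavy_only), 0L)
  }
  out <- data.frame(
    peptide = if (!is.null(names(peptide_sels))) names(peptide_sels)
              else seq_along(peptide_sels),
    mean_contacts = colMeans(counts),
    sd_contacts = apply(counts, 2, stats::sd))
  attr(out, "counts") <- counts
  out
}
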