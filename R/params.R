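# Physical constants used throughout: the MD-convention Coulomb prefactor in
# kcal*A/(mol*e^2) and its electrostatic-potential analogue in V*A/e.
COULOMB_KCAL <- 332.0636
COULOMB_VOLT <- 14.3996

#' Nonbonded analysis parameters
#'
#' Bundles the knobs shared by the energy, surface-area and contact analyses:
#' the uniform dielectric used to screen Coulomb interactions, the
#' Lennard-Jones truncation distance, the heavy-atom contact cutoff, the
#' solvent probe radius, and the Monte-Carlo surface sampling density.
#'
#' @param dielectric Uniform relative dielectric constant (dimensionless).
#'   The default 78.5 mimics bulk water in post-hoc energy evaluation.
#' @param lj_cutoff Lennard-Jones truncation distance in Angstrom. Pairs
#'   farther apart contribute no LJ energy; no switching function is applied.
#' @param coulomb_cutoff Optional Coulomb truncation distance in Angstrom.
#'   `NULL` (the default) sums over all pairs; a finite value is offered for
#'   sensitivity analysis only.
#' @param contact_cutoff Distance in Angstrom below which (inclusive) an atom
#'   counts as contacting the partner group.
#' @param probe_radius Solvent probe radius in Angstrom (water: 1.4).
#' @param sasa_points Number of Monte-Carlo points sampled on each atom's
#'   probe-expanded sphere.
#' @param bare_occluders Logical; if `TRUE`, accessibility is checked against
#'   bare van der Waals occluder spheres instead of probe-expanded ones.
#' @param rng_seed Integer seed for the surface-point sampler.
#'
#' @return An object of class `nonbonded_params` (a named list).
#' @examples
#' nonbonded_params()
#' nonbonded_params(dielectric = 1, sasa_points = 1e4)
#' @export
nonbonded_params <- function(dielectric = 78.5,
                             lj_cutoff = 10,
                             coulomb_cutoff = NULL,
                             contact_cutoff = 5,
                             probe_radius = 1.4,
                             sasa_points = 500,
                             bare_occluders = FALSE,
                             rng_seed = 1L) {
  stopifnot(is.numeric(dielectric), length(dielectric) == 1L, dielectric > 0)
  stopifnot(is.numeric(lj_cutoff), lj_cutoff > 0)
  if (!is.null(coulomb_cutoff)) stopifnot(is.numeric(coulomb_cutoff), coulomb_cutoff > 0)
  stopifnot(is.numeric(contact_cutoff), contact_cutoff > 0)
  stopifnot(is.numeric(probe_radius), probe_radius >= 0)
  stopifnot(is.numeric(sasa_points), sasa_points >= 1)
  p <- list(dielectric = dielectric, lj_cutoff = lj_cutoff,
            coulomb_cutoff = coulomb_cutoff, contact_cutoff = contact_cutoff,
            probe_radius = probe_radius, sasa_points = as.integer(sasa_points),
            bare_occluders = isTRUE(bare_occluders),
            rng_seed = as.integer(rng_seed))
  class(p) <- "nonbonded_params"
  p
}

#' @export
print.nonbonded_params <- function(x, ...) {
  cat("Nonbonded analysis parameters\n")
  cat(sprintf("  dielectric      : %g\n", x$dielectric))
  cat(sprintf("  LJ cutoff       : %g A\n", x$lj_cutoff))
  cat(sprintf("  Coulomb cutoff  : %s\n",
              if (is.null(x$coulomb_cutoff)) "none (all pairs)" else paste0(x$coulomb_cutoff, " A")))
  cat(sprintf("  contact cutoff  : %g A (inclusive)\n", x$contact_cutoff))
  cat(sprintf("  probe radius    : %g A\n", x$probe_radius))
  cat(sprintf("  SASA points/atom: %d (seed %d, %s occluders)\n",
              x$sasa_points, x$rng_seed,
              if (x$bare_occluders) "bare-vdW" else "probe-expanded"))
  invisible(x)
}
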