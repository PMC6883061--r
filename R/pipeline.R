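pipeline_defaults <- function() {
  list(
    fibril = list(n_peptides = 29L, rise = 4.8, imposed_twist = 6.48,
                  noise_sigma = 0, include_disordered_stub = FALSE,
                  charged_termini = FALSE, rng_seed = 1L),
    np = list(recipe = "Pos", core_diameter = 22, au_bond_length = 2.74,
              rng_seed = 1L),
    pose = list(target = "beta_sheet", gap = 5, center = NULL),
    trajectory = list(n_frames = 500L, noise_sigma = 0, rng_seed = 1L,
                      frame_dt = 10),
    analysis = list(protofilament = 1L, inner_first = 4L, inner_last = 25L,
                    last_n_frames = 500L, dielectric = 78.5, lj_cutoff = 10,
                    contact_cutoff = 5, probe_radius = 1.4, sasa_points = 500L,
                    sasa_seed = 1L, area_stride = 50L, energy_stride = 10L,
                    contact_stride = 10L),
    output = list(write_trajectory = FALSE))
}

#' Assemble a pipeline run configuration
#'
#' Nested-list configuration for [run_pipeline()]. Each section overrides the
#' package defaults (29-peptide fibril with 6.48 degrees imposed twist, `Pos`
#' nanoparticle recipe posed at the beta-sheet face, 500 noiseless frames at
#' 10 ps, analysis over the trailing 500 frames with ordinals 4..25). Every
#' stochastic stage carries an explicit seed. Configurations round-trip
#' losslessly through YAML via [write_run_config()] / [read_run_config()].
#'
#' @param fibril,np,pose,trajectory,analysis,output Named lists of overrides;
#'   see `fibnp:::pipeline_defaults()` for the recognised fields. `pose$target`
#'   is one of `"beta_sheet"` (acidic Glu22/Asp23 face), `"tip"` (above the
#'   exposed Lys column at the fibril end) or `"custom"` (explicit
#'   `pose$center`). The `*_stride` analysis fields thin the frames entering
#'   the SASA, energy and contact stages (twist always uses every retained
#'   frame).
#' @return An object of class `run_config`.
#' @export
run_config <- function(fibril = list(), np = list(), pose = list(),
                       trajectory = list(), analysis = list(),
                       output = list()) {
  d <- pipeline_defaults()
  cfg <- list(fibril = utils::modifyList(d$fibril, fibril),
              np = utils::modifyList(d$np, np),
              pose = utils::modifyList(d$pose, pose, keep.null = TRUE),
              trajectory = utils::modifyList(d$trajectory, trajectory),
              analysis = utils::modifyList(d$analysis, analysis),
              output = utils::modifyList(d$output, output))
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as YAML
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `write_run_config` invisibly returns `path`; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

min_intermodel_distance <- function(xa, xb) {
  # chunked brute-force minimum distance (exact)
  dmin <- Inf
  step <- 200L
  for (s in seq(1, nrow(xa), by = step)) {
    rows <- s:min(s + step - 1L, nrow(xa))
    pa <- xa[rows, , drop = FALSE]
    d2 <- outer(rowSums(pa^2), rep(1, nrow(xb))) +
      outer(rep(1, nrow(pa)), rowSums(xb^2)) - 2 * pa %*% t(xb)
    dmin <- min(dmin, sqrt(pmax(min(d2), 0)))
  }
  dmin
}

# Place the nanoparticle outward of a surface patch, then slide it along the
# outward direction until its closest atom sits `gap` A from the fibril.
pose_center <- function(fibril, np, pose) {
  r_np <- max(sqrt(rowSums(model_coords(np)^2)))
  a <- fibril$atoms
  if (pose$target == "custom") {
    if (is.null(pose$center) || length(pose$center) != 3L)
      stop("custom pose requires a length-3 'center'")
    return(as.numeric(pose$center))
  }
  if (pose$target == "beta_sheet") {
    # acidic patch: Glu22/Asp23 side beads of the middle peptide, PF1
    mid <- ceiling(max(fibril$peptides$ordinal) / 2)
    sel <- select_atoms(fibril, protofilament = 1L, peptide = mid,
                        resseq = 22:23, name = "CB")
    patch <- colMeans(cbind(a$x[sel], a$y[sel], a$z[sel]))
    u <- c(patch[1:2] / sqrt(sum(patch[1:2]^2)), 0)
    center <- c(patch[1:2], patch[3]) + u * (r_np + pose$gap)
  } else if (pose$target == "tip") {
    # above the exposed Lys28 side bead of the last peptide, PF1
    top <- max(fibril$peptides$ordinal)
    sel <- select_atoms(fibril, protofilament = 1L, peptide = top,
                        resseq = 28, name = "CB")
    patch <- colMeans(cbind(a$x[sel], a$y[sel], a$z[sel]))
    u <- c(0, 0, 1)
    center <- c(patch[1:2], max(a$z) + r_np + pose$gap)
  } else stop("unknown pose target: ", pose$target)
  xf <- model_coords(fibril)
  for (it in 1:10) {
    dmin <- min_intermodel_distance(
      sweep(model_coords(np), 2, center, "+"), xf)
    if (abs(dmin - pose$gap) < 0.25) break
    center <- center + u * (pose$gap - dmin)
  }
  center
}

stride_trajectory <- function(traj, last_n_frames, stride) {
  frames <- last_frame_indices(traj, last_n_frames)
  frames <- frames[seq(1, length(frames), by = stride)]
  trajectory(traj$topology, traj$xyz[frames, , drop = FALSE],
             frame_dt = traj$frame_dt * stride)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full generate-analyze-report pipeline
#'
#' Builds the fibril and nanoparticle, poses the nanoparticle, synthesizes a
#' trajectory, and runs the twist, contact-area, contact-profile and
#' interaction-energy analyses. All stage outputs are written under `out_dir`
#' (structures as PQR, the report as JSON, a human-readable summary table) and
#' the run is deterministic under the configured seeds.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return An object of class `analysis_report`.
#' @examples
#' \donttest{
#' cfg <- run_config(fibril = list(n_peptides = 8),
#'                   trajectory = list(n_frames = 10),
#'                   analysis = list(inner_first = 2, inner_last = 7,
#'                                   last_n_frames = 10, area_stride = 5,
#'                                   energy_stride = 5, contact_stride = 5))
#' rep <- run_pipeline(cfg, out_dir = tempfile("fibnp"))
#' }
#' @export
run_pipeline <- function(config, out_dir = tempfile("fibnp_run")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  an <- config$analysis

  fib <- run_stage("build_fibril", build_fibril(fibril_spec(
    n_peptides = config$fibril$n_peptides, rise = config$fibril$rise,
    imposed_twist = config$fibril$imposed_twist,
    noise_sigma = config$fibril$noise_sigma,
    include_disordered_stub = config$fibril$include_disordered_stub,
    charged_termini = config$fibril$charged_termini,
    rng_seed = config$fibril$rng_seed)))
  np <- run_stage("build_nanoparticle", build_nanoparticle(np_spec_from(config$np)))
  center <- run_stage("pose", pose_center(fib, np, config$pose))
  complex <- run_stage("combine", combine_models(fib, translate_model(np, center)))
  fib_idx <- complex$components[[1]]
  np_idx <- complex$components[[2]]

  traj <- run_stage("synthesize_trajectory", synthesize_trajectory(
    complex, n_frames = config$trajectory$n_frames,
    noise_sigma = config$trajectory$noise_sigma,
    rng_seed = config$trajectory$rng_seed,
    frame_dt = config$trajectory$frame_dt))

  params <- nonbonded_params(
    dielectric = an$dielectric, lj_cutoff = an$lj_cutoff,
    contact_cutoff = an$contact_cutoff, probe_radius = an$probe_radius,
    sasa_points = an$sasa_points, rng_seed = an$sasa_seed)
  inner <- seq.int(an$inner_first, an$inner_last)

  twist <- run_stage("twist_analysis", compute_twist_report(
    traj, protofilament = an$protofilament, inner_range = inner,
    last_n_frames = an$last_n_frames))

  beta_sel <- select_atoms(complex, segid = c("FIB1", "FIB2"), resseq = 12:40)
  area_traj <- stride_trajectory(traj, an$last_n_frames, an$area_stride)
  areas <- run_stage("contact_area", list(
    full = contact_area(area_traj, np_idx, fib_idx, params = params,
                        last_n_frames = n_frames(area_traj),
                        context_label = "full fibril"),
    beta_sheet = contact_area(area_traj, np_idx, beta_sel, params = params,
                              last_n_frames = n_frames(area_traj),
                              context_label = "fibril beta-sheet (12-40)")))

  contact_traj <- stride_trajectory(traj, an$last_n_frames, an$contact_stride)
  pep_sels <- lapply(seq_len(config$fibril$n_peptides), function(o)
    select_atoms(complex, protofilament = an$protofilament, peptide = o))
  names(pep_sels) <- paste0("pf", an$protofilament, "_pep", seq_along(pep_sels))
  profile <- run_stage("binding_profile", binding_profile(
    contact_traj, pep_sels, np_idx, params = params,
    last_n_frames = n_frames(contact_traj)))

  energy_traj <- stride_trajectory(traj, an$last_n_frames, an$energy_stride)
  energies <- run_stage("trajectory_energy", list(
    full = trajectory_energy(energy_traj, np_idx, fib_idx, params = params,
                             last_n_frames = n_frames(energy_traj)),
    beta_sheet = trajectory_energy(energy_traj, np_idx, beta_sel,
                                   params = params,
                                   last_n_frames = n_frames(energy_traj))))

  files <- c(fibril = file.path(out_dir, "fibril.pqr"),
             nanoparticle = file.path(out_dir, "nanoparticle.pqr"),
             complex = file.path(out_dir, "complex.pqr"),
             config = file.path(out_dir, "config.yaml"))
  write_structure(fib, files["fibril"], format = "pqr")
  write_structure(np, files["nanoparticle"], format = "pqr")
  write_structure(complex, files["complex"], format = "pqr")
  write_run_config(config, files["config"])
  if (isTRUE(config$output$write_trajectory)) {
    files["trajectory"] <- file.path(out_dir, "trajectory.xyz")
    write_trajectory_xyz(traj, files["trajectory"])
  }
  utils::write.table(
    data.frame(frame = last_frame_indices(traj, an$last_n_frames),
               mean_twist = twist$frame_means),
    file.path(out_dir, "twist_frame_means.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)

  report <- list(
    config = unclass(config),
    pose_center = center,
    twist = list(theta_twist = twist$theta_twist, m = twist$m,
                 frames_used = twist$frames_used,
                 n_angles = twist$frames_used * twist$m,
                 bin_percentages = as.list(twist$bin_percentages)),
    areas = list(
      full = list(contact_area_A2 = areas$full$contact_area,
                  contact_area_nm2 = areas$full$contact_area / 100,
                  mc_se_A2 = areas$full$mc_se,
                  frames_used = areas$full$frames_used),
      beta_sheet = list(contact_area_A2 = areas$beta_sheet$contact_area,
                        contact_area_nm2 = areas$beta_sheet$contact_area / 100,
                        mc_se_A2 = areas$beta_sheet$mc_se,
                        frames_used = areas$beta_sheet$frames_used)),
    contacts = list(peptide = profile$peptide,
                    mean_contacts = profile$mean_contacts,
                    sd_contacts = profile$sd_contacts),
    energies = list(
      full = list(coulomb = energies$full$coulomb, lj = energies$full$lj,
                  total = energies$full$total,
                  frames_used = energies$full$frames_used),
      beta_sheet = list(coulomb = energies$beta_sheet$coulomb,
                        lj = energies$beta_sheet$lj,
                        total = energies$beta_sheet$total,
                        frames_used = energies$beta_sheet$frames_used)),
    provenance = list(package_version = as.character(utils::packageVersion("fibnp")),
                      file_md5 = as.list(tools::md5sum(unname(files)))))
  names(report$provenance$file_md5) <- names(files)

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out <- list(twist = twist, areas = areas, profile = profile,
              energies = energies, report = report, out_dir = out_dir)
  class(out) <- "analysis_report"
  writeLines(summarize_report(out), file.path(out_dir, "summary.txt"))
  out
}

np_spec_from <- function(npcfg) {
  if (!is.null(npcfg$recipe))
    return(np_recipe(npcfg$recipe, core_diameter = npcfg$core_diameter,
                     au_bond_length = npcfg$au_bond_length,
                     rng_seed = npcfg$rng_seed))
  np_spec(core_diameter = npcfg$core_diameter,
          n_ligands = sum(unlist(npcfg$composition)),
          composition = unlist(npcfg$composition),
          placement = if (is.null(npcfg$placement)) "homogeneous" else npcfg$placement,
          au_bond_length = npcfg$au_bond_length, rng_seed = npcfg$rng_seed)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(summarize_report(x), sep = "\n")
  invisible(x)
}

#' Render an analysis report as a summary table
#'
#' One human-readable block per analysis: twist statistic and band
#' percentages (two decimals), contact areas in nm^2 (exactly A^2 / 100),
#' per-peptide contact extremes, and frame-averaged energies in kcal/mol.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @return Character vector of table lines.
#' @export
summarize_report <- function(report) {
  r <- report$report
  lines <- c("== fibnp pipeline summary ==", "")
  if (!is.null(r$twist)) {
    bp <- unlist(r$twist$bin_percentages)
    lines <- c(lines, "Twist angles:",
               sprintf("  theta_twist = %.4f deg  (m = %d pairs, %d frames, %d angles)",
                       r$twist$theta_twist, r$twist$m, r$twist$frames_used,
                       r$twist$n_angles),
               sprintf("  <10: %.2f%%   10-20: %.2f%%   >=20: %.2f%%",
                       bp[1], bp[2], bp[3]), "")
  }
  if (!is.null(r$areas)) {
    lines <- c(lines, "Contact areas (SASA difference):",
               sprintf("  vs full fibril : %8.2f A^2 = %7.4f nm^2 (%d frames)",
                       r$areas$full$contact_area_A2,
                       r$areas$full$contact_area_nm2,
                       r$areas$full$frames_used),
               sprintf("  vs beta-sheet  : %8.2f A^2 = %7.4f nm^2 (%d frames)",
                       r$areas$beta_sheet$contact_area_A2,
                       r$areas$beta_sheet$contact_area_nm2,
                       r$areas$beta_sheet$frames_used), "")
  }
  if (!is.null(r$contacts) && length(r$contacts$mean_contacts)) {
    mc <- unlist(r$contacts$mean_contacts)
    lines <- c(lines, "Heavy-atom contacts (per peptide, frame-averaged):",
               sprintf("  max %.1f (peptide %s), %d peptides with > 0 contacts",
                       max(mc), r$contacts$peptide[which.max(mc)],
                       sum(mc > 0)), "")
  }
  if (!is.null(r$energies)) {
    lines <- c(lines, "Interaction energies (kcal/mol):",
               sprintf("  vs full fibril : Coulomb %10.3f   LJ %10.3f   total %10.3f",
                       r$energies$full$coulomb, r$energies$full$lj,
                       r$energies$full$total),
               sprintf("  vs beta-sheet  : Coulomb %10.3f   LJ %10.3f   total %10.3f",
                       r$energies$beta_sheet$coulomb, r$energies$beta_sheet$lj,
                       r$energies$beta_sheet$total), "")
  }
  lines
}
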