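test_that("an isolated sphere gets exactly its probe-expanded area", {
  r <- compute_sasa(matrix(0, 1, 3), 1.7, params = nonbonded_params(rng_seed = 5))
  expect_equal(r$total_area, 4 * pi * 3.1^2, tolerance = 1e-12)
  expect_equal(r$mc_se, 0)
  expect_equal(r$total_area, sum(r$per_atom_area))
})

test_that("a fully buried atom scores zero area", {
  co <- rbind(c(0, 0, 0), c(0.2, 0, 0))
  r <- compute_sasa(co, c(1.0, 8.0), params = nonbonded_params(rng_seed = 5))
  expect_equal(r$per_atom_area[1], 0)
})

test_that("two fused spheres match the analytic cap formula", {
  co <- rbind(c(0, 0, 0), c(3, 0, 0))
  expct <- two_sphere_exposed_area(R = 1.7 + 1.4, d = 3)
  r500 <- compute_sasa(co, 1.7, params = nonbonded_params(sasa_points = 500,
                                                          rng_seed = 21))
  expect_lt(abs(r500$total_area - expct), 3 * r500$mc_se)
  r1e6 <- compute_sasa(co, 1.7, params = nonbonded_params(sasa_points = 1e6,
                                                          rng_seed = 21))
  expect_lt(abs(r1e6$total_area - expct) / expct, 0.002)
})

test_that("per-atom areas never exceed the sphere bound and match a dense reference", {
  m <- random_model(10, box = 8, seed = 3)
  m$atoms$radius <- runif(10, 1.4, 2.2)
  co <- model_coords(m)
  r <- compute_sasa(co, m$atoms$radius,
                    params = nonbonded_params(sasa_points = 500, rng_seed = 1))
  expect_true(all(r$per_atom_area <= 4 * pi * (m$atoms$radius + 1.4)^2 + 1e-9))
  ref <- compute_sasa(co, m$atoms$radius,
                      params = nonbonded_params(sasa_points = 2e5, rng_seed = 2))
  expect_lt(abs(r$total_area - ref$total_area), 3 * (r$mc_se + ref$mc_se))
})

test_that("replicate scatter is consistent with the binomial standard error", {
  # the accessible fraction of one atom is exactly Binomial(n, p)/n, so the
  # replicate variance must sit inside the chi-square band of that prediction
  co <- rbind(c(0, 0, 0), c(3, 0, 0))
  sph <- 4 * pi * 3.1^2
  p_hat <- vapply(1:50, function(s)
    compute_sasa(co, 1.7, params = nonbonded_params(sasa_points = 500,
                                                    rng_seed = s))$per_atom_area[1],
    0) / sph
  se2 <- mean(p_hat) * (1 - mean(p_hat)) / 500
  chi2 <- 49 * var(p_hat) / se2
  expect_gt(chi2, qchisq(0.005, df = 49))
  expect_lt(chi2, qchisq(0.995, df = 49))
  # and the reported total mc_se is the quadrature sum of the per-atom ses
  r <- compute_sasa(co, 1.7, params = nonbonded_params(sasa_points = 500,
                                                       rng_seed = 1))
  p1 <- r$per_atom_area / sph
  expect_equal(r$mc_se, sqrt(sum(sph^2 * p1 * (1 - p1) / 500)), tolerance = 1e-9)
})

test_that("SASA is exactly translation invariant and rotation invariant to MC error", {
  m <- random_model(8, box = 6, seed = 4)
  co <- model_coords(m); rad <- rep(1.8, 8)
  p <- nonbonded_params(rng_seed = 6)
  base <- compute_sasa(co, rad, params = p)
  shifted <- compute_sasa(sweep(co, 2, c(31, -12, 7), "+"), rad, params = p)
  expect_identical(base$total_area, shifted$total_area)
  rotated <- compute_sasa(co %*% t(rot_z_deg(34)), rad, params = p)
  expect_lt(abs(base$total_area - rotated$total_area),
            3 * (base$mc_se + rotated$mc_se) + 1e-9)
})

test_that("contact area vanishes for distant contexts and is monotone in the occluder set", {
  fib <- build_fibril(fibril_spec(n_peptides = 4))
  np <- build_nanoparticle(np_spec(core_diameter = 10, n_ligands = 8,
                                   composition = c("Pos-lig" = 8)))
  near <- combine_models(fib, translate_model(np, c(0, 28, 8)))
  np_idx <- near$components[[2]]; fib_idx <- near$components[[1]]
  tr <- synthesize_trajectory(near, 2, noise_sigma = 0.1, rng_seed = 2)
  p <- nonbonded_params(rng_seed = 3)

  far <- combine_models(fib, translate_model(np, c(0, 100, 0)))
  tr_far <- synthesize_trajectory(far, 2, noise_sigma = 0.1, rng_seed = 2)
  ca_far <- contact_area(tr_far, far$components[[2]], far$components[[1]],
                         params = p, last_n_frames = 2)
  expect_lt(abs(ca_far$contact_area), 3 * ca_far$mc_se + 1e-9)

  beta <- select_atoms(near, segid = c("FIB1", "FIB2"), resseq = 12:40)
  ca_full <- contact_area(tr, np_idx, fib_idx, params = p, last_n_frames = 2)
  ca_beta <- contact_area(tr, np_idx, beta, params = p, last_n_frames = 2)
  # same seed, same point sets: occluder-subset monotonicity is exact per frame
  expect_true(all(ca_full$per_frame$contact_area >=
                    ca_beta$per_frame$contact_area - 1e-9))
  expect_gte(ca_full$contact_area, ca_full$sasa_alone * 0 - 3 * ca_full$mc_se)
  expect_lte(ca_full$contact_area, ca_full$sasa_alone)
  expect_error(contact_area(tr, np_idx, np_idx, params = p, last_n_frames = 2),
               "overlap")
})

test_that("missing radii raise an explicit parameters-missing error", {
  expect_error(compute_sasa(matrix(0, 1, 3), NA_real_), "parameters missing")
  expect_error(compute_sasa(matrix(0, 1, 3), 1.7,
                            occ_coords = matrix(1, 1, 3), occ_radii = NA_real_),
               "parameters missing")
})

test_that("contact counting is exact against the brute-force double loop", {
  set.seed(8)
  at <- make_atoms(100, x = runif(100, 0, 20), y = runif(100, 0, 20),
                   z = runif(100, 0, 20))
  m <- structure_model(at)
  ga <- 1:50; gb <- 51:100
  co <- model_coords(m)
  expect_equal(count_contacts(m, ga, gb, cutoff = 5),
               naive_contacts(co[ga, ], co[gb, ], 5))
  # boundary inclusive at exactly the cutoff
  at2 <- make_atoms(2, x = c(0, 5))
  m2 <- structure_model(at2)
  expect_equal(count_contacts(m2, 1L, 2L, cutoff = 5), 1L)
  at3 <- make_atoms(2, x = c(0, 20))
  expect_equal(count_contacts(structure_model(at3), 1L, 2L, cutoff = 5), 0L)
  expect_error(count_contacts(m, 1:10, 5:20), "overlap")
  # hydrogen atoms are excluded from the counted group by default
  at4 <- make_atoms(3, x = c(0, 0.5, 4), element = c("H", "C", "C"))
  m4 <- structure_model(at4)
  expect_equal(count_contacts(m4, 1:2, 3L, cutoff = 5), 1L)
  expect_equal(count_contacts(m4, 1:2, 3L, cutoff = 5, heavy_only = FALSE), 2L)
})

test_that("binding profiles recover constructed contact counts", {
  # 30 heavy atoms placed 3 A from the probe group: well inside the 5 A shell
  set.seed(12)
  pep <- make_atoms(30, x = runif(30, -0.5, 0.5), y = runif(30, -0.5, 0.5),
                    z = 3, segid = "PEP")
  npx <- make_atoms(5, x = 0, y = 0, z = 0, segid = "NPX")
  m <- structure_model(rbind(pep, npx))
  m$atoms$atom_id <- seq_len(35)
  tr0 <- synthesize_trajectory(m, 4, noise_sigma = 0)
  prof <- binding_profile(tr0, list(pep = 1:30), 31:35, last_n_frames = 4)
  expect_equal(prof$mean_contacts, 30)
  expect_equal(prof$sd_contacts, 0)
  # gentle noise cannot carry atoms across the 2 A margin: mean unchanged
  trn <- synthesize_trajectory(m, 20, noise_sigma = 0.2, rng_seed = 5)
  profn <- binding_profile(trn, list(pep = 1:30), 31:35, last_n_frames = 20)
  expect_equal(profn$mean_contacts, 30)
  # distant peptide scores zero everywhere
  far <- structure_model(rbind(pep, make_atoms(5, x = 100, segid = "NPX")))
  trf <- synthesize_trajectory(far, 3, noise_sigma = 0.1, rng_seed = 1)
  proff <- binding_profile(trf, list(pep = 1:30), 31:35, last_n_frames = 3)
  expect_equal(proff$mean_contacts, 0)
  expect_error(binding_profile(tr0, list(), 31:35, last_n_frames = 4), "empty")
})
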