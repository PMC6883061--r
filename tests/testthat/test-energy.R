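two_charge_model <- function(r, q1 = 1, q2 = -1, eps = 0.1, rmin_half = 2) {
  at <- make_atoms(2, x = c(0, r), charge = c(q1, q2), epsilon = eps,
                   rmin_half = rmin_half, resseq = c(1L, 2L))
  structure_model(at)
}

test_that("Coulomb term reproduces the closed-form constant and dielectric scaling", {
  m <- two_charge_model(3.320636)
  e1 <- pair_energy(m, 1L, 2L, params = nonbonded_params(dielectric = 1))
  expect_equal(e1$coulomb, -100, tolerance = 1e-10)
  e78 <- pair_energy(m, 1L, 2L, params = nonbonded_params(dielectric = 78.5))
  expect_equal(e78$coulomb, e1$coulomb / 78.5, tolerance = 1e-14)  # 1/eps scaling
  expect_equal(e78$coulomb, -1.27389, tolerance = 1e-4)
  expect_equal(e1$total, e1$coulomb + e1$lj, tolerance = 1e-9)
})

test_that("LJ minimum equals -eps_ij at the combined rmin and vanishes past the cutoff", {
  m <- two_charge_model(4, q1 = 0, q2 = 0, eps = 0.1, rmin_half = 2)
  e <- pair_energy(m, 1L, 2L)
  expect_equal(e$lj, -0.1, tolerance = 1e-12)
  expect_equal(e$coulomb, 0)
  far <- two_charge_model(10.5, q1 = 0, q2 = 0)
  expect_equal(pair_energy(far, 1L, 2L)$lj, 0)
  # heterogeneous combining: eps_ij = sqrt(e_i e_j), rmin_ij = rh_i + rh_j
  at <- make_atoms(2, x = c(0, 3.7), charge = 0, epsilon = c(0.1, 0.4),
                   rmin_half = c(1.5, 2.2), resseq = 1:2)
  eh <- pair_energy(structure_model(at), 1L, 2L)
  expect_equal(eh$lj, -sqrt(0.1 * 0.4), tolerance = 1e-12)
})

test_that("Coulomb is linear in charges and symmetric under group swap; LJ charge-blind", {
  m <- random_model(40, seed = 10)
  ga <- 1:20; gb <- 21:40
  e <- pair_energy(m, ga, gb)
  m2 <- m; m2$atoms$charge[ga] <- 2 * m2$atoms$charge[ga]
  e2 <- pair_energy(m2, ga, gb)
  expect_equal(e2$coulomb, 2 * e$coulomb, tolerance = 1e-12)
  expect_identical(e2$lj, e$lj)
  esw <- pair_energy(m, gb, ga)
  expect_equal(esw$coulomb, e$coulomb, tolerance = 1e-9)
  expect_equal(esw$lj, e$lj, tolerance = 1e-9)
})

test_that("accelerated energies equal the naive double loop on random fixtures", {
  for (seed in 1:25) {
    m <- random_model(60, box = 18, seed = seed)
    ga <- 1:30; gb <- 31:60
    co <- model_coords(m)
    e <- pair_energy(m, ga, gb, params = nonbonded_params(dielectric = 1))
    expect_equal(e$coulomb,
                 naive_coulomb(co[ga, ], m$atoms$charge[ga],
                               co[gb, ], m$atoms$charge[gb]),
                 tolerance = 1e-10)
    expect_equal(e$lj,
                 naive_lj(co[ga, ], m$atoms$epsilon[ga], m$atoms$rmin_half[ga],
                          co[gb, ], m$atoms$epsilon[gb], m$atoms$rmin_half[gb]),
                 tolerance = 1e-10)
  }
})

test_that("per-residue decomposition conserves the totals", {
  m <- random_model(60, seed = 2)
  e <- pair_energy(m, 1:30, 31:60)
  per <- per_residue_decomposition(e)
  expect_lt(abs(sum(per$coulomb) - e$coulomb), 1e-6)
  expect_lt(abs(sum(per$lj) - e$lj), 1e-6)
  # single-residue group_b: decomposition is the total
  m1 <- two_charge_model(3)
  e1 <- pair_energy(m1, 1L, 2L)
  expect_equal(nrow(e1$per_residue), 1L)
  expect_equal(e1$per_residue$coulomb, e1$coulomb)
  # zero charges give exactly zero Coulomb rows
  mz <- random_model(20, seed = 3); mz$atoms$charge <- 0
  ez <- pair_energy(mz, 1:10, 11:20)
  expect_identical(unique(ez$per_residue$coulomb), 0)
})

test_that("trajectory averaging equals the single-frame value on constant frames", {
  m <- random_model(30, seed = 6)
  tr <- synthesize_trajectory(m, 5, noise_sigma = 0)
  et <- trajectory_energy(tr, 1:15, 16:30, last_n_frames = 5)
  e1 <- pair_energy(m, 1:15, 16:30)
  expect_equal(et$coulomb, e1$coulomb, tolerance = 1e-12)
  expect_equal(et$lj, e1$lj, tolerance = 1e-12)
  expect_equal(nrow(et$per_frame), 5L)
  expect_error(trajectory_energy(tr, 1:15, 16:30, last_n_frames = 10), "frames")
})

test_that("missing parameters and overlapping atoms raise explicit errors", {
  m <- two_charge_model(3)
  m$atoms$charge[2] <- NA
  expect_error(pair_energy(m, 1L, 2L), "parameters missing.*2")
  m2 <- two_charge_model(0)
  expect_error(pair_energy(m2, 1L, 2L), "overlapping atoms")
  expect_error(pair_energy(two_charge_model(3), 1L, 1L), "overlap")
})

test_that("potential grids obey the stated constant, linearity and symmetry", {
  at <- make_atoms(1, charge = 1)
  m <- structure_model(at)
  box <- list(min = c(14.3996, 0, 0), max = c(14.3996, 0, 0))
  g <- coulomb_grid(m, box = box, spacing = 1, params = nonbonded_params(dielectric = 1))
  expect_equal(g$values[1], 1, tolerance = 1e-12)
  g78 <- coulomb_grid(m, box = box, spacing = 1,
                      params = nonbonded_params(dielectric = 78.5))
  expect_equal(g78$values[1], 1 / 78.5, tolerance = 1e-12)

  dip <- structure_model(make_atoms(2, x = c(-2, 2), charge = c(1, -1),
                                    resseq = 1:2))
  gp <- coulomb_grid(dip, box = list(min = c(0, -5, -5), max = c(0, 5, 5)),
                     spacing = 1, params = nonbonded_params(dielectric = 1))
  expect_true(all(abs(gp$values) < 1e-9))     # bisector plane of the dipole
  dipf <- structure_model(make_atoms(2, x = c(-2, 2), charge = c(-1, 1),
                                     resseq = 1:2))
  g1 <- coulomb_grid(dip, box = list(min = c(5, 0, 0), max = c(8, 0, 0)),
                     spacing = 1, params = nonbonded_params(dielectric = 1))
  g2 <- coulomb_grid(dipf, box = list(min = c(5, 0, 0), max = c(8, 0, 0)),
                     spacing = 1, params = nonbonded_params(dielectric = 1))
  expect_equal(g2$values, -g1$values, tolerance = 1e-12)
  # masking near atom centers
  gm <- coulomb_grid(m, box = list(min = c(0, 0, 0), max = c(1, 0, 0)),
                     spacing = 1, params = nonbonded_params())
  expect_true(is.na(gm$values[1]) && !is.na(gm$values[2]))
})

test_that("a +90e nanoparticle attracts at the acidic face and repels at the Lys tip", {
  fib <- build_fibril(fibril_spec(imposed_twist = 0))
  np <- build_nanoparticle(np_recipe("Pos"))
  beta <- select_atoms(fib, resseq = 12:40)
  p <- nonbonded_params()

  face_center <- fibnp:::pose_center(fib, np, list(target = "beta_sheet", gap = 5))
  face <- combine_models(fib, translate_model(np, face_center))
  e_face <- pair_energy(face, face$components[[2]], beta, params = p)
  expect_lt(e_face$coulomb, 0)

  tip_center <- fibnp:::pose_center(fib, np, list(target = "tip", gap = 5))
  tip <- combine_models(fib, translate_model(np, tip_center))
  e_tip <- pair_energy(tip, tip$components[[2]], beta, params = p)
  expect_gt(e_tip$coulomb, 0)
})
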