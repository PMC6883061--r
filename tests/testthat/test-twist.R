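test_that("peptide vectors point from residue 32 toward residue 18", {
  at <- make_atoms(2, name = "CA", resseq = c(18L, 32L), chain = "A",
                   segid = "FIB1")
  at$x <- c(1, 0); at$y <- c(0, 0); at$z <- c(0, 0)
  m <- structure_model(at, peptides = data.frame(
    chain = "A", segid = "FIB1", first_res = 1L, last_res = 40L,
    protofilament = 1L, ordinal = 1L))
  expect_equal(peptide_vector(m, ordinal = 1), c(x = 1, y = 0, z = 0))
  expect_error(peptide_vector(m, ordinal = 1, from_residue = 19),
               "missing in peptide ordinal 1")
})

test_that("pair angles are unsigned, symmetric, clamped to [0, 180]", {
  expect_equal(pair_twist_angle(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(pair_twist_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(pair_twist_angle(c(1, 0, 0), c(-2, 0, 0)), 180)
  expect_equal(pair_twist_angle(c(1, 2, 3), c(-3, 1, 2)),
               pair_twist_angle(c(-3, 1, 2), c(1, 2, 3)))
  expect_error(pair_twist_angle(c(0, 0, 0), c(1, 0, 0)), "zero")
})

test_that("default selection uses 22 inner peptides, 21 pairs, pooling 10,500 angles", {
  fib <- build_fibril(fibril_spec(imposed_twist = 6.48, rng_seed = 4))
  tr <- synthesize_trajectory(fib, 500, noise_sigma = 0.2, rng_seed = 4)
  rep <- compute_twist_report(tr)
  expect_equal(rep$m, 21L)
  expect_equal(rep$frames_used, 500L)
  expect_equal(length(rep$pair_angles), 10500L)
  expect_equal(sum(rep$histogram$counts), 10500L)
  expect_equal(sum(rep$bin_percentages), 100, tolerance = 1e-9)
  # grand mean equals the mean of frame means (constant m)
  expect_equal(rep$theta_twist, mean(rep$frame_means), tolerance = 1e-12)
})

test_that("noiseless twist recovery is exact for 0, 3, 6.48 and 12 degrees", {
  for (theta in c(0, 3, 6.48, 12)) {
    fib <- build_fibril(fibril_spec(imposed_twist = theta))
    tr <- synthesize_trajectory(fib, 3, noise_sigma = 0)
    for (pf in 1:2) {
      rep <- compute_twist_report(tr, protofilament = pf, last_n_frames = 3)
      expect_equal(rep$theta_twist, theta, tolerance = 1e-6)
    }
  }
})

test_that("coordinate noise biases the twist statistic upward, more so at higher sigma", {
  thetas <- vapply(c(0, 0.1, 0.3), function(sig) {
    fib <- build_fibril(fibril_spec(imposed_twist = 6.48))
    tr <- synthesize_trajectory(fib, 500, noise_sigma = sig, rng_seed = 7)
    compute_twist_report(tr)$theta_twist
  }, 0)
  expect_equal(thetas[1], 6.48, tolerance = 1e-9)
  expect_true(all(diff(thetas) >= 0))
  expect_gt(thetas[3], thetas[1])
})

test_that("report is invariant under global rigid motion of every frame", {
  fib <- build_fibril(fibril_spec(n_peptides = 8, imposed_twist = 6.48))
  tr <- synthesize_trajectory(fib, 10, noise_sigma = 0.2, rng_seed = 3)
  base <- compute_twist_report(tr, inner_range = 2:7, last_n_frames = 10)
  R <- rot_z_deg(77.7) %*% matrix(c(1, 0, 0, 0, cos(0.4), -sin(0.4),
                                    0, sin(0.4), cos(0.4)), 3, 3, byrow = TRUE)
  shift <- c(12, -7, 33)
  xyz2 <- t(apply(tr$xyz, 1, function(row) {
    m <- matrix(row, ncol = 3, byrow = TRUE)
    as.vector(t(sweep(m %*% t(R), 2, shift, "+")))
  }))
  tr2 <- trajectory(fib, xyz2)
  moved <- compute_twist_report(tr2, inner_range = 2:7, last_n_frames = 10)
  expect_equal(moved$pair_angles, base$pair_angles, tolerance = 1e-9)
  expect_equal(moved$theta_twist, base$theta_twist, tolerance = 1e-9)
})

test_that("band percentages follow the half-open [0,10), [10,20), [20,180] convention", {
  expect_equal(unname(bin_percentages(c(5, 15, 25, 35))), c(25, 25, 50))
  expect_equal(unname(bin_percentages(rep(9.99, 7))), c(100, 0, 0))
  expect_equal(unname(bin_percentages(10))[2], 100)   # boundary goes up
  expect_equal(unname(bin_percentages(20))[3], 100)
  expect_equal(sum(bin_percentages(runif(1000, 0, 180))), 100, tolerance = 1e-9)
  expect_error(bin_percentages(numeric(0)), "empty")
})

test_that("constant angles collapse the report onto one bin", {
  fib <- build_fibril(fibril_spec(n_peptides = 8, imposed_twist = 12))
  tr <- synthesize_trajectory(fib, 4, noise_sigma = 0)
  rep <- compute_twist_report(tr, inner_range = 2:7, last_n_frames = 4)
  expect_equal(rep$theta_twist, 12, tolerance = 1e-9)
  expect_equal(unname(rep$bin_percentages), c(0, 100, 0))
  h <- rep$histogram
  expect_equal(h$counts[which(h$breaks == 12)], sum(h$counts))
})

test_that("out-of-range inner peptides error instead of clipping", {
  fib <- build_fibril(fibril_spec(n_peptides = 10))
  tr <- synthesize_trajectory(fib, 2)
  expect_error(compute_twist_report(tr, inner_range = 4:25, last_n_frames = 2),
               "exceeds")
  expect_error(compute_twist_report(tr, inner_range = c(2, 4), last_n_frames = 2),
               "consecutive")
})
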