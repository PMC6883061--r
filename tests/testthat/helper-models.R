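# Fixture constructors and independent brute-force oracles used across tests.

make_atoms <- function(n, x = 0, y = 0, z = 0, charge = 0, element = "C",
                       name = "CA", resseq = seq_len(n), chain = "A",
                       segid = "S", resname = "RES", epsilon = 0.1,
                       rmin_half = 2, radius = 1.7) {
  data.frame(atom_id = seq_len(n), name = rep_len(name, n),
             element = rep_len(element, n), resname = rep_len(resname, n),
             resseq = rep_len(resseq, n), chain = rep_len(chain, n),
             segid = rep_len(segid, n),
             x = rep_len(x, n), y = rep_len(y, n), z = rep_len(z, n),
             charge = rep_len(charge, n), epsilon = rep_len(epsilon, n),
             rmin_half = rep_len(rmin_half, n), radius = rep_len(radius, n),
             stringsAsFactors = FALSE)
}

# Random atom cloud with a physical minimum separation (2 A, roughly a vdW
# contact), so r^-12 terms stay in a numerically benign range.
random_model <- function(n, box = 20, seed = 1, min_sep = 2) {
  set.seed(seed)
  pts <- matrix(numeric(0), 0, 3)
  while (nrow(pts) < n) {
    cand <- matrix(runif(3 * n, 0, box), ncol = 3)
    for (k in seq_len(nrow(cand))) {
      if (nrow(pts) == n) break
      if (!nrow(pts) ||
          min(sqrt(rowSums(sweep(pts, 2, cand[k, ])^2))) >= min_sep)
        pts <- rbind(pts, cand[k, ])
    }
  }
  at <- make_atoms(n, x = pts[, 1], y = pts[, 2], z = pts[, 3],
                   charge = round(runif(n, -1, 1), 3),
                   resseq = sample(1:8, n, replace = TRUE))
  at$epsilon <- runif(n, 0.05, 0.3)
  at$rmin_half <- runif(n, 1.5, 2.5)
  structure_model(at)
}

# Independent O(n_a * n_b) oracles (plain double loops, no cell list).
naive_coulomb <- function(xa, qa, xb, qb, dielectric = 1, cutoff = NULL) {
  e <- 0
  for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb))) {
    r <- sqrt(sum((xa[i, ] - xb[j, ])^2))
    if (is.null(cutoff) || r <= cutoff)
      e <- e + 332.0636 * qa[i] * qb[j] / (dielectric * r)
  }
  e
}

naive_lj <- function(xa, ea, ra, xb, eb, rb, cutoff = 10) {
  e <- 0
  for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb))) {
    r <- sqrt(sum((xa[i, ] - xb[j, ])^2))
    if (r <= cutoff) {
      eps <- sqrt(ea[i] * eb[j]); rmin <- ra[i] + rb[j]
      e <- e + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
    }
  }
  e
}

naive_contacts <- function(xa, xb, cutoff = 5) {
  n <- 0L
  for (i in seq_len(nrow(xa))) {
    dmin <- Inf
    for (j in seq_len(nrow(xb)))
      dmin <- min(dmin, sqrt(sum((xa[i, ] - xb[j, ])^2)))
    if (dmin <= cutoff) n <- n + 1L
  }
  n
}

# Closed-form exposed area of two identical fused spheres of radius R (vdW +
# probe) with centers d apart: each loses a cap of height h = R - d/2.
two_sphere_exposed_area <- function(R, d) {
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

rot_z_deg <- function(theta) {
  t <- theta * pi / 180
  matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}
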