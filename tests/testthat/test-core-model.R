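test_that("minimal PDB and PQR records parse with correct fields", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.104   6.134  -6.504  1.00  0.00           C",
    "END"), pdb)
  m <- read_structure(pdb)
  expect_equal(n_atoms(m), 1L)
  expect_true(m$atoms$heavy[1])
  expect_equal(m$atoms$resseq[1], 1L)
  expect_equal(unname(model_coords(m)[1, ]), c(11.104, 6.134, -6.504))

  pqr <- tempfile(fileext = ".pqr")
  writeLines(c(
    "ATOM      1  OD1 ASP A   2      1.000   2.000   3.000 -1.0000  1.7000",
    "END"), pqr)
  mq <- read_structure(pqr)
  expect_equal(mq$atoms$charge[1], -1.0)
  expect_equal(mq$atoms$radius[1], 1.7)
})

test_that("malformed PDB raises a parse error naming the file", {
  bad <- tempfile(fileext = ".pdb")
  writeLines("this is not a pdb at all", bad)
  expect_error(read_structure(bad), "parse|failed")
  expect_error(read_structure("/nonexistent/file.pdb"), "not found")
})

test_that("fibril structures round-trip through PDB and PQR", {
  fib <- build_fibril(fibril_spec(n_peptides = 29, imposed_twist = 6.48))
  pdb <- tempfile(fileext = ".pdb")
  write_structure(fib, pdb)
  back <- read_structure(pdb)
  expect_equal(n_atoms(back), n_atoms(fib))
  expect_lt(max(abs(model_coords(back) - model_coords(fib))), 1e-3)
  expect_equal(back$atoms$resseq, fib$atoms$resseq)
  expect_equal(nrow(back$peptides), nrow(fib$peptides))
  expect_equal(back$role, "fibril")

  pqr <- tempfile(fileext = ".pqr")
  write_structure(fib, pqr)
  backq <- read_structure(pqr)
  expect_identical(backq$atoms$charge, fib$atoms$charge)  # integral charges: exact
  expect_equal(backq$atoms$radius, fib$atoms$radius)
  # read-write-read is the identity on the identity+coordinate columns
  pdb2 <- tempfile(fileext = ".pdb")
  write_structure(back, pdb2)
  expect_identical(substr(readLines(pdb), 1, 54), substr(readLines(pdb2), 1, 54))
})

test_that("writer emits TER per chain and END; empty model is END only", {
  fib <- build_fibril(fibril_spec(n_peptides = 2))
  f <- tempfile(fileext = ".pdb")
  write_structure(fib, f)
  lines <- readLines(f)
  expect_equal(sum(lines == "TER"), 4L)  # 2 peptides x 2 protofilaments
  expect_equal(tail(lines, 1), "END")
  # TER directly after the last atom of each chain
  expect_equal(which(lines == "TER")[1], 81L)

  empty <- structure_model(make_atoms(0))
  fe <- tempfile(fileext = ".pdb")
  write_structure(empty, fe)
  expect_equal(readLines(fe), "END")
})

test_that("selections filter by field, compose, and are idempotent", {
  at <- make_atoms(10, element = c(rep("C", 4), rep("H", 4), "N", "O"))
  m <- structure_model(at)
  heavies <- select_atoms(m, heavy = TRUE)
  expect_length(heavies, 6L)
  expect_identical(select_atoms(m, heavy = TRUE), heavies)

  fib <- build_fibril(fibril_spec(n_peptides = 2))
  beta <- select_atoms(fib, resseq = 12:40, chain = "A", segid = "FIB1")
  expect_equal(length(unique(fib$atoms$resseq[beta])), 29L)

  all_idx <- select_atoms(fib)
  expect_length(setdiff(seq_len(n_atoms(fib)), all_idx), 0L)
  # union / intersection / complement compose as plain index sets
  a <- select_atoms(fib, segid = "FIB1")
  b <- select_atoms(fib, resseq = 1)
  expect_setequal(intersect(a, b), select_atoms(fib, segid = "FIB1", resseq = 1))
  expect_error(select_atoms(fib, ligand_type = "Pos-lig"), "ligand_map")
})

test_that("LJ parameter table lookup uses residue/atom key with element fallback", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("residue\tatom\tepsilon\trmin_half",
               "ALA\tCA\t0.2\t2.1",
               "*\tC\t0.05\t1.9",
               "*\tN\t0.1\t1.8"), tsv)
  tbl <- read_lj_params(tsv)
  at <- make_atoms(3, name = c("CA", "CB", "NZ"), element = c("C", "C", "N"),
                   resname = c("ALA", "GLY", "LYS"), epsilon = NA_real_,
                   rmin_half = NA_real_)
  m <- apply_lj_params(structure_model(at), tbl)
  expect_equal(m$atoms$epsilon, c(0.2, 0.05, 0.1))    # direct, fallback, fallback
  expect_equal(m$atoms$rmin_half, c(2.1, 1.9, 1.8))

  at2 <- make_atoms(1, name = "XX", element = "ZZ", epsilon = NA_real_,
                    rmin_half = NA_real_)
  m2 <- apply_lj_params(structure_model(at2), tbl)
  expect_true(is.na(m2$atoms$epsilon))  # unmatched stays NA -> explicit error later
  m2$atoms$charge <- 0.5
  other <- structure_model(make_atoms(1, x = 3, charge = 1))
  expect_error(pair_energy(combine_models(m2, other), 1, 2), "parameters missing")
})

test_that("gold atoms must carry zero charge and invalid radii are rejected", {
  at <- make_atoms(1, element = "AU", charge = 0.1)
  expect_error(structure_model(at), "gold")
  at2 <- make_atoms(1, radius = -1)
  expect_error(structure_model(at2), "radius")
})
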