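# Synthetic-data generators: tetramer ensembles and DEER traces.

test_that("zero-variance generator is exact", {
  ens <- generate_ensemble(ensemble_spec(
    n_configs = 5, intra_mean = 2.0, intra_sd = 0, plane_angle_sd = 0,
    seed = 7))
  d <- pair_distances(ens, "intra_dimer")
  expect_length(d, 10)              # AB and CD in each of 5 configurations
  expect_true(all(abs(d - 2.0) < 1e-9))
  o <- orientation_distribution(ens, "intra_dimer")
  expect_true(all(abs(o$scalar_products - 1) < 1e-9))
})

test_that("Cuh stoichiometry has Cu on chains A and C only", {
  ens <- generate_ensemble(ensemble_spec(
    n_configs = 6, stoichiometry = "Cuh", seed = 8))
  for (cfg in ens$configurations) {
    expect_length(cfg$cu_sites, 2)
    expect_setequal(vapply(cfg$cu_sites, `[[`, "", "chain"), c("A", "C"))
  }
  expect_length(suppressMessages(pair_distances(ens, "intra_dimer")), 0)
  expect_length(suppressMessages(pair_distances(ens, "inter_dimer")), 6)
})

test_that("generated distance laws are recovered at n = 1000", {
  ens <- generate_ensemble(ensemble_spec(
    n_configs = 1000, intra_mean = 2.0, intra_sd = 0.2,
    inter_mean = 3.6, inter_sd = 0.9, seed = 31))
  intra <- pair_distances(ens, "intra_dimer")
  inter <- pair_distances(ens, "inter_dimer")
  expect_lt(abs(mean(intra) - 2.0), 3 * 0.2 / sqrt(length(intra)))
  expect_lt(abs(sd(intra) - 0.2), 3 * 0.2 / sqrt(2 * length(intra)))
  expect_lt(abs(mean(inter) - 3.6), 3 * 0.9 / sqrt(length(inter)))
})

test_that("infeasible distance laws are rejected with a diagnostic", {
  expect_error(ensemble_spec(intra_mean = 0.2), "infeasible geometry")
  expect_error(ensemble_spec(inter_mean = 12), "infeasible geometry")
})

test_that("fixed seed gives byte-identical PDB and trace files", {
  spec <- ensemble_spec(n_configs = 3, seed = 55)
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(generate_ensemble(spec), f1)
  write_ensemble_pdb(generate_ensemble(spec), f2)
  expect_identical(readLines(f1), readLines(f2))

  p <- gaussian_distribution(2.25, 0.2)
  acq <- deer_acquisition(seed = 12)
  t1 <- tempfile(); t2 <- tempfile()
  write_deer_trace(simulate_deer_trace(p, acq), t1)
  write_deer_trace(simulate_deer_trace(p, acq), t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("trace generator composes background, modulation and kernel", {
  p <- gaussian_distribution(2.25, 0.2)
  # lambda = 0: no oscillation, pure background + noise
  tr0 <- simulate_deer_trace(p, deer_acquisition(lambda = 0, k = 5e-4,
                                                 noise_sd = 0, seed = 1))
  tau <- tr0$t - tr0$t[1]
  expect_equal(tr0$v, exp(-5e-4 * tau), tolerance = 1e-12)
  # noise-free, k = 0, lambda = 1, delta distribution: V = K(tau, r0)
  r <- seq(1, 8, length.out = 201)
  delta <- distance_distribution(r, as.numeric(abs(r - 3) < 0.02))
  r0 <- r[which(abs(r - 3) < 0.02)]
  trd <- simulate_deer_trace(delta, deer_acquisition(lambda = 1, k = 0,
                                                     noise_sd = 0))
  expect_lt(max(abs(trd$v - powder_kernel(tau, r0))), 1e-9)
  # ground truth is carried along
  expect_equal(trd$ground_truth$lambda, 1)
})

test_that("acquisition defaults match the measurement grid", {
  acq <- deer_acquisition()
  expect_equal(acq$t0, 100)
  expect_equal(acq$dt, 10)
  expect_equal(acq$n_points, 200L)
  tr <- simulate_deer_trace(gaussian_distribution(2.25, 0.2), acq)
  expect_equal(tr$t[1], 100)
  expect_equal(max(tr$t), 100 + 10 * 199)
})

test_that("PDB round trip preserves models, sites and distances", {
  ens <- fixture_cub()
  f <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, f)
  back <- read_ensemble(f)
  expect_length(back$configurations, length(ens$configurations))
  expect_length(back$configurations[[1]]$cu_sites, 4)
  # coordinates are written at 3 decimals in Angstrom: 1e-3 nm accuracy
  expect_lt(max(abs(pair_distances(ens, "intra_dimer") -
                      pair_distances(back, "intra_dimer"))), 2e-4)
  # Angstrom-to-nm conversion on read
  cu1 <- ens$configurations[[1]]$cu_sites[[1]]$cu
  cu2 <- back$configurations[[1]]$cu_sites[[1]]$cu
  expect_equal(cu1, cu2, tolerance = 1e-3)
})

test_that("models with defective Cu sites are skipped with a warning", {
  ens <- generate_ensemble(ensemble_spec(n_configs = 5, seed = 77))
  f <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, f)
  lines <- readLines(f)
  # remove the NE2 (His13-role) ligand of the first Cu site of model 2
  m2 <- which(grepl("^MODEL", lines))[2]
  ne2 <- which(grepl("^HETATM.*NE2", lines) & seq_along(lines) > m2)[1]
  writeLines(lines[-ne2], f)
  expect_warning(back <- read_ensemble(f), "model 2 skipped")
  expect_length(back$configurations, 4)
})

test_that("independent PDB reader agrees on the written coordinates", {
  skip_if_not_installed("bio3d")
  ens <- fixture_cub()
  f <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, f)
  pdb <- bio3d::read.pdb(f, multi = TRUE, verbose = FALSE)
  sel <- bio3d::atom.select(pdb, elety = "CU", verbose = FALSE)
  cu_bio <- matrix(pdb$xyz[1, sel$xyz], ncol = 3, byrow = TRUE)
  cu_ours <- t(vapply(ens$configurations[[1]]$cu_sites,
                      function(s) s$cu, numeric(3))) * 10
  expect_equal(cu_bio, cu_ours, tolerance = 1e-3, ignore_attr = TRUE)
})
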