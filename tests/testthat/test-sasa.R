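# Shrake-Rupley surface areas and the SASA-ratio tetramer filter.

test_that("single sphere reproduces the closed-form area", {
  for (R in c(1.5, 3, 6)) {
    a <- sasa(matrix(0, 1, 3), R)
    expect_lt(abs(as.numeric(a) / (4 * pi * (R + 1.4)^2) - 1), 0.01)
  }
})

test_that("well-separated spheres are exactly additive", {
  xyz <- rbind(c(0, 0, 0), c(50, 0, 0))
  tot <- as.numeric(sasa(xyz, c(2, 3)))
  iso <- as.numeric(sasa(matrix(0, 1, 3), 2)) +
    as.numeric(sasa(matrix(0, 1, 3), 3))
  expect_lt(abs(tot - iso) / iso, 1e-9)
})

test_that("coincident identical spheres count one surface", {
  xyz <- rbind(c(0, 0, 0), c(0, 0, 0))
  tot <- as.numeric(sasa(xyz, c(2, 2)))
  one <- as.numeric(sasa(matrix(0, 1, 3), 2))
  expect_equal(tot, one, tolerance = 1e-9)
})

test_that("touching spheres bury surface monotonically on approach", {
  areas <- vapply(c(10, 6, 4, 3, 2, 1), function(d)
    as.numeric(sasa(rbind(c(0, 0, 0), c(d, 0, 0)), c(2, 2))), 0)
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("missing or invalid radii are reported by atom", {
  expect_error(sasa(matrix(0, 2, 3), 1), "one radius per atom")
  expect_error(sasa(rbind(c(0, 0, 0), c(5, 0, 0)), c(2, NA)), "atom")
})

test_that("tetramer filter accepts compact and rejects separated assemblies", {
  compact <- generate_ensemble(ensemble_spec(
    n_configs = 8, inter_mean = 3.0, inter_sd = 0.3, seed = 70))
  apart <- generate_ensemble(ensemble_spec(
    n_configs = 8, inter_mean = 3.0, inter_sd = 0.3, compactness = 0.2,
    seed = 71))
  fc <- filter_tetramers(compact)
  fa <- filter_tetramers(apart)
  expect_true(all(fc$assembled))
  expect_true(all(fc$ratio < 0.95))
  expect_true(all(!fa$assembled))
  expect_true(all(fa$ratio >= 0.99))
  # ratio never exceeds 1 by more than quadrature tolerance
  expect_true(all(c(fc$ratio, fa$ratio) <= 1 + 1e-9))
  expect_equal(attr(fc, "fraction"), 1)
})

test_that("the 0.95 boundary is strict", {
  # a fabricated result exactly at the threshold must be rejected;
  # exercised through the threshold argument on a real configuration
  cfg <- generate_ensemble(ensemble_spec(n_configs = 1, seed = 72))$configurations[[1]]
  res <- tetramer_filter(cfg)
  ratio <- attr(res, "ratio")
  at_boundary <- tetramer_filter(cfg, threshold = ratio)
  expect_false(as.logical(at_boundary))   # ratio < ratio is FALSE
})

test_that("ratio decreases as the dimers are brought into contact", {
  base <- generate_ensemble(ensemble_spec(n_configs = 1, inter_mean = 3.0,
                                          inter_sd = 0.1, seed = 73))
  cfg <- base$configurations[[1]]
  # translate chains C and D outward along the dimer-centre axis
  c_ab <- colMeans(rbind(cfg$chains$A, cfg$chains$B))
  c_cd <- colMeans(rbind(cfg$chains$C, cfg$chains$D))
  axis <- (c_cd - c_ab) / sqrt(sum((c_cd - c_ab)^2))
  ratios <- vapply(c(0, 1, 2.5, 6), function(extra) {
    shifted <- cfg
    for (ch in c("C", "D"))
      shifted$chains[[ch]] <- cfg$chains[[ch]] + rep(axis * extra, each = nrow(cfg$chains[[ch]]))
    shifted$cu_sites <- lapply(cfg$cu_sites, function(s) {
      if (s$chain %in% c("C", "D")) {
        s$cu <- s$cu + axis * extra
        s$n_his6 <- s$n_his6 + axis * extra
        s$n_his13 <- s$n_his13 + axis * extra
      }
      s
    })
    attr(tetramer_filter(shifted), "ratio")
  }, 0)
  expect_true(all(diff(ratios) >= -1e-9))   # ratio grows with separation
  expect_lt(ratios[1], 0.95)
  expect_gt(ratios[4], 0.99)
})
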