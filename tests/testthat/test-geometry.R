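# Pair-class distances, coordination normals, orientation statistics, Rg.

test_that("pair classes partition all Cu pairs exactly once", {
  ens <- fixture_cub()
  n_cfg <- length(ens$configurations)
  intra <- pair_distances(ens, "intra_dimer")
  inter <- pair_distances(ens, "inter_dimer")
  # 4 Cu sites: C(4,2) = 6 pairs = 2 intra + 4 inter per configuration
  expect_length(intra, 2 * n_cfg)
  expect_length(inter, 4 * n_cfg)
})

test_that("pair distances are invariant under rigid motions", {
  ens <- fixture_cub()
  set.seed(20)
  moved <- ens
  moved$configurations <- lapply(ens$configurations, function(cfg)
    transform_config(cfg, random_rotation(), runif(3, -5, 5)))
  expect_equal(pair_distances(moved, "intra_dimer"),
               pair_distances(ens, "intra_dimer"), tolerance = 1e-10)
  expect_equal(pair_distances(moved, "inter_dimer"),
               pair_distances(ens, "inter_dimer"), tolerance = 1e-10)
})

test_that("pair restriction and empty classes behave as documented", {
  ens <- fixture_cub()
  ab <- pair_distances(ens, "intra_dimer", pairs = "AB")
  expect_length(ab, length(ens$configurations))
  ench <- generate_ensemble(ensemble_spec(n_configs = 4,
                                          stoichiometry = "Cuh", seed = 2))
  expect_message(d <- pair_distances(ench, "intra_dimer"), "no intra-dimer")
  expect_length(d, 0)
})

test_that("distance summaries match hand computation", {
  s <- summarize_distances(c(1, 2, 3))
  expect_equal(unname(s["mean"]), 2)
  expect_equal(unname(s["sd"]), sqrt(2 / 3))   # population sd
  expect_equal(unname(summarize_distances(rep(1.4, 5))["sd"]), 0)
  expect_error(summarize_distances(2.2), "at least two")
})

test_that("distance histograms integrate to one regardless of sample size", {
  set.seed(30)
  h1 <- distance_histogram(rnorm(100, 3.6, 0.9))
  h2 <- distance_histogram(rnorm(10000, 3.6, 0.9))
  expect_equal(oligodeer:::trapz_(h1$r, h1$p), 1, tolerance = 1e-9)
  expect_equal(oligodeer:::trapz_(h2$r, h2$p), 1, tolerance = 1e-9)
  # single repeated value: one occupied bin of height 1/bin_width
  h3 <- distance_histogram(rep(2.0, 7), bin_width = 0.1)
  expect_equal(max(h3$p), 10, tolerance = 1e-9)
  expect_equal(sum(h3$p > 0), 1)
  expect_error(distance_histogram(numeric(0)), "no distances")
})

test_that("coordination normal follows the right-hand convention", {
  site <- list(cu = c(0, 0, 0), n_his6 = c(1, 0, 0), n_his13 = c(0, 1, 0))
  expect_equal(coordination_normal(site), c(0, 0, 1))
  # swapping ligand roles negates the normal
  swapped <- list(cu = site$cu, n_his6 = site$n_his13, n_his13 = site$n_his6)
  expect_equal(coordination_normal(swapped), -coordination_normal(site))
  # collinear bonds are rejected
  bad <- list(cu = c(0, 0, 0), n_his6 = c(1, 0, 0), n_his13 = c(2, 0, 0))
  expect_error(coordination_normal(bad), "collinear")
})

test_that("coordination normal is rotation-equivariant", {
  set.seed(40)
  for (i in 1:20) {
    site <- list(cu = runif(3), n_his6 = runif(3), n_his13 = runif(3))
    n0 <- coordination_normal(site)
    R <- random_rotation(); tr <- runif(3, -2, 2)
    moved <- list(cu = as.vector(R %*% site$cu) + tr,
                  n_his6 = as.vector(R %*% site$n_his6) + tr,
                  n_his13 = as.vector(R %*% site$n_his13) + tr)
    expect_equal(coordination_normal(moved), as.vector(R %*% n0),
                 tolerance = 1e-9)
  }
})

test_that("orientation statistics recover the generator's angular spread", {
  ens <- generate_ensemble(ensemble_spec(n_configs = 1000,
                                         plane_angle_sd = 20, seed = 50))
  o <- orientation_distribution(ens, "intra_dimer")
  expect_true(all(abs(o$scalar_products) <= 1))
  expect_lt(abs(o$angle_sd_deg - 20), 2)
  # inter-dimer planes are uncorrelated: scalar products spread over [-1, 1]
  oi <- orientation_distribution(ens, "inter_dimer")
  expect_lt(abs(mean(oi$scalar_products)), 0.1)
  expect_gt(sd(oi$scalar_products), 0.4)
})

test_that("antiparallel normals give scalar product -1", {
  cfg <- list(chains = list(), radii = numeric(0),
              cu_sites = list(
                list(chain = "A", cu = c(0, 0, 0),
                     n_his6 = c(0.2, 0, 0), n_his13 = c(0, 0.2, 0)),
                list(chain = "B", cu = c(2, 0, 0),
                     n_his6 = c(2, 0.2, 0), n_his13 = c(2.2, 0, 0))))
  ens <- structure(list(configurations = list(cfg), stoichiometry = "Cub",
                        spec = NULL), class = "oligomer_ensemble")
  o <- orientation_distribution(ens, "intra_dimer")
  expect_equal(o$scalar_products, -1, tolerance = 1e-12)
})

test_that("generated normals are unit and orthogonal to the ligand plane", {
  ens <- fixture_cub()
  for (cfg in ens$configurations[1:5]) for (s in cfg$cu_sites) {
    n <- coordination_normal(s)
    expect_equal(sqrt(sum(n^2)), 1, tolerance = 1e-12)
    expect_lt(abs(sum(n * (s$n_his6 - s$cu))), 1e-12)
    expect_lt(abs(sum(n * (s$n_his13 - s$cu))), 1e-12)
  }
})

test_that("radius of gyration has its closed forms and invariances", {
  two <- list(chains = list(A = rbind(c(0, 0, 0), c(1, 0, 0))))
  expect_equal(radius_of_gyration(two, "A"), 0.5)
  # rigid translation leaves Rg unchanged
  ens <- fixture_cub()
  cfg <- ens$configurations[[1]]
  moved <- cfg
  moved$chains <- lapply(cfg$chains, function(m) m + rep(c(3, -2, 7), each = nrow(m)))
  expect_equal(radius_of_gyration(moved), radius_of_gyration(cfg),
               tolerance = 1e-12)
  # uniform points on a sphere of radius R have Rg = R
  set.seed(60)
  z <- 2 * runif(4000) - 1; phi <- 2 * pi * runif(4000)
  sph <- 2.5 * cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
  onsph <- list(chains = list(A = sph))
  expect_equal(radius_of_gyration(onsph, "A"), 2.5, tolerance = 0.01)
  expect_error(radius_of_gyration(list(chains = list(A = sph[1, , drop = FALSE])), "A"),
               "at least two")
})
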