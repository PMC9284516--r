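# Independent oracles and fixture builders shared across tests.

# Monte-Carlo orientation average of the dipolar oscillation: mean of
# cos(2 pi nu(r, theta) t) over orientations uniform on the sphere,
# stratified in cos(theta) for variance reduction. Independent of the
# package's Fresnel/quadrature kernels.
mc_kernel <- function(t_ns, r_nm, n = 1e6L, stratified = TRUE) {
  u <- if (stratified) (seq_len(n) - runif(n)) / n else runif(n)
  nu <- DIPOLAR_NU0 / r_nm^3 * (1 - 3 * u^2)   # MHz
  vapply(t_ns, function(tt) mean(cos(2 * pi * nu * tt * 1e-3)), 0)
}

# Exhaustive active-set solution of min ||Ax-b||^2 + alpha^2||Lx||^2, x >= 0
# on a small grid: enumerates all 2^n passive sets, keeps the KKT point.
brute_force_tikhonov <- function(F, tau, r, alpha) {
  n <- length(r)
  stopifnot(n <= 12)
  K <- oligodeer:::deer_kernel_matrix(tau, r)
  L <- oligodeer:::second_derivative_operator(n)
  AtA <- crossprod(K) + alpha^2 * crossprod(L)
  Atb <- as.vector(crossprod(K, F))
  best <- NULL
  bestobj <- Inf
  for (mask in 0:(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    x <- numeric(n)
    if (length(S)) {
      xs <- tryCatch(solve(AtA[S, S, drop = FALSE], Atb[S]),
                     error = function(e) NULL)
      if (is.null(xs) || any(xs < 0)) next
      x[S] <- xs
    }
    w <- Atb - as.vector(AtA %*% x)
    if (any(w[setdiff(seq_len(n), S)] > 1e-8)) next
    obj <- 0.5 * sum(x * (AtA %*% x)) - sum(Atb * x)
    if (obj < bestobj) { bestobj <- obj; best <- x }
  }
  best
}

# Random 3-D rotation matrix (uniform axis, uniform angle).
random_rotation <- function() {
  z <- 2 * runif(1) - 1; phi <- 2 * pi * runif(1)
  k <- c(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
  th <- 2 * pi * runif(1)
  ct <- cos(th); st <- sin(th)
  Kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) * ct + st * Kx + (1 - ct) * outer(k, k)
}

# Apply a rigid motion (rotation R, translation tr) to one configuration.
transform_config <- function(config, R, tr) {
  config$chains <- lapply(config$chains, function(m)
    m %*% t(R) + rep(tr, each = nrow(m)))
  config$cu_sites <- lapply(config$cu_sites, function(s) {
    s$cu <- as.vector(R %*% s$cu) + tr
    s$n_his6 <- as.vector(R %*% s$n_his6) + tr
    s$n_his13 <- as.vector(R %*% s$n_his13) + tr
    s
  })
  config
}

# Small ensembles reused by several test files (cached per session).
fixture_env <- new.env(parent = emptyenv())

fixture_cub <- function() {
  if (is.null(fixture_env$cub))
    fixture_env$cub <- generate_ensemble(
      ensemble_spec(n_configs = 20, seed = 101))
  fixture_env$cub
}
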