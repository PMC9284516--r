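# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. `seed = NULL` leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Trapezoid quadrature on an arbitrary strictly increasing grid.
trapz_ <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Trapezoid weights w such that sum(w * y) == trapz_(x, y).
trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2L) stop("grid needs at least two points")
  h <- diff(x)
  w <- numeric(n)
  w[1] <- h[1] / 2
  w[n] <- h[n - 1] / 2
  if (n > 2L) w[2:(n - 1)] <- (h[-1] + h[-(n - 1)]) / 2
  w
}

# Truncated-normal draws, lower bound only (rejection; exact for sd = 0).
rnorm_trunc <- function(n, mean, sd, lower) {
  if (sd == 0) {
    if (mean < lower) stop("degenerate law entirely below truncation bound")
    return(rep(mean, n))
  }
  x <- rnorm(n, mean, sd)
  bad <- x < lower
  guard <- 0L
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x < lower
    guard <- guard + 1L
    if (guard > 10000L) stop("truncated-normal rejection failed to terminate")
  }
  x
}

# Normalize rows of a matrix of 3-vectors to unit length.
unit_rows <- function(m) {
  m / sqrt(rowSums(m^2))
}

# Uniform random unit vectors (n x 3).
runif_sphere <- function(n) {
  z <- 2 * runif(n) - 1
  phi <- 2 * pi * runif(n)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

# Rodrigues rotation of row vectors `v` about unit axis `k` by angle `theta`.
rotate_about <- function(v, k, theta) {
  k <- k / sqrt(sum(k^2))
  ct <- cos(theta); st <- sin(theta)
  kv <- v %*% k            # component along axis
  cross <- cbind(k[2] * v[, 3] - k[3] * v[, 2],
                 k[3] * v[, 1] - k[1] * v[, 3],
                 k[1] * v[, 2] - k[2] * v[, 1])
  v * ct + cross * st + outer(as.vector(kv), k) * (1 - ct)
}

# An arbitrary unit vector perpendicular to unit vector `u`.
perp_vector <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- ref - sum(ref * u) * u
  p / sqrt(sum(p^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
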