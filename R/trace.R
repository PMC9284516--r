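# DEER traces: sampled dipolar evolution signal vs pump-pulse delay,
# plus the synthetic trace generator used for round-trip validation.

#' DEER acquisition grid and instrument parameters
#'
#' Describes the sampling of a four-pulse DEER measurement. The defaults
#' reproduce the acquisition used for the Cu-labelled oligomer samples:
#' initial delay 100 ns, 10 ns increments, 200 points.
#'
#' @param t0 initial pump-pulse delay, ns.
#' @param dt increment step, ns.
#' @param n_points number of increments.
#' @param lambda modulation depth, fraction in (0, 1).
#' @param k background decay rate, per ns.
#' @param noise_sd additive Gaussian noise standard deviation as a fraction
#'   of the echo amplitude at zero evolution time.
#' @param seed integer seed for the noise draw (`NULL` = use current RNG).
#' @return an object of class `deer_acquisition`.
#' @export
deer_acquisition <- function(t0 = 100, dt = 10, n_points = 200,
                             lambda = 0.3, k = 5e-4, noise_sd = 0.01,
                             seed = NULL) {
  stopifnot(t0 >= 0, dt > 0, n_points >= 2,
            lambda >= 0, lambda <= 1, k >= 0, noise_sd >= 0)
  structure(list(t0 = t0, dt = dt, n_points = as.integer(n_points),
                 lambda = lambda, k = k, noise_sd = noise_sd, seed = seed),
            class = "deer_acquisition")
}

#' DEER trace
#'
#' A sampled echo-intensity trace on a uniform delay-time grid. The dipolar
#' evolution time is measured from the first sample (no zero-time
#' refinement), so `v[1]` is approximately 1 for a normalized trace.
#'
#' @param t delay times, ns, strictly increasing.
#' @param v echo intensities (dimensionless).
#' @param ground_truth optional list recording the generating distribution
#'   and parameters of a synthetic trace.
#' @return an object of class `deer_trace`.
#' @export
deer_trace <- function(t, v, ground_truth = NULL) {
  t <- as.numeric(t); v <- as.numeric(v)
  if (length(t) != length(v)) stop("`t` and `v` must have equal length")
  if (length(t) < 2L) stop("a trace needs at least two points")
  if (any(diff(t) <= 0)) stop("`t` must be strictly increasing")
  if (any(!is.finite(v))) stop("`v` must be finite")
  structure(list(t = t, v = v, ground_truth = ground_truth),
            class = "deer_trace")
}

# Evolution time measured from the first sample.
trace_tau <- function(trace) trace$t - trace$t[1]

#' Simulate a DEER trace from a known distance distribution
#'
#' Forward-simulates \eqn{V(t) = B(t)\,(1 - \lambda + \lambda F(t))} on the
#' acquisition grid, with exponential background, powder-kernel form factor
#' and additive Gaussian noise. The generating distribution and parameters
#' are stored in the `ground_truth` field so inversions can be validated
#' against them.
#'
#' @param p a [distance_distribution] (the ground truth).
#' @param acq a [deer_acquisition]; its `seed` fixes the noise draw.
#' @return a [deer_trace] with `ground_truth` attached.
#' @examples
#' p <- gaussian_distribution(2.25, 0.2)
#' tr <- simulate_deer_trace(p, deer_acquisition(noise_sd = 0.01, seed = 1))
#' @export
simulate_deer_trace <- function(p, acq = deer_acquisition()) {
  p <- as_distance_distribution(p)
  stopifnot(inherits(acq, "deer_acquisition"))
  t <- acq$t0 + acq$dt * (seq_len(acq$n_points) - 1L)
  tau <- t - t[1]
  f <- form_factor(p, tau, lambda = acq$lambda)
  v <- deer_background(tau, acq$k) * f
  noise <- with_seed(acq$seed, rnorm(length(v), 0, acq$noise_sd))
  deer_trace(t, v + noise,
             ground_truth = list(p = p, lambda = acq$lambda, k = acq$k,
                                 noise_sd = acq$noise_sd, seed = acq$seed))
}

#' @export
print.deer_trace <- function(x, ...) {
  cat(sprintf("DEER trace: %d points, t = %.0f..%.0f ns (dt = %.3g ns)\n",
              length(x$t), min(x$t), max(x$t), mean(diff(x$t))))
  if (!is.null(x$ground_truth))
    cat(sprintf("  synthetic: lambda = %.3g, k = %.3g /ns, noise = %.3g\n",
                x$ground_truth$lambda, x$ground_truth$k, x$ground_truth$noise_sd))
  invisible(x)
}

#' @export
plot.deer_trace <- function(x, ..., xlab = "t (ns)", ylab = "V(t)") {
  plot(x$t, x$v, type = "l", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Read and write DEER traces as two-column ASCII
#'
#' Format: optional comment lines prefixed `#` (`# key: value` pairs are
#' parsed into numeric metadata), then two whitespace-separated columns,
#' delay time in ns and echo intensity.
#'
#' @param trace a [deer_trace].
#' @param file path.
#' @param header named vector of extra `# key: value` lines; ground-truth
#'   parameters of synthetic traces are written automatically.
#' @return `read_deer_trace` returns a [deer_trace] (parsed metadata in
#'   attribute `"metadata"`); `write_deer_trace` returns `file` invisibly.
#' @export
write_deer_trace <- function(trace, file, header = NULL) {
  stopifnot(inherits(trace, "deer_trace"))
  meta <- header
  gt <- trace$ground_truth
  if (!is.null(gt))
    meta <- c(meta, lambda = gt$lambda, k = gt$k, noise_sd = gt$noise_sd,
              seed = gt$seed %||% NA)
  lines <- character(0)
  if (!is.null(meta))
    lines <- sprintf("# %s: %s", names(meta), as.character(meta))
  lines <- c(lines, sprintf("%.10g %.10g", trace$t, trace$v))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_deer_trace
#' @export
read_deer_trace <- function(file) {
  raw <- readLines(file)
  com <- grepl("^\\s*#", raw)
  meta <- list()
  kv <- regmatches(raw[com], regexec("^\\s*#\\s*([^:]+):\\s*(.+)$", raw[com]))
  for (m in kv) if (length(m) == 3L) {
    val <- suppressWarnings(as.numeric(m[3]))
    meta[[trimws(m[2])]] <- if (is.na(val)) trimws(m[3]) else val
  }
  tab <- read.table(text = raw[!com], col.names = c("t", "v"))
  structure(deer_trace(tab$t, tab$v), metadata = meta)
}
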