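# Distance distributions: probability densities over an interspin
# distance grid (nm), normalized to unit trapezoid integral.

#' Distance distribution
#'
#' Construct a probability density over an interspin distance grid.
#' The density is non-negative and renormalized to unit trapezoid integral
#' unless `normalize = FALSE`.
#'
#' @param r strictly increasing distance grid, nm.
#' @param p non-negative density values per nm.
#' @param normalize rescale to unit integral (default `TRUE`).
#' @return an object of class `distance_distribution` with fields `r`, `p`.
#' @examples
#' r <- seq(1, 8, length.out = 201)
#' dd <- distance_distribution(r, dnorm(r, 2.25, 0.2))
#' distribution_mode(dd)
#' @export
distance_distribution <- function(r, p, normalize = TRUE) {
  r <- as.numeric(r); p <- as.numeric(p)
  if (length(r) != length(p)) stop("`r` and `p` must have equal length")
  if (length(r) < 2L) stop("distance grid needs at least two points")
  if (any(diff(r) <= 0)) stop("`r` must be strictly increasing")
  if (any(!is.finite(p)) || any(p < -1e-12)) stop("`p` must be finite and non-negative")
  p <- pmax(p, 0)
  if (normalize) {
    z <- trapz_(r, p)
    if (z <= 0) stop("density integrates to zero; cannot normalize")
    p <- p / z
  }
  structure(list(r = r, p = p), class = "distance_distribution")
}

as_distance_distribution <- function(x) {
  if (inherits(x, "distance_distribution")) return(x)
  if (is.list(x) && all(c("r", "p") %in% names(x)))
    return(distance_distribution(x$r, x$p, normalize = FALSE))
  stop("cannot interpret input as a distance distribution")
}

#' Gaussian and Gaussian-mixture distance distributions
#'
#' Convenience constructor discretizing a (mixture of) normal laws on a
#' distance grid, truncated to the grid and renormalized.
#'
#' @param mean,sd component means and standard deviations, nm.
#' @param weight mixture weights (recycled, renormalized).
#' @param r distance grid, nm; default 201 points on 1-8 nm, the DEER
#'   sensitivity window.
#' @return a [distance_distribution].
#' @export
gaussian_distribution <- function(mean, sd, weight = 1,
                                  r = seq(1, 8, length.out = 201)) {
  stopifnot(length(mean) == length(sd), all(sd >= 0))
  weight <- rep_len(weight, length(mean))
  weight <- weight / sum(weight)
  p <- numeric(length(r))
  for (i in seq_along(mean)) {
    p <- p + weight[i] * if (sd[i] == 0) {
      d <- numeric(length(r)); d[which.min(abs(r - mean[i]))] <- 1; d
    } else dnorm(r, mean[i], sd[i])
  }
  distance_distribution(r, p)
}

#' Mode of a distance distribution
#'
#' Distance at the global maximum of the density. Ties are broken toward
#' the smallest distance; the grid spacing is attached as the resolution.
#'
#' @param p a [distance_distribution].
#' @return mode in nm, with attribute `"resolution"` (grid spacing, nm).
#' @export
distribution_mode <- function(p) {
  p <- as_distance_distribution(p)
  if (diff(range(p$p)) == 0)
    stop("density is flat; mode undefined")
  i <- which.max(p$p)   # which.max returns the first (smallest-r) maximum
  structure(p$r[i], resolution = mean(diff(p$r)))
}

#' Local maxima of a distance distribution
#'
#' Finds interior local maxima with height at least `min_height` times the
#' global maximum and mutual separation at least `min_separation`; used to
#' flag multimodal inversions. Peaks at the grid edges are included.
#'
#' @param p a [distance_distribution].
#' @param min_height minimum relative peak height (default 0.2).
#' @param min_separation minimum peak separation in nm (default 0.3).
#' @return numeric vector of peak positions (nm), decreasing height order.
#' @export
distribution_peaks <- function(p, min_height = 0.2, min_separation = 0.3) {
  p <- as_distance_distribution(p)
  y <- p$p; n <- length(y)
  if (diff(range(y)) == 0) return(numeric(0))
  left <- c(-Inf, y[-n]); right <- c(y[-1], -Inf)
  cand <- which(y >= left & y > right | (y > left & y >= right))
  cand <- cand[y[cand] >= min_height * max(y)]
  cand <- cand[order(-y[cand])]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(p$r[i] - p$r[keep]) >= min_separation))
      keep <- c(keep, i)
  }
  p$r[keep]
}

#' Overlap coefficient between two distance distributions
#'
#' \eqn{\int \min(p_1, p_2)\, dr} on a common grid (the first grid;
#' the second density is linearly interpolated). Equals 1 for identical
#' normalized densities and 0 for disjoint supports.
#'
#' @param p1,p2 [distance_distribution] objects.
#' @return overlap coefficient in `[0, 1]`.
#' @export
overlap_coefficient <- function(p1, p2) {
  p1 <- as_distance_distribution(p1); p2 <- as_distance_distribution(p2)
  y2 <- approx(p2$r, p2$p, xout = p1$r, yleft = 0, yright = 0)$y
  trapz_(p1$r, pmin(p1$p, y2))
}

#' Normalized histogram of a distance sample
#'
#' Bins a sample of distances and rescales the histogram to unit trapezoid
#' integral, so curves from samples of different size are directly
#' comparable.
#'
#' @param distances sample of distances, nm (at least one value).
#' @param bin_width bin width in nm (default 0.1).
#' @param range optional `c(lo, hi)` range; default spans the data padded
#'   by one bin.
#' @return a [distance_distribution] evaluated at bin centres.
#' @export
distance_histogram <- function(distances, bin_width = 0.1, range = NULL) {
  distances <- as.numeric(distances)
  if (!length(distances)) stop("no distances supplied")
  if (!is.numeric(bin_width) || bin_width <= 0) stop("`bin_width` must be positive")
  if (is.null(range))
    range <- c(min(distances) - bin_width, max(distances) + bin_width)
  breaks <- seq(range[1], range[2] + bin_width, by = bin_width)
  cnt <- tabulate(findInterval(distances, breaks, rightmost.closed = TRUE),
                  nbins = length(breaks) - 1L)
  centres <- breaks[-length(breaks)] + bin_width / 2
  dens <- cnt / (sum(cnt) * bin_width)
  distance_distribution(centres, dens)
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("Distance distribution: %d points on [%.3g, %.3g] nm\n",
              length(x$r), min(x$r), max(x$r)))
  cat(sprintf("  integral %.6f, mode %.3f nm\n",
              trapz_(x$r, x$p), tryCatch(as.numeric(distribution_mode(x)),
                                         error = function(e) NA_real_)))
  invisible(x)
}

#' @export
plot.distance_distribution <- function(x, ..., xlab = "r (nm)",
                                       ylab = "P(r) (1/nm)", type = "l") {
  plot(x$r, x$p, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Write / read a distance distribution as a two-column table
#'
#' Plain-text format: comment lines prefixed `#`, then two whitespace
#' separated columns (distance nm, density per nm).
#'
#' @param p a [distance_distribution].
#' @param file path.
#' @param header named character or numeric vector written as `# key: value`.
#' @return `write_distribution` returns `file` invisibly;
#'   `read_distribution` returns a [distance_distribution].
#' @export
write_distribution <- function(p, file, header = NULL) {
  p <- as_distance_distribution(p)
  lines <- character(0)
  if (!is.null(header))
    lines <- sprintf("# %s: %s", names(header), as.character(header))
  lines <- c(lines, sprintf("%.8g %.8g", p$r, p$p))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(file) {
  tab <- read.table(file, comment.char = "#", col.names = c("r", "p"))
  distance_distribution(tab$r, tab$p, normalize = FALSE)
}
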