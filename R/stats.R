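# Statistical comparison of distance samples and selection of
# representative configurations.

#' Compare two Cu-Cu distance samples
#'
#' Two-sample test of whether the pair-class distance distributions of two
#' ensembles differ. Default is the two-sided Mann-Whitney rank test;
#' the Kolmogorov-Smirnov test is available as an alternative. An optional
#' subsampling stride thins each sample (every `stride`-th value) to
#' mitigate serial correlation among configurations.
#'
#' @param d1,d2 distance samples, nm, at least 10 values each.
#' @param method `"wilcoxon"` (Mann-Whitney U, default) or `"ks"`.
#' @param stride subsampling stride (default 1 = use all values).
#' @param alpha significance level for the `significant` flag (0.05).
#' @return an object of class `distance_comparison`: list with `p_value`,
#'   `statistic`, `test_name`, `n1`, `n2`, `effect` (difference of means,
#'   nm) and `significant`.
#' @examples
#' compare_distance_samples(rnorm(100, 1.7, 0.5), rnorm(100, 2.0, 0.2))
#' @export
compare_distance_samples <- function(d1, d2, method = c("wilcoxon", "ks"),
                                     stride = 1L, alpha = 0.05) {
  method <- match.arg(method)
  stride <- as.integer(stride)
  stopifnot(stride >= 1L)
  d1 <- as.numeric(d1)[seq(1L, length(d1), by = stride)]
  d2 <- as.numeric(d2)[seq(1L, length(d2), by = stride)]
  if (length(d1) < 10L || length(d2) < 10L)
    stop("each sample must contain at least 10 values (after thinning)")
  ht <- switch(method,
    wilcoxon = suppressWarnings(
      wilcox.test(d1, d2, alternative = "two.sided", exact = FALSE,
                  correct = TRUE)),
    ks = suppressWarnings(ks.test(d1, d2, alternative = "two.sided"))
  )
  structure(list(p_value = unname(ht$p.value),
                 statistic = unname(ht$statistic),
                 test_name = if (method == "wilcoxon")
                   "two-sided Mann-Whitney U" else
                   "two-sided Kolmogorov-Smirnov",
                 n1 = length(d1), n2 = length(d2),
                 effect = mean(d2) - mean(d1),
                 significant = unname(ht$p.value) < alpha,
                 alpha = alpha),
            class = "distance_comparison")
}

#' @export
print.distance_comparison <- function(x, ...) {
  cat(sprintf("%s: p = %.4g (n1 = %d, n2 = %d)\n",
              x$test_name, x$p_value, x$n1, x$n2))
  cat(sprintf("  difference of means %.3f nm; %ssignificant at %.3g\n",
              x$effect, if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Select representative configurations
#'
#' Picks the configurations lying in the maximally populated bin of the
#' two-dimensional histogram of two per-configuration quantities
#' (typically the intra-dimer Cu-Cu distance and the radius of gyration).
#' Ties between equally populated bins break toward the lowest bin index
#' (column-major order). An optional window on a third per-configuration
#' distance quantity intersects the selection, which may empty it.
#'
#' @param ens an `oligomer_ensemble`.
#' @param quantity_x,quantity_y functions mapping one configuration to a
#'   scalar, or precomputed numeric vectors (one value per configuration).
#' @param bins number of bins per axis (default 20).
#' @param window optional `c(lo, hi)` interval applied to `window_values`.
#' @param window_values per-configuration values the window applies to;
#'   defaults to `quantity_x`'s values.
#' @return integer vector of configuration ids (ensemble order), with
#'   attributes `"x"`, `"y"` (the quantity values) and `"bin"` (modal bin
#'   index).
#' @export
select_representatives <- function(ens, quantity_x, quantity_y, bins = 20L,
                                   window = NULL, window_values = NULL) {
  stopifnot(inherits(ens, "oligomer_ensemble"))
  n <- length(ens$configurations)
  if (!n) stop("ensemble is empty")
  eval_q <- function(q) {
    if (is.function(q)) vapply(ens$configurations, q, 0)
    else if (is.numeric(q) && length(q) == n) as.numeric(q)
    else stop("quantities must be functions of a configuration or ",
              "numeric vectors of length n_configs")
  }
  x <- eval_q(quantity_x); y <- eval_q(quantity_y)
  bin_of <- function(v) {
    rg <- range(v)
    if (diff(rg) == 0) return(rep(1L, length(v)))
    b <- findInterval(v, seq(rg[1], rg[2], length.out = bins + 1L),
                      rightmost.closed = TRUE, all.inside = TRUE)
    pmin(pmax(b, 1L), bins)
  }
  bx <- bin_of(x); by <- bin_of(y)
  cell <- (by - 1L) * bins + bx   # column-major flat index
  counts <- tabulate(cell, nbins = bins * bins)
  modal <- which.max(counts)      # first maximum = lowest bin index
  ids <- which(cell == modal)
  if (!is.null(window)) {
    wv <- if (is.null(window_values)) x else eval_q(window_values)
    ids2 <- ids[wv[ids] >= window[1] & wv[ids] <= window[2]]
    if (!length(ids2))
      message("distance window excludes all configurations of the modal bin")
    ids <- ids2
  }
  structure(ids, x = x, y = y, bin = modal)
}
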