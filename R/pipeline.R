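# End-to-end orchestration: ensemble statistics, forward DEER simulation,
# inversion, and the model-versus-measurement comparison report.

#' Pipeline configuration
#'
#' Bundles the knobs of [run_model_experiment_comparison]. Read/written as
#' plain JSON so runs are reproducible from a single text file.
#'
#' @param acquisition a [deer_acquisition].
#' @param r_grid inversion distance grid, nm.
#' @param alpha `"lcurve"` or a positive number.
#' @param fit_start_fraction background fit window start.
#' @param bin_width_distance,bin_width_orientation histogram bin widths.
#' @param test method for [compare_distance_samples].
#' @param seed master seed recorded in every output.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(acquisition = deer_acquisition(),
                            r_grid = seq(1, 8, length.out = 201),
                            alpha = "lcurve",
                            fit_start_fraction = 0.5,
                            bin_width_distance = 0.1,
                            bin_width_orientation = 0.05,
                            test = "wilcoxon",
                            seed = 1L) {
  structure(list(acquisition = acquisition, r_grid = r_grid, alpha = alpha,
                 fit_start_fraction = fit_start_fraction,
                 bin_width_distance = bin_width_distance,
                 bin_width_orientation = bin_width_orientation,
                 test = test, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param file JSON path.
#' @export
write_pipeline_config <- function(config, file) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$acquisition <- unclass(x$acquisition)
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  acq <- do.call(deer_acquisition, x$acquisition[
    names(x$acquisition) %in% names(formals(deer_acquisition))])
  pipeline_config(acquisition = acq, r_grid = x$r_grid, alpha = x$alpha,
                  fit_start_fraction = x$fit_start_fraction,
                  bin_width_distance = x$bin_width_distance,
                  bin_width_orientation = x$bin_width_orientation,
                  test = x$test, seed = x$seed)
}

#' Compare an ensemble model with a DEER measurement
#'
#' Runs the full analysis chain and assembles the comparison report:
#' pair-class Cu-Cu distance distributions and summaries, coordination
#' plane orientation statistics, the SASA tetramer filter, Tikhonov
#' inversion of the trace, and the agreement between the ensemble's
#' intra-dimer distance distribution (restricted to the 1-8 nm DEER
#' window) and the inverted distribution: mode difference and overlap
#' coefficient \eqn{\int \min(p_1, p_2) dr}. When the ensemble has no
#' intra-dimer pairs (half-occupancy stoichiometry) the inter-dimer
#' distribution is used for the comparison and flagged as such.
#'
#' If `trace` is `NULL`, a trace is forward-simulated from the ensemble's
#' own intra-dimer (or inter-dimer) distance distribution under
#' `config$acquisition` -- the self-consistency round trip.
#'
#' @param ens an `oligomer_ensemble` (or path to a multi-model PDB).
#' @param trace a [deer_trace], path to a trace file, or `NULL`.
#' @param config a [pipeline_config].
#' @param run_filter compute the SASA tetramer filter (the slowest stage;
#'   default `TRUE`).
#' @return an object of class `oligomer_report`.
#' @examples
#' \donttest{
#' ens <- generate_ensemble(ensemble_spec(n_configs = 50, seed = 1))
#' rep <- run_model_experiment_comparison(ens, config = pipeline_config())
#' print(rep)
#' }
#' @export
run_model_experiment_comparison <- function(ens, trace = NULL,
                                            config = pipeline_config(),
                                            run_filter = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (is.character(ens)) ens <- stage("read_ensemble", read_ensemble(ens))
  stopifnot(inherits(ens, "oligomer_ensemble"))

  dist_stats <- stage("ensemble_geometry", {
    res <- list()
    for (cls in PAIR_CLASSES) {
      d <- suppressMessages(pair_distances(ens, cls))
      res[[cls]] <- if (length(d) >= 2L)
        list(distances = d,
             summary = summarize_distances(d),
             histogram = distance_histogram(d, config$bin_width_distance))
      else list(distances = d, summary = NULL, histogram = NULL)
    }
    res
  })

  orient <- stage("orientation", {
    lapply(setNames(PAIR_CLASSES, PAIR_CLASSES), function(cls)
      suppressMessages(
        orientation_distribution(ens, cls, config$bin_width_orientation)))
  })

  filt <- if (run_filter) stage("oligomer_filter", filter_tetramers(ens))
          else NULL

  # the ensemble-side distribution entering the DEER comparison
  comp_class <- if (length(dist_stats$intra_dimer$distances) >= 2L)
    "intra_dimer" else "inter_dimer"
  # Gaussian kernel density on the inversion grid: a smooth mode estimate,
  # unlike the binned histograms reported in the distance tables.
  ens_dist <- stage("ensemble_distribution", {
    d <- dist_stats[[comp_class]]$distances
    d <- d[d >= min(config$r_grid) & d <= max(config$r_grid)]
    if (length(d) < 2L)
      stop("no ensemble distances inside the inversion window")
    kd <- stats::density(d, from = min(config$r_grid), to = max(config$r_grid),
                         n = length(config$r_grid))
    distance_distribution(config$r_grid, pmax(kd$y, 0))
  })

  acq <- config$acquisition
  if (is.null(trace)) {
    trace <- stage("deer_forward", {
      a <- acq; a$seed <- config$seed
      simulate_deer_trace(ens_dist, a)
    })
  } else if (is.character(trace)) {
    trace <- stage("read_trace", read_deer_trace(trace))
  }

  fit <- stage("deer_inversion",
               deer_fit(trace, r = config$r_grid, alpha = config$alpha,
                        fit_start_fraction = config$fit_start_fraction))

  comparison <- stage("comparison", {
    ens_mode <- as.numeric(distribution_mode(ens_dist))
    pk <- distribution_peaks(fit$p)
    list(class_used = comp_class,
         ensemble_mode = ens_mode,
         inverted_mode = fit$mode_r,
         mode_difference = fit$mode_r - ens_mode,
         overlap = overlap_coefficient(ens_dist, fit$p),
         inverted_peaks = pk,
         multimodal = length(pk) > 1L)
  })

  structure(list(distances = dist_stats,
                 orientation = orient,
                 filter = filt,
                 ensemble_distribution = ens_dist,
                 trace = trace,
                 fit = fit,
                 comparison = comparison,
                 stoichiometry = ens$stoichiometry,
                 config = config),
            class = "oligomer_report")
}

#' @export
print.oligomer_report <- function(x, ...) {
  cat(sprintf("Model-experiment comparison (%s ensemble)\n", x$stoichiometry))
  for (cls in PAIR_CLASSES) {
    s <- x$distances[[cls]]$summary
    if (!is.null(s))
      cat(sprintf("  %-12s Cu-Cu: %.2f +/- %.2f nm (n = %d)\n",
                  gsub("_", "-", cls), s["mean"], s["sd"], as.integer(s["n"])))
  }
  ao <- x$orientation$intra_dimer$angle_sd_deg
  if (!is.na(ao))
    cat(sprintf("  within-dimer plane-normal spread: %.1f deg\n", ao))
  if (!is.null(x$filter))
    cat(sprintf("  assembled tetramers (SASA ratio < 0.95): %.0f%%\n",
                100 * attr(x$filter, "fraction")))
  cat(sprintf("  inverted mode %.2f nm vs ensemble (%s) mode %.2f nm\n",
              x$comparison$inverted_mode,
              gsub("_", "-", x$comparison$class_used),
              x$comparison$ensemble_mode))
  cat(sprintf("  overlap coefficient %.3f%s\n", x$comparison$overlap,
              if (x$comparison$multimodal) "  [inverted P(r) multimodal]" else ""))
  invisible(x)
}

#' Write a report as plain-text key-value + tables
#'
#' Machine-readable dump of an [run_model_experiment_comparison] report:
#' a `key: value` header (including the seed and a hash of the
#' configuration) followed by the distance and orientation tables.
#'
#' @param report an `oligomer_report`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "oligomer_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- jsonlite::toJSON(unclass(report$config), auto_unbox = TRUE,
                               digits = NA, force = TRUE)
  kv <- c(stoichiometry = report$stoichiometry,
          seed = report$config$seed,
          config_hash = sprintf("%08x", sum(utf8ToInt(cfg_json) *
            (seq_along(utf8ToInt(cfg_json)) %% 251 + 1)) %% .Machine$integer.max),
          class_used = report$comparison$class_used,
          ensemble_mode_nm = report$comparison$ensemble_mode,
          inverted_mode_nm = report$comparison$inverted_mode,
          mode_difference_nm = report$comparison$mode_difference,
          overlap_coefficient = report$comparison$overlap,
          multimodal = report$comparison$multimodal,
          lambda = report$fit$lambda,
          k_per_ns = report$fit$k,
          alpha = report$fit$alpha)
  for (cls in PAIR_CLASSES) {
    s <- report$distances[[cls]]$summary
    if (!is.null(s)) {
      kv[paste0(cls, "_mean_nm")] <- s[["mean"]]
      kv[paste0(cls, "_sd_nm")] <- s[["sd"]]
      kv[paste0(cls, "_n")] <- s[["n"]]
    }
    a <- report$orientation[[cls]]$angle_sd_deg
    if (!is.na(a)) kv[paste0(cls, "_angle_sd_deg")] <- a
  }
  if (!is.null(report$filter))
    kv["assembled_fraction"] <- attr(report$filter, "fraction")
  writeLines(sprintf("%s: %s", names(kv), as.character(kv)),
             file.path(dir, "report.txt"))
  write_distribution(report$fit$p, file.path(dir, "inverted_distribution.txt"),
                     header = c(seed = report$config$seed))
  write_distribution(report$ensemble_distribution,
                     file.path(dir, "ensemble_distribution.txt"),
                     header = c(seed = report$config$seed))
  if (!is.null(report$filter))
    write.table(report$filter, file.path(dir, "tetramer_filter.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
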