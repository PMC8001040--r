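#' Run the full particle-tracking analysis pipeline
#'
#' Wires all stages together: read (or simulate) the dataset, drop short
#' trajectories, trim curves to the lag-time threshold, fit the anomalous
#' diffusion model per particle, screen, and summarise. When `output_dir`
#' is given, a per-particle results CSV and a JSON run report (stage counts,
#' thresholds, mean and median summaries) are written there.
#'
#' `config` is a named list (or the path of a JSON file with the same
#' fields):
#'
#' * `input` — path of a data CSV / xlsx workbook, *or* `simulate = TRUE`
#'   with optional `mixture` arguments for [mixture_spec()];
#' * `min_segments` (10), `lag_max` (1 s), `short_lag` (0.2 s),
#'   `fit_method` (`"log_linear"`), `diagnostic_space` (`"original"`);
#' * screening: `r2_min` (0.5), `rss_max` (5), `alpha_max` (1.1), `mode`
#'   (`"combined"`), `rss_metric` (`"rss"`);
#' * summaries: `statistic` (`"median"`), `thickness` (100 um), `p`
#'   (0.999);
#' * optional `r2_grid` — when present a threshold sweep table is included;
#' * `output_dir` — where to write `results.csv` and `report.json`.
#'
#' @param config Named list or path to a JSON config file.
#' @return An object of class `pt_report` (a list): `stage_counts`,
#'   `screening` ([screen_particles()] outcome), `results` (per-particle
#'   data frame), `summary_mean`, `summary_median`, `passage_time_s`, and
#'   optionally `sweep`.
#' @export
pt_pipeline <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- utils::modifyList(
    list(min_segments = 10L, lag_max = 1.0, short_lag = 0.2,
         fit_method = "log_linear", diagnostic_space = "original",
         r2_min = 0.5, rss_max = 5, alpha_max = 1.1, mode = "combined",
         rss_metric = "rss", statistic = "median",
         thickness = 100, p = 0.999),
    config)

  # --- input stage ---------------------------------------------------------
  if (!is.null(cfg$input)) {
    ds <- read_msd_workbook(cfg$input, metadata_path = cfg$metadata)
    labels <- NULL
  } else if (isTRUE(cfg$simulate)) {
    mspec <- do.call(mixture_spec, cfg$mixture %||% list())
    mix <- simulate_mixture(mspec)
    ds <- mix$dataset
    labels <- mix$labels
  } else {
    stop("config must name an 'input' file or set simulate = TRUE",
         call. = FALSE)
  }
  n_read <- length(ds$curves)

  # --- filtering stages ----------------------------------------------------
  ds <- filter_min_segments(ds, cfg$min_segments)
  n_minseg <- length(ds$curves)
  if (n_minseg == 0L)
    stop("no trajectories left after the minimum-segment filter",
         call. = FALSE)
  ds$curves <- lapply(ds$curves, trim_to_lag, lag_max = cfg$lag_max)
  ds$curves <- ds$curves[vapply(ds$curves, function(cu) length(cu$lags) > 0,
                                logical(1))]

  # --- fit and screen ------------------------------------------------------
  fits <- fit_dataset(ds, method = cfg$fit_method, short_lag = cfg$short_lag,
                      diagnostic_space = cfg$diagnostic_space)
  scfg <- screening_config(r2_min = cfg$r2_min, rss_max = cfg$rss_max,
                           alpha_max = cfg$alpha_max, mode = cfg$mode,
                           rss_metric = cfg$rss_metric)
  scr <- screen_particles(fits, scfg)
  if (scr$n_kept == 0L)
    stop("screening discarded every trajectory", call. = FALSE)
  rec <- scr$records
  rec$transport_class <- as.character(
    ifelse(rec$unfit, NA, as.character(
      classify_transport(clamp_alpha(ifelse(rec$unfit, 0, rec$alpha_star)),
                         alpha_max = cfg$alpha_max))))
  kept <- rec[rec$kept, , drop = FALSE]

  # --- summaries -----------------------------------------------------------
  sum_mean <- summarize_population(kept, statistic = "mean",
                                   alpha_max = cfg$alpha_max)
  sum_median <- summarize_population(kept, statistic = "median",
                                     alpha_max = cfg$alpha_max)
  chosen <- if (cfg$statistic == "mean") sum_mean else sum_median
  pt_cross <- passage_time(chosen$D_summary, thickness_r = cfg$thickness,
                           p = cfg$p)

  report <- list(
    stage_counts = list(read = n_read, after_min_segments = n_minseg,
                        fitted = nrow(rec), kept = scr$n_kept,
                        discarded = as.list(table(
                          rec$discard_reason[rec$discard_reason != "none"]))),
    config = cfg,
    screening = scr,
    results = rec,
    labels = labels,
    summary_mean = sum_mean,
    summary_median = sum_median,
    passage_time_s = pt_cross)
  if (!is.null(cfg$r2_grid))
    report$sweep <- threshold_sweep(fits, r2_grid = as.numeric(cfg$r2_grid),
                                    config = scfg)
  class(report) <- "pt_report"

  # --- outputs -------------------------------------------------------------
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_results_table(rec, file.path(cfg$output_dir, "results.csv"))
    js <- list(stage_counts = report$stage_counts,
               thresholds = cfg[c("min_segments", "lag_max", "r2_min",
                                  "rss_max", "alpha_max", "mode")],
               retention_pct = scr$retention_pct,
               summary_mean = unclass_summary(sum_mean),
               summary_median = unclass_summary(sum_median),
               passage_time_s = pt_cross)
    if (!is.null(report$sweep)) js$sweep <- report$sweep
    jsonlite::write_json(js, file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

unclass_summary <- function(s) {
  list(statistic = s$statistic, D = s$D_summary,
       D_over_ref = s$D_over_ref_summary, alpha = s$alpha_summary,
       mean_median_ratio_D = s$mean_median_ratio_D,
       class_fractions = as.list(s$class_fractions), n_kept = s$n_kept)
}

#' @export
print.pt_report <- function(x, ...) {
  sc <- x$stage_counts
  cat("Particle-tracking pipeline report\n")
  cat(sprintf("  curves read:              %d\n", sc$read))
  cat(sprintf("  after min-segment filter: %d\n", sc$after_min_segments))
  cat(sprintf("  kept after screening:     %d (%.1f%%)\n", sc$kept,
              x$screening$retention_pct))
  if (length(sc$discarded))
    for (nm in names(sc$discarded))
      cat(sprintf("    discarded %-22s %d\n", nm, sc$discarded[[nm]]))
  cat("\n")
  print(if (x$config$statistic == "mean") x$summary_mean else x$summary_median)
  cat(sprintf("\n  passage time across %g um layer (p = %g): %.4g s\n",
              x$config$thickness, x$config$p, x$passage_time_s))
  invisible(x)
}
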