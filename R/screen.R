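#' Screening thresholds for trajectory goodness-of-fit
#'
#' Bundles the thresholds used to keep or discard fitted trajectories:
#'
#' * `r2_min` — minimum R2 (default 0.5);
#' * `rss_max` — maximum residual sum of squares in (um^2)^2 (default 5);
#' * `alpha_max` — largest valid clamped exponent; above it a trajectory is
#'   treated as a flow artifact (default 1.1, boundary kept);
#' * `alpha_min` — smallest valid clamped exponent (default 0, i.e. none
#'   excluded: immobile particles are kept);
#' * `mode` — `"combined"` keeps a trajectory when the fit is good OR the
#'   residuals are small (failing both marks it erratic); `"conventional"`
#'   applies the R2 threshold alone; `"strict_and"` requires both (provided
#'   for comparison);
#' * `rss_metric` — whether `rss_max` is compared against `"rss"` (default)
#'   or `"rmse"`.
#'
#' @param r2_min Minimum R2 in \[0, 1\].
#' @param rss_max Maximum RSS, (um^2)^2 (or RMSE in um^2, see `rss_metric`).
#' @param alpha_max,alpha_min Validity window for alpha_star.
#' @param mode Screening rule.
#' @param rss_metric Residual statistic thresholded by `rss_max`.
#' @return An object of class `screening_config`.
#' @export
screening_config <- function(r2_min = 0.5, rss_max = 5, alpha_max = 1.1,
                             alpha_min = 0,
                             mode = c("combined", "conventional", "strict_and"),
                             rss_metric = c("rss", "rmse")) {
  mode <- match.arg(mode)
  rss_metric <- match.arg(rss_metric)
  if (!is.finite(r2_min) || r2_min < 0 || r2_min > 1)
    stop("'r2_min' must be in [0, 1]", call. = FALSE)
  if (!is.finite(rss_max) || rss_max < 0)
    stop("'rss_max' must be >= 0", call. = FALSE)
  if (!(alpha_max > alpha_min))
    stop("'alpha_max' must exceed 'alpha_min'", call. = FALSE)
  structure(list(r2_min = r2_min, rss_max = rss_max, alpha_max = alpha_max,
                 alpha_min = alpha_min, mode = mode, rss_metric = rss_metric),
            class = "screening_config")
}

#' @export
print.screening_config <- function(x, ...) {
  cat(sprintf("Screening config (%s): R2 >= %g, %s <= %g, alpha* in [%g, %g]\n",
              x$mode, x$r2_min, toupper(x$rss_metric), x$rss_max,
              x$alpha_min, x$alpha_max))
  invisible(x)
}

#' Flag super-diffusive exponents
#'
#' Exponents above `alpha_max` usually indicate directed flow (e.g. a badly
#' sealed sample) rather than diffusion and are discarded; the rule is a
#' strict inequality, so `alpha_star == alpha_max` is kept. Negative raw
#' exponents were already clamped to 0 upstream and are *not* discarded —
#' they are immobile particles.
#'
#' @param alpha_star Numeric vector of clamped exponents.
#' @param alpha_max Validity threshold (default 1.1).
#' @return Logical vector: `TRUE` where the exponent is invalid
#'   (super-diffusive).
#' @export
alpha_validity_filter <- function(alpha_star, alpha_max = 1.1) {
  alpha_star > alpha_max
}

#' Screen fitted trajectories
#'
#' Applies a [screening_config] to a table of per-particle fits (from
#' [fit_dataset()]). Every particle receives a verdict and a reason:
#'
#' * `unfit` — the model could not be fitted (too few usable points);
#' * `alpha_superdiffusive` — alpha_star outside the validity window;
#' * `low_r2` — R2 below `r2_min` (conventional / strict_and modes);
#' * `erratic_high_rss` — R2 below `r2_min` *and* residuals above `rss_max`
#'   (combined mode; also strict_and when only the residuals fail);
#' * `none` — kept.
#'
#' The combined rule keeps a particle when *either* criterion passes: flat,
#' mucus-trapped trajectories score near-zero R2 but tiny residuals and are
#' retained, while erratic trajectories fail both tests.
#'
#' @param fits A data frame of per-particle fit records with columns `R2`,
#'   `RSS` (and `RMSE`), `alpha_star`, `unfit`.
#' @param config A [screening_config]; individual thresholds may be
#'   overridden via `...` which is passed to [screening_config()] when
#'   `config` is missing.
#' @return An object of class `pt_screen`: the input records plus `kept`
#'   and `discard_reason` columns, with `n_total`, `n_kept` and
#'   `retention_pct` attached.
#' @export
screen_particles <- function(fits, config = screening_config()) {
  stopifnot(is.data.frame(fits), inherits(config, "screening_config"))
  n <- nrow(fits)
  if (n == 0L) {
    out <- list(records = fits, config = config, n_total = 0L, n_kept = 0L,
                retention_pct = NaN)
    class(out) <- "pt_screen"
    return(out)
  }
  resid_stat <- if (config$rss_metric == "rmse") fits$RMSE else fits$RSS
  reason <- rep("none", n)
  unfit <- isTRUE_vec(fits$unfit)
  reason[unfit] <- "unfit"
  bad_alpha <- !unfit &
    (alpha_validity_filter(fits$alpha_star, config$alpha_max) |
       fits$alpha_star < config$alpha_min)
  reason[bad_alpha] <- "alpha_superdiffusive"
  open <- !unfit & !bad_alpha
  low_r2 <- open & fits$R2 < config$r2_min
  high_rss <- open & resid_stat > config$rss_max
  if (config$mode == "conventional") {
    reason[low_r2] <- "low_r2"
  } else if (config$mode == "combined") {
    reason[low_r2 & high_rss] <- "erratic_high_rss"
  } else { # strict_and
    reason[low_r2] <- "low_r2"
    reason[!low_r2 & high_rss] <- "erratic_high_rss"
  }
  kept <- reason == "none"
  rec <- fits
  rec$kept <- kept
  rec$discard_reason <- reason
  out <- list(records = rec, config = config,
              n_total = n, n_kept = sum(kept),
              retention_pct = retention_percentage(sum(kept), n))
  class(out) <- "pt_screen"
  out
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE

#' @rdname screen_particles
#' @param ... Threshold overrides passed to [screening_config()].
#' @export
screen_conventional <- function(fits, ...) {
  screen_particles(fits, screening_config(..., mode = "conventional"))
}

#' @rdname screen_particles
#' @export
screen_combined <- function(fits, ...) {
  screen_particles(fits, screening_config(..., mode = "combined"))
}

#' @export
print.pt_screen <- function(x, ...) {
  cat(sprintf("Trajectory screening (%s): kept %d of %d (%.1f%%)\n",
              x$config$mode, x$n_kept, x$n_total, x$retention_pct))
  tb <- table(x$records$discard_reason)
  tb <- tb[names(tb) != "none"]
  if (length(tb))
    for (nm in names(tb)) cat(sprintf("  discarded %-22s %d\n", nm, tb[[nm]]))
  invisible(x)
}

#' Retention percentage
#'
#' Percentage of trajectories kept by a screening rule, reported to one
#' decimal place as in retention tables.
#'
#' @param n_kept Number kept (0 <= n_kept <= n_total).
#' @param n_total Total number of trajectories (>= 1).
#' @return `round(100 * n_kept / n_total, 1)`.
#' @examples
#' retention_percentage(6681, 6965)  # 95.9
#' @export
retention_percentage <- function(n_kept, n_total) {
  if (any(n_total < 1)) stop("'n_total' must be >= 1", call. = FALSE)
  if (any(n_kept < 0) || any(n_kept > n_total))
    stop("'n_kept' must be between 0 and 'n_total'", call. = FALSE)
  round(100 * n_kept / n_total, 1)
}

#' Sweep the R2 threshold and compare with combined screening
#'
#' Reproduces the structure of a screening-comparison table: one row per R2
#' threshold using the conventional rule, plus a final row for the combined
#' R2/RSS rule at `config`'s thresholds. Each row reports the summary alpha
#' and D/D_ref of the kept particles (by `statistic`, default mean), the
#' number kept and the retention percentage.
#'
#' @param fits Per-particle fit records (see [fit_dataset()]).
#' @param r2_grid Numeric vector of R2 thresholds.
#' @param config Base [screening_config] supplying `rss_max`, `alpha_max`
#'   and the combined row's `r2_min`.
#' @param reference_D Reference diffusion coefficient; defaults to using the
#'   `D_over_Dref` column when present.
#' @param statistic `"mean"` or `"median"` summary of kept particles.
#' @return A data frame with columns `approach`, `alpha_summary`,
#'   `D_over_ref_summary`, `n_kept`, `retention_pct`.
#' @export
threshold_sweep <- function(fits, r2_grid = seq(0, 0.9, by = 0.1),
                            config = screening_config(),
                            reference_D = NULL,
                            statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  stat_fun <- if (statistic == "mean") mean else stats::median
  dref <- function(rec) {
    if (!is.null(reference_D)) rec$D / reference_D
    else if ("D_over_Dref" %in% names(rec)) rec$D_over_Dref
    else rep(NA_real_, nrow(rec))
  }
  one_row <- function(scr, label) {
    kept <- scr$records[scr$records$kept, , drop = FALSE]
    data.frame(approach = label,
               alpha_summary = if (nrow(kept)) stat_fun(kept$alpha_star) else NA_real_,
               D_over_ref_summary = if (nrow(kept)) stat_fun(dref(kept)) else NA_real_,
               n_kept = scr$n_kept,
               retention_pct = scr$retention_pct,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(r2_grid, function(t) {
    cfg <- screening_config(r2_min = t, rss_max = config$rss_max,
                            alpha_max = config$alpha_max,
                            alpha_min = config$alpha_min,
                            mode = "conventional",
                            rss_metric = config$rss_metric)
    one_row(screen_particles(fits, cfg), sprintf("R2 >= %.1f", t))
  })
  cfg_comb <- screening_config(r2_min = config$r2_min, rss_max = config$rss_max,
                               alpha_max = config$alpha_max,
                               alpha_min = config$alpha_min,
                               mode = "combined",
                               rss_metric = config$rss_metric)
  rows <- c(rows, list(one_row(screen_particles(fits, cfg_comb), "R2 + RSS")))
  do.call(rbind, rows)
}
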