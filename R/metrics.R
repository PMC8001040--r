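#' Ratio of a particle's D to a reference medium
#'
#' D measured in mucus divided by D measured in a simple reference medium
#' (water or saline). Ratios near 1 indicate unimpeded (mucodiffusive)
#' particles; ratios much below 1 indicate mucus-trapped particles.
#'
#' @param D_hat Fitted diffusion coefficient(s), um^2/s.
#' @param reference_D Reference diffusion coefficient, um^2/s (> 0).
#' @return `D_hat / reference_D`.
#' @export
ratio_to_reference <- function(D_hat, reference_D) {
  if (!is.finite(reference_D) || reference_D <= 0)
    stop("'reference_D' must be > 0", call. = FALSE)
  D_hat / reference_D
}

#' Diffusivity factor DF = D_long / D_short
#'
#' Fits the same trajectory over a long and a short lag-time window (1 s and
#' 0.2 s by default) and returns the ratio of the two diffusion
#' coefficients. Freely diffusing particles show the same power law at both
#' scales (DF >= 0.9); particles that progressively interact with the mucus
#' slow down with time and give DF < 0.9. An exact power law gives DF = 1
#' for any alpha.
#'
#' @param curve An [msd_curve] reaching at least `long_lag`.
#' @param long_lag,short_lag Window lengths in seconds, `short_lag <
#'   long_lag`.
#' @param method Fitting method passed to [msd_fit()].
#' @return The ratio `DF`, or `NA` (with a warning) when the curve does not
#'   reach `long_lag` or either windowed fit fails.
#' @export
diffusivity_factor <- function(curve, long_lag = 1.0, short_lag = 0.2,
                               method = "log_linear") {
  stopifnot(inherits(curve, "msd_curve"))
  if (!(short_lag < long_lag))
    stop("'short_lag' must be smaller than 'long_lag'", call. = FALSE)
  if (max(curve$lags) < long_lag - 1e-9) {
    warning("curve does not reach 'long_lag'; DF omitted")
    return(NA_real_)
  }
  f_long <- msd_fit(trim_to_lag(curve, long_lag), method = method)
  cu_short <- trim_to_lag(curve, short_lag)
  if (length(cu_short$lags) < 3L || f_long$unfit) {
    warning("windowed fit failed; DF omitted")
    return(NA_real_)
  }
  f_short <- msd_fit(cu_short, method = method)
  if (f_short$unfit) {
    warning("windowed fit failed; DF omitted")
    return(NA_real_)
  }
  f_long$D_hat / f_short$D_hat
}

#' Transport class of an anomalous exponent
#'
#' Assigns each clamped exponent to the standard particle-tracking transport
#' mode: immobile (alpha < 0.2), hindered (0.2 <= alpha < 0.4), subdiffusive
#' (0.4 <= alpha < 0.9), diffusive (0.9 <= alpha <= alpha_max), and
#' super-diffusive (> alpha_max, normally discarded as a flow artifact).
#' Boundaries are closed below and open above, with 0.9 belonging to the
#' diffusive class.
#'
#' @param alpha_star Numeric vector of clamped exponents (>= 0).
#' @param alpha_max Upper validity bound (default 1.1).
#' @return A factor with levels `immobile`, `hindered`, `subdiffusive`,
#'   `diffusive`, `superdiffusive_discarded`.
#' @examples
#' classify_transport(c(0.1, 0.3, 0.5, 1.0, 1.2))
#' @export
classify_transport <- function(alpha_star, alpha_max = 1.1) {
  if (any(alpha_star < 0, na.rm = TRUE))
    stop("'alpha_star' must be >= 0 (clamp first)", call. = FALSE)
  cut(alpha_star,
      breaks = c(-Inf, 0.2, 0.4, 0.9, alpha_max, Inf),
      labels = c("immobile", "hindered", "subdiffusive", "diffusive",
                 "superdiffusive_discarded"),
      right = FALSE, include.lowest = TRUE) ->
    cl
  # cut() with right = FALSE makes [0.9, alpha_max) diffusive and puts
  # alpha_max itself in the top bin; the validity rule is strict (> alpha_max
  # discarded), so pull the boundary back in
  cl[!is.na(alpha_star) & alpha_star == alpha_max] <- "diffusive"
  cl
}

#' Time to traverse a mucus layer
#'
#' Expected time for a particle of diffusivity D to cross a layer of
#' thickness r with probability p, under exponential first-passage kinetics
#' with rate 4 D / r^2 (the 2-D MSD scaling):
#'
#'   t = r^2 * ln(1 / (1 - p)) / (4 D).
#'
#' Larger D shortens the passage time proportionally; larger p or thicker
#' layers lengthen it. The factor 4 reflects the dimensionality of the MSD
#' model and can be changed via `dimension_factor`.
#'
#' @param D_hat Diffusion coefficient(s), um^2/s.
#' @param thickness_r Layer thickness in um (default 100, a typical
#'   intestinal mucus blanket).
#' @param p Crossing probability in (0, 1) (default 0.999).
#' @param dimension_factor MSD dimensionality constant (default 4).
#' @return Passage time(s) in seconds; `Inf` for D = 0.
#' @examples
#' passage_time(1)  # 100 um layer: 1e4 * log(1000) / 4 ~ 17269 s
#' @export
passage_time <- function(D_hat, thickness_r = 100, p = 0.999,
                         dimension_factor = 4) {
  if (!is.finite(p) || p <= 0 || p >= 1)
    stop("'p' must be in (0, 1)", call. = FALSE)
  if (any(D_hat < 0, na.rm = TRUE))
    stop("'D_hat' must be >= 0", call. = FALSE)
  if (!is.finite(thickness_r) || thickness_r <= 0)
    stop("'thickness_r' must be > 0", call. = FALSE)
  ifelse(D_hat == 0, Inf,
         thickness_r^2 * log(1 / (1 - p)) / (dimension_factor * D_hat))
}

#' Population summary of kept particles
#'
#' Summarises the diffusion metrics of the particles kept by screening: the
#' chosen statistic (median by default, the robust choice for heterogeneous
#' formulations) of D, D/D_ref and alpha_star, the transport-class
#' fractions, and the mean/median ratio of D — a heterogeneity indicator
#' that is ~1 for Gaussian-like populations and grows with skew.
#'
#' @param records Data frame of kept per-particle records with columns `D`
#'   and `alpha_star` (and optionally `D_over_Dref`).
#' @param statistic `"median"` (default) or `"mean"`.
#' @param reference_D Optional reference D used when `D_over_Dref` is
#'   absent.
#' @param alpha_max Passed to [classify_transport()].
#' @return An object of class `population_summary` with fields `statistic`,
#'   `D_summary`, `D_over_ref_summary`, `alpha_summary`,
#'   `mean_median_ratio_D`, `class_fractions`, `n_kept`.
#' @export
summarize_population <- function(records, statistic = c("median", "mean"),
                                 reference_D = NULL, alpha_max = 1.1) {
  statistic <- match.arg(statistic)
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("'records' must contain at least one kept particle", call. = FALSE)
  stat_fun <- if (statistic == "mean") mean else stats::median
  dref <- if (!is.null(reference_D)) records$D / reference_D
          else if ("D_over_Dref" %in% names(records)) records$D_over_Dref
          else rep(NA_real_, nrow(records))
  cls <- classify_transport(records$alpha_star, alpha_max = alpha_max)
  fractions <- table(cls) / length(cls)
  structure(
    list(statistic = statistic,
         D_summary = stat_fun(records$D),
         D_over_ref_summary = stat_fun(dref),
         alpha_summary = stat_fun(records$alpha_star),
         mean_median_ratio_D = mean(records$D) / stats::median(records$D),
         class_fractions = fractions,
         n_kept = nrow(records)),
    class = "population_summary")
}

#' @export
print.population_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Population summary (%s of %d kept particles)\n",
              x$statistic, x$n_kept))
  cat(sprintf("  D:        %s um^2/s\n", signif(x$D_summary, digits)))
  if (is.finite(x$D_over_ref_summary))
    cat(sprintf("  D/D_ref:  %s\n", signif(x$D_over_ref_summary, digits)))
  cat(sprintf("  alpha*:   %s\n", signif(x$alpha_summary, digits)))
  cat(sprintf("  mean/median D (heterogeneity): %s\n",
              signif(x$mean_median_ratio_D, digits)))
  cat("  transport classes:\n")
  fr <- x$class_fractions
  for (nm in names(fr))
    cat(sprintf("    %-25s %5.1f%%\n", nm, 100 * fr[[nm]]))
  invisible(x)
}

#' Histogram export of per-particle metrics
#'
#' Bin edges and counts for the distributions of D/D_ref, alpha_star, R2 and
#' RSS (those present in `records`), matching what population histograms
#' display.
#'
#' @param records Per-particle records.
#' @param breaks Number of bins (passed to [graphics::hist()]).
#' @return Named list; each element has `breaks`, `counts`, `mids`.
#' @export
population_histograms <- function(records, breaks = 30) {
  vars <- intersect(c("D_over_Dref", "alpha_star", "R2", "RSS"),
                    names(records))
  out <- lapply(vars, function(v) {
    x <- records[[v]]
    x <- x[is.finite(x)]
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    list(breaks = h$breaks, counts = h$counts, mids = h$mids)
  })
  stats::setNames(out, vars)
}
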