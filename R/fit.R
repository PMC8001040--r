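#' Fit the anomalous diffusion model to one MSD curve
#'
#' Fits MSD = 4 * D * tau^alpha to a particle's MSD-versus-lag-time curve.
#' Two estimation methods are available:
#'
#' * `"log_linear"` (default): ordinary least squares of log(MSD) on
#'   log(tau), i.e. log(MSD) = log(4 D) + alpha * log(tau) + eps. The slope
#'   is the estimate of alpha and D = exp(intercept) / 4. Points with
#'   MSD <= 0 cannot be log-transformed and are excluded; if more than
#'   `max_excluded_frac` of the points are excluded, or fewer than 3 usable
#'   points remain, the particle is flagged unfit.
#' * `"nonlinear"`: bounded Levenberg-Marquardt least squares of
#'   sum (MSD_k - 4 D tau_k^alpha)^2 with D > 0 and alpha in
#'   `alpha_bounds`, started from the log-linear estimates when available.
#'
#' Goodness-of-fit diagnostics (R2, RSS, TSS, RMSE) are computed by
#' [goodness_of_fit()] in the original, untransformed MSD space for both
#' methods (`diagnostic_space = "original"`), so that RSS thresholds in
#' (um^2)^2 and R2 thresholds are comparable across methods. Set
#' `diagnostic_space = "transformed"` to diagnose the log-linear fit in log
#' space instead.
#'
#' The clamped exponent alpha_star = max(0, alpha_hat) is always reported:
#' slightly negative fitted exponents arise for immobile particles and are
#' read as alpha = 0.
#'
#' @param curve An [msd_curve].
#' @param method `"log_linear"` or `"nonlinear"`.
#' @param diagnostic_space Space in which R2/RSS/RMSE are computed;
#'   `"original"` (default) or `"transformed"` (log-log, log_linear method
#'   only).
#' @param alpha_bounds Lower and upper bounds on alpha for the nonlinear
#'   optimizer. The default upper bound 3 is loose; screening discards
#'   super-diffusive exponents separately.
#' @param max_excluded_frac Largest tolerated fraction of non-positive MSD
#'   points before the particle is flagged unfit (log-linear method).
#' @return An object of class `msd_fit` with components `D_hat`,
#'   `alpha_hat`, `alpha_star`, `beta0_hat`, `beta1_hat` (log-linear only),
#'   `R2`, `RSS`, `TSS`, `RMSE`, `n_points`, `n_excluded`, `converged`,
#'   `unfit`, `unfit_reason`, `method`, and the fitted `curve`.
#' @examples
#' cu <- msd_curve((1:100) / 100, 4 * 0.5 * ((1:100) / 100)^0.8)
#' fit <- msd_fit(cu)
#' coef(fit)  # D = 0.5, alpha = 0.8
#' @seealso [goodness_of_fit()], [clamp_alpha()], [fit_dataset()]
#' @export
msd_fit <- function(curve,
                    method = c("log_linear", "nonlinear"),
                    diagnostic_space = c("original", "transformed"),
                    alpha_bounds = c(0, 3),
                    max_excluded_frac = 0.2) {
  stopifnot(inherits(curve, "msd_curve"))
  method <- match.arg(method)
  diagnostic_space <- match.arg(diagnostic_space)

  n_all <- length(curve$lags)
  usable <- curve$msd > 0 & curve$lags > 0
  n_usable <- sum(usable)
  n_excluded <- n_all - n_usable

  unfit_result <- function(reason) {
    structure(
      list(method = method, curve = curve,
           D_hat = NA_real_, alpha_hat = NA_real_, alpha_star = NA_real_,
           beta0_hat = NA_real_, beta1_hat = NA_real_,
           R2 = NA_real_, RSS = NA_real_, TSS = NA_real_, RMSE = NA_real_,
           n_points = n_all, n_excluded = n_excluded,
           converged = FALSE, unfit = TRUE, unfit_reason = reason,
           diagnostic_space = diagnostic_space),
      class = "msd_fit")
  }

  if (n_usable < 3L) return(unfit_result("too_few_points"))
  if (n_all > 0L && n_excluded / n_all > max_excluded_frac)
    return(unfit_result("too_many_nonpositive"))

  lx <- log(curve$lags[usable])
  ly <- log(curve$msd[usable])
  if (stats::var(lx) < 1e-24) return(unfit_result("zero_lag_variance"))

  # log-linear estimates are always computed: they are either the result or
  # the nonlinear starting values
  ll <- stats::lm.fit(cbind(1, lx), ly)
  beta0 <- unname(ll$coefficients[1])
  beta1 <- unname(ll$coefficients[2])
  D_ll <- exp(beta0) / 4
  a_ll <- beta1

  if (method == "log_linear") {
    D_hat <- D_ll; alpha_hat <- a_ll
    converged <- TRUE
  } else {
    start <- list(D = max(D_ll, 1e-12),
                  alpha = min(max(a_ll, alpha_bounds[1]), alpha_bounds[2]))
    df <- data.frame(lag = curve$lags, msd = curve$msd)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        msd ~ 4 * D * lag^alpha, data = df, start = start,
        lower = c(D = 1e-12, alpha = alpha_bounds[1]),
        upper = c(D = Inf, alpha = alpha_bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10,
                                             ptol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      D_hat <- unname(cf["D"]); alpha_hat <- unname(cf["alpha"])
      converged <- fit$convInfo$isConv %||% TRUE
    } else {
      # degenerate curves (e.g. zero residuals at the start) can break the
      # LM step; minimise the same RSS with bounded quasi-Newton instead
      obj <- function(p) {
        r <- df$msd - 4 * exp(p[1]) * df$lag^p[2]
        sum(r * r)
      }
      op <- stats::optim(c(log(start$D), start$alpha), obj,
                         method = "L-BFGS-B",
                         lower = c(-60, alpha_bounds[1]),
                         upper = c(60, alpha_bounds[2]))
      D_hat <- exp(op$par[1]); alpha_hat <- op$par[2]
      converged <- op$convergence == 0L
    }
  }

  if (diagnostic_space == "transformed") {
    lcurve <- msd_curve(exp(lx), exp(ly))  # usable points only
    pred <- log(4 * D_hat) + alpha_hat * lx
    r <- ly - pred
    RSS <- sum(r * r)
    TSS <- sum((ly - mean(ly))^2)
    R2 <- if (TSS > 1e-12) max(0, 1 - RSS / TSS) else 0
    gof <- list(R2 = R2, RSS = RSS, TSS = TSS, RMSE = sqrt(RSS / length(r)))
    n_pts <- length(r)
  } else {
    gof <- goodness_of_fit(curve, D = D_hat, alpha = alpha_hat)
    n_pts <- n_all
  }

  structure(
    list(method = method, curve = curve,
         D_hat = D_hat, alpha_hat = alpha_hat,
         alpha_star = clamp_alpha(alpha_hat),
         beta0_hat = if (method == "log_linear") beta0 else NA_real_,
         beta1_hat = if (method == "log_linear") beta1 else NA_real_,
         R2 = gof$R2, RSS = gof$RSS, TSS = gof$TSS, RMSE = gof$RMSE,
         n_points = n_pts, n_excluded = n_excluded,
         converged = converged, unfit = FALSE, unfit_reason = "none",
         diagnostic_space = diagnostic_space),
    class = "msd_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Goodness-of-fit of an anomalous diffusion model
#'
#' Evaluates a candidate model MSD = 4 D tau^alpha against an observed curve
#' in untransformed MSD space: residuals r_k = MSD_k - 4 D tau_k^alpha,
#' RSS = sum r_k^2, TSS = sum (MSD_k - mean(MSD))^2,
#' R2 = max(0, 1 - RSS/TSS), RMSE = sqrt(RSS / n).
#'
#' Two conventions make R2 well behaved on flat (mucoadhesive) curves:
#' when TSS is below `tss_floor` (an exactly constant curve) R2 is defined
#' as 0, and values of 1 - RSS/TSS below zero (a model worse than the
#' constant mean, possible when the model was not optimised in this space)
#' are reported as 0. Horizontal data therefore always score R2 ~ 0 while
#' their raw residual size remains visible in RSS and RMSE.
#'
#' @param curve An [msd_curve].
#' @param D,alpha Model parameters.
#' @param tss_floor TSS below which the curve counts as exactly flat,
#'   in (um^2)^2.
#' @return A list with `R2`, `RSS`, `TSS`, `RMSE`.
#' @export
goodness_of_fit <- function(curve, D, alpha, tss_floor = 1e-12) {
  stopifnot(inherits(curve, "msd_curve"))
  if (length(curve$lags) == 0L)
    stop("empty curve", call. = FALSE)
  pred <- 4 * D * curve$lags^alpha
  r <- curve$msd - pred
  RSS <- sum(r * r)
  TSS <- sum((curve$msd - mean(curve$msd))^2)
  R2 <- if (TSS > tss_floor) max(0, 1 - RSS / TSS) else 0
  list(R2 = R2, RSS = RSS, TSS = TSS, RMSE = sqrt(RSS / length(r)))
}

#' Clamp a fitted anomalous exponent at zero
#'
#' Fitted exponents can come out slightly negative for immobile particles;
#' such values are read as alpha = 0 (no dependence of MSD on lag time).
#'
#' @param alpha_hat Numeric vector of fitted exponents.
#' @return `pmax(0, alpha_hat)`.
#' @export
clamp_alpha <- function(alpha_hat) {
  pmax(0, alpha_hat)
}

#' @export
coef.msd_fit <- function(object, ...) {
  c(D = object$D_hat, alpha = object$alpha_hat)
}

#' @export
print.msd_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Anomalous diffusion fit (%s), video %s particle %s\n",
              x$method, x$curve$video_id, x$curve$particle_id))
  if (x$unfit) {
    cat("  unfit:", x$unfit_reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  MSD = 4 * %s * tau^%s   (alpha* = %s)\n",
              signif(x$D_hat, digits), signif(x$alpha_hat, digits),
              signif(x$alpha_star, digits)))
  cat(sprintf("  R2 = %s, RSS = %s (um^2)^2, RMSE = %s um^2 over %d points [%s space]\n",
              signif(x$R2, digits), signif(x$RSS, digits),
              signif(x$RMSE, digits), x$n_points, x$diagnostic_space))
  if (!x$converged) cat("  warning: optimizer did not converge\n")
  invisible(x)
}

#' @export
summary.msd_fit <- function(object, ...) {
  structure(list(fit = object,
                 transport_class = if (object$unfit) NA_character_
                                   else as.character(classify_transport(object$alpha_star))),
            class = "summary.msd_fit")
}

#' @export
print.summary.msd_fit <- function(x, ...) {
  print(x$fit)
  if (!is.na(x$transport_class))
    cat("  transport class:", x$transport_class, "\n")
  invisible(x)
}

#' @export
predict.msd_fit <- function(object, newlags = NULL, ...) {
  if (object$unfit) stop("cannot predict from an unfit particle", call. = FALSE)
  if (is.null(newlags)) newlags <- object$curve$lags
  4 * object$D_hat * newlags^object$alpha_hat
}

#' @export
fitted.msd_fit <- function(object, ...) predict(object)

#' @export
residuals.msd_fit <- function(object, ...) {
  object$curve$msd - predict(object)
}

#' @export
plot.msd_fit <- function(x, log = "xy", ...) {
  plot(x$curve$lags, x$curve$msd, log = log,
       xlab = "lag time (s)", ylab = expression(MSD ~ (mu * m^2)),
       main = sprintf("video %s / particle %s (%s)",
                      x$curve$video_id, x$curve$particle_id, x$method), ...)
  if (!x$unfit) {
    tau <- exp(seq(log(min(x$curve$lags)), log(max(x$curve$lags)),
                   length.out = 200))
    graphics::lines(tau, 4 * x$D_hat * tau^x$alpha_hat, lty = 2)
  }
  invisible(x)
}

#' Simulate new MSD curves from a fitted model
#'
#' Draws curves from the fitted power law on the observed lag grid, with
#' optional multiplicative log-normal noise of a given coefficient of
#' variation (the same noise model as [simulate_msd_curve()]).
#'
#' @param object An `msd_fit`.
#' @param nsim Number of curves.
#' @param seed Optional RNG seed.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param ... Unused.
#' @return A data frame with one column per simulated curve and the lag grid
#'   as row names.
#' @export
simulate.msd_fit <- function(object, nsim = 1, seed = NULL, noise_cv = 0, ...) {
  if (object$unfit) stop("cannot simulate from an unfit particle", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- predict(object)
  sims <- replicate(nsim, apply_lognormal_noise(m, noise_cv))
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- format(object$curve$lags)
  out
}

#' Fit every particle of a dataset
#'
#' Applies [msd_fit()] to each curve and collects per-particle records in a
#' data frame ready for screening. When the metadata carries a reference
#' diffusion coefficient the D/D_ref ratio is included; when `short_lag` is
#' given, a second fit on the curve trimmed to `short_lag` provides
#' `D_short` and the diffusivity factor `DF = D / D_short`.
#'
#' @param ds A [track_dataset].
#' @param method Passed to [msd_fit()].
#' @param short_lag Optional short lag-time window (s) for `D_short`/`DF`.
#' @param ... Further arguments passed to [msd_fit()].
#' @return A data frame of class `msd_fit_table`: one row per particle with
#'   columns `video_id`, `particle_id`, `n_segments`, `D`, `alpha_hat`,
#'   `alpha_star`, `beta0_hat`, `beta1_hat`, `R2`, `RSS`, `TSS`, `RMSE`,
#'   `converged`, `unfit`, `unfit_reason`, and optionally `D_over_Dref`,
#'   `D_short`, `DF`.
#' @export
fit_dataset <- function(ds, method = c("log_linear", "nonlinear"),
                        short_lag = NULL, ...) {
  stopifnot(inherits(ds, "track_dataset"))
  method <- match.arg(method)
  fits <- lapply(ds$curves, msd_fit, method = method, ...)
  rec <- data.frame(
    video_id = vapply(ds$curves, `[[`, character(1), "video_id"),
    particle_id = vapply(ds$curves, `[[`, character(1), "particle_id"),
    n_segments = vapply(ds$curves, length, integer(1)),
    D = vapply(fits, `[[`, numeric(1), "D_hat"),
    alpha_hat = vapply(fits, `[[`, numeric(1), "alpha_hat"),
    alpha_star = vapply(fits, `[[`, numeric(1), "alpha_star"),
    beta0_hat = vapply(fits, `[[`, numeric(1), "beta0_hat"),
    beta1_hat = vapply(fits, `[[`, numeric(1), "beta1_hat"),
    R2 = vapply(fits, `[[`, numeric(1), "R2"),
    RSS = vapply(fits, `[[`, numeric(1), "RSS"),
    TSS = vapply(fits, `[[`, numeric(1), "TSS"),
    RMSE = vapply(fits, `[[`, numeric(1), "RMSE"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    unfit = vapply(fits, `[[`, logical(1), "unfit"),
    unfit_reason = vapply(fits, `[[`, character(1), "unfit_reason"),
    stringsAsFactors = FALSE)
  if (!is.null(ds$metadata$reference_D))
    rec$D_over_Dref <- rec$D / ds$metadata$reference_D
  if (!is.null(short_lag)) {
    ds_short <- lapply(ds$curves, trim_to_lag, lag_max = short_lag)
    fshort <- lapply(ds_short, function(cu) {
      if (length(cu$lags) < 3L) return(NA_real_)
      f <- msd_fit(cu, method = method, ...)
      if (f$unfit) NA_real_ else f$D_hat
    })
    rec$D_short <- unlist(fshort)
    rec$DF <- rec$D / rec$D_short
  }
  class(rec) <- c("msd_fit_table", "data.frame")
  rec
}
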