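#' Time-averaged MSD of a 2-D position track
#'
#' Computes the time-averaged mean squared displacement with overlapping
#' windows, the standard estimator in particle tracking: for lag k * dt,
#'
#'   MSD_k = mean over all pairs (t, t + k dt) of
#'           (x(t + k dt) - x(t))^2 + (y(t + k dt) - y(t))^2.
#'
#' The track must be uniformly sampled (frame interval inferred from the
#' time stamps; deviations above 1e-6 s are an error).
#'
#' @param track A [position_track].
#' @param max_lag Largest lag time to evaluate (s). Defaults to the full
#'   track duration.
#' @return An [msd_curve] with the track's identifiers.
#' @examples
#' tr <- position_track(0:3, x = 0:3, y = rep(0, 4))
#' time_averaged_msd(tr)  # msd = 1, 4, 9 um^2 at lags 1, 2, 3 s
#' @export
time_averaged_msd <- function(track, max_lag = NULL) {
  stopifnot(inherits(track, "position_track"))
  dts <- diff(track$times)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6))
    stop("track is not uniformly sampled (tolerance 1e-6 s)", call. = FALSE)
  n <- length(track$times)
  if (is.null(max_lag)) max_lag <- (n - 1) * dt
  if (max_lag < dt)
    stop("'max_lag' must be at least one frame interval", call. = FALSE)
  K <- min(n - 1L, floor(max_lag / dt + 1e-9))
  msd <- vapply(seq_len(K), function(k) {
    dx <- track$x[(1 + k):n] - track$x[1:(n - k)]
    dy <- track$y[(1 + k):n] - track$y[1:(n - k)]
    mean(dx * dx + dy * dy)
  }, numeric(1))
  msd_curve(lags = seq_len(K) * dt, msd = msd,
            video_id = track$video_id, particle_id = track$particle_id)
}

#' Trim an MSD curve to a maximum lag time
#'
#' Long lags are supported by few displacement pairs and carry large
#' statistical error, so curves are conventionally cut at a lag-time
#' threshold (1 s by default) before fitting. The boundary is inclusive
#' (within 1e-9 s).
#'
#' @param curve An [msd_curve].
#' @param lag_max Largest lag time retained, in seconds.
#' @return An [msd_curve]; possibly with zero points, in which case a plain
#'   empty structure is returned (downstream minimum-segment filtering
#'   governs such curves).
#' @export
trim_to_lag <- function(curve, lag_max = 1.0) {
  stopifnot(inherits(curve, "msd_curve"))
  keep <- curve$lags <= lag_max + 1e-9
  if (!any(keep)) {
    out <- curve
    out$lags <- numeric(0)
    out$msd <- numeric(0)
    return(out)
  }
  out <- curve
  out$lags <- curve$lags[keep]
  out$msd <- curve$msd[keep]
  out
}

#' Prototype (median) particle of a set of curves
#'
#' Builds the virtual particle whose MSD at each lag is the median of the
#' MSDs of all curves observed at that lag. With ragged curves the median at
#' a given lag uses only the curves that reach it, mirroring the decreasing
#' number of trajectories at long lags. Even counts use the midpoint of the
#' two central values.
#'
#' @param curves A list of [msd_curve] objects (e.g. one video's curves) or
#'   a [track_dataset].
#' @param video_id Identifier given to the returned curve; defaults to the
#'   first input curve's video.
#' @return An [msd_curve] with `particle_id` `"0"`.
#' @export
prototype_particle <- function(curves, video_id = NULL) {
  if (inherits(curves, "track_dataset")) curves <- curves$curves
  if (!is.list(curves) || length(curves) == 0L)
    stop("'curves' must be a non-empty list of msd_curve objects", call. = FALSE)
  stopifnot(all(vapply(curves, inherits, logical(1), "msd_curve")))
  # group on lag values rounded to 1e-9 s so identical grids match exactly
  lag_all <- unlist(lapply(curves, `[[`, "lags"))
  msd_all <- unlist(lapply(curves, `[[`, "msd"))
  key <- round(lag_all / 1e-9)
  med <- tapply(msd_all, key, stats::median)
  lag_rep <- tapply(lag_all, key, `[`, 1L)
  ord <- order(lag_rep)
  if (is.null(video_id)) video_id <- curves[[1]]$video_id
  msd_curve(lags = as.numeric(lag_rep[ord]), msd = as.numeric(med[ord]),
            video_id = video_id, particle_id = "0")
}
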