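#' Experiment metadata
#'
#' Holds the sample-level information that accompanies a set of MSD curves:
#' the sample name, the reference diffusion coefficient measured in a simple
#' medium (water or saline, used for the D/D_ref ratio), the camera frame
#' interval, and optionally the diffusion coefficient of a mucodiffusive
#' control.
#'
#' @param sample_name Character scalar.
#' @param reference_D Reference diffusion coefficient D_ref in um^2/s
#'   (must be > 0).
#' @param frame_interval Time between frames in seconds (must be > 0).
#' @param control_D Optional diffusion coefficient of a mucodiffusive control,
#'   um^2/s.
#' @param notes Optional free-text notes.
#' @return An object of class `pt_metadata`.
#' @examples
#' pt_metadata("nanoemulsion", reference_D = 2, frame_interval = 0.01)
#' @export
pt_metadata <- function(sample_name, reference_D, frame_interval,
                        control_D = NULL, notes = NULL) {
  stopifnot(is.character(sample_name), length(sample_name) == 1L)
  reference_D <- as.numeric(reference_D)
  frame_interval <- as.numeric(frame_interval)
  if (!is.finite(reference_D) || reference_D <= 0)
    stop("'reference_D' must be a positive number (um^2/s)", call. = FALSE)
  if (!is.finite(frame_interval) || frame_interval <= 0)
    stop("'frame_interval' must be a positive number (s)", call. = FALSE)
  if (!is.null(control_D)) {
    control_D <- as.numeric(control_D)
    if (!is.finite(control_D) || control_D <= 0)
      stop("'control_D' must be a positive number (um^2/s)", call. = FALSE)
  }
  structure(
    list(sample_name = sample_name, reference_D = reference_D,
         frame_interval = frame_interval, control_D = control_D,
         notes = notes),
    class = "pt_metadata"
  )
}

#' @export
print.pt_metadata <- function(x, ...) {
  cat("Particle-tracking metadata\n")
  cat("  sample:         ", x$sample_name, "\n")
  cat("  reference D:    ", x$reference_D, "um^2/s\n")
  cat("  frame interval: ", x$frame_interval, "s\n")
  if (!is.null(x$control_D)) cat("  control D:      ", x$control_D, "um^2/s\n")
  if (!is.null(x$notes)) cat("  notes:          ", x$notes, "\n")
  invisible(x)
}

#' One particle's MSD-versus-lag-time curve
#'
#' The elementary data object of the analysis: an ordered series of
#' (lag time, MSD) pairs for one trajectory `j` in one video `i`. Lag times
#' are in seconds and strictly increasing; MSD values are in um^2 and
#' non-negative. The number of points is the number of segments n_ij of the
#' trajectory.
#'
#' @param lags Numeric vector of lag times tau in seconds, strictly
#'   increasing, all > 0.
#' @param msd Numeric vector of MSD values in um^2, same length as `lags`,
#'   all >= 0.
#' @param video_id Video (movie) identifier.
#' @param particle_id Particle (trajectory) identifier within the video.
#' @return An object of class `msd_curve`.
#' @examples
#' msd_curve(lags = (1:10) / 100, msd = 4 * 0.5 * ((1:10) / 100)^0.8)
#' @export
msd_curve <- function(lags, msd, video_id = "v1", particle_id = 1L) {
  lags <- as.numeric(lags)
  msd <- as.numeric(msd)
  if (length(lags) != length(msd))
    stop("'lags' and 'msd' must have the same length", call. = FALSE)
  if (length(lags) < 1L)
    stop("an MSD curve needs at least one point", call. = FALSE)
  if (anyNA(lags) || anyNA(msd))
    stop("'lags' and 'msd' must not contain NA", call. = FALSE)
  if (any(lags <= 0))
    stop("all lag times must be > 0", call. = FALSE)
  if (any(diff(lags) <= 0))
    stop("'lags' must be strictly increasing", call. = FALSE)
  if (any(msd < 0))
    stop("all MSD values must be >= 0", call. = FALSE)
  structure(
    list(video_id = as.character(video_id),
         particle_id = as.character(particle_id),
         lags = lags, msd = msd),
    class = "msd_curve"
  )
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve: video %s, particle %s, %d segments, lag %.4g-%.4g s\n",
              x$video_id, x$particle_id, length(x$lags),
              min(x$lags), max(x$lags)))
  invisible(x)
}

#' @export
length.msd_curve <- function(x) length(x$lags)

#' @export
as.data.frame.msd_curve <- function(x, ...) {
  data.frame(video_id = x$video_id, particle_id = x$particle_id,
             lag_s = x$lags, msd_um2 = x$msd, stringsAsFactors = FALSE)
}

#' Raw 2-D particle positions
#'
#' A time-ordered (t, x, y) trajectory from which a time-averaged MSD curve
#' can be computed. Positions are in micrometres, times in seconds.
#'
#' @param times Strictly increasing numeric vector of times (s).
#' @param x,y Numeric position vectors (um), same length as `times`.
#' @param video_id,particle_id Identifiers.
#' @return An object of class `position_track`.
#' @export
position_track <- function(times, x, y, video_id = "v1", particle_id = 1L) {
  times <- as.numeric(times); x <- as.numeric(x); y <- as.numeric(y)
  n <- length(times)
  if (length(x) != n || length(y) != n)
    stop("'times', 'x' and 'y' must have the same length", call. = FALSE)
  if (n < 2L)
    stop("a position track needs at least 2 points", call. = FALSE)
  if (anyNA(times) || anyNA(x) || anyNA(y))
    stop("positions must not contain NA", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  structure(
    list(video_id = as.character(video_id),
         particle_id = as.character(particle_id),
         times = times, x = x, y = y),
    class = "position_track"
  )
}

#' @export
print.position_track <- function(x, ...) {
  cat(sprintf("Position track: video %s, particle %s, %d frames over %.4g s\n",
              x$video_id, x$particle_id, length(x$times),
              max(x$times) - min(x$times)))
  invisible(x)
}

#' A collection of MSD curves with metadata
#'
#' Groups the curves of an experiment (videos i = 1..I, trajectories
#' j = 1..m_i) together with the sample metadata. (video_id, particle_id)
#' pairs must be unique.
#'
#' @param curves List of [msd_curve] objects.
#' @param metadata A [pt_metadata] object.
#' @return An object of class `track_dataset`.
#' @export
track_dataset <- function(curves, metadata) {
  if (!inherits(metadata, "pt_metadata"))
    stop("'metadata' must be a pt_metadata object", call. = FALSE)
  if (!is.list(curves) || !all(vapply(curves, inherits, logical(1), "msd_curve")))
    stop("'curves' must be a list of msd_curve objects", call. = FALSE)
  ids <- vapply(curves, function(cu) paste(cu$video_id, cu$particle_id, sep = "\r"),
                character(1))
  if (anyDuplicated(ids))
    stop("duplicate (video_id, particle_id) pairs in dataset", call. = FALSE)
  structure(list(metadata = metadata, curves = curves), class = "track_dataset")
}

#' @export
print.track_dataset <- function(x, ...) {
  vids <- vapply(x$curves, `[[`, character(1), "video_id")
  cat(sprintf("Track dataset '%s': %d curves in %d videos (reference D = %g um^2/s)\n",
              x$metadata$sample_name, length(x$curves),
              length(unique(vids)), x$metadata$reference_D))
  invisible(x)
}

#' @export
length.track_dataset <- function(x) length(x$curves)

#' @export
as.data.frame.track_dataset <- function(x, ...) {
  do.call(rbind, lapply(x$curves, as.data.frame))
}

# internal: video ids of all curves
dataset_video_ids <- function(ds) {
  vapply(ds$curves, `[[`, character(1), "video_id")
}
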