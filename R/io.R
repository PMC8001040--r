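#' Read an MSD dataset from a workbook or CSV pair
#'
#' Reads a long-format data table (columns `video_id`, `particle_id`,
#' `lag_s`, `msd_um2`) and a key/value metadata table into a
#' [track_dataset]. Two on-disk layouts are supported:
#'
#' * an `.xlsx` workbook with sheets `"data"` and `"metadata"` (requires the
#'   readxl package);
#' * a CSV pair: `path` is the data table and `metadata_path` (default:
#'   `<path-without-extension>_metadata.csv`) the metadata table with columns
#'   `key` and `value`.
#'
#' Recognised metadata keys: `sample_name`, `reference_D`, `frame_interval`,
#' `control_D`, `notes`, plus the optional unit declarations `lag_unit`
#' (`"s"`, `"ms"`) and `msd_unit` (`"um2"`, `"nm2"`); inputs are converted to
#' seconds and um^2 on read. `reference_D` and `frame_interval` are required.
#'
#' Rows whose MSD does not parse as a number are dropped (a message reports
#' the count); duplicate (video, particle, lag) triples are an error. Curves
#' are returned sorted by (video_id, particle_id, lag).
#'
#' @param path Path to the `.xlsx` workbook or the data CSV.
#' @param metadata_path Path to the metadata CSV (CSV layout only).
#' @return A [track_dataset].
#' @seealso [write_msd_dataset()] for the inverse operation.
#' @export
read_msd_workbook <- function(path, metadata_path = NULL) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx workbooks requires the 'readxl' package", call. = FALSE)
    sheets <- readxl::excel_sheets(path)
    if (!"data" %in% sheets)
      stop("workbook is missing the 'data' sheet", call. = FALSE)
    if (!"metadata" %in% sheets)
      stop("workbook is missing the 'metadata' sheet", call. = FALSE)
    dat <- as.data.frame(readxl::read_excel(path, sheet = "data",
                                            col_types = "text"))
    met <- as.data.frame(readxl::read_excel(path, sheet = "metadata",
                                            col_types = "text"))
  } else {
    if (is.null(metadata_path))
      metadata_path <- paste0(tools::file_path_sans_ext(path), "_metadata.csv")
    if (!file.exists(metadata_path))
      stop("metadata file not found (expected 'metadata' companion): ",
           metadata_path, call. = FALSE)
    dat <- utils::read.csv(path, colClasses = "character")
    met <- utils::read.csv(metadata_path, colClasses = "character")
  }
  build_track_dataset(dat, met)
}

# assemble and validate a track_dataset from raw character tables
build_track_dataset <- function(dat, met) {
  need <- c("video_id", "particle_id", "lag_s", "msd_um2")
  if (!all(need %in% names(dat)))
    stop("data table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(c("key", "value") %in% names(met)))
    stop("metadata table must have columns 'key' and 'value'", call. = FALSE)

  kv <- stats::setNames(as.list(met$value), met$key)
  for (k in c("reference_D", "frame_interval"))
    if (is.null(kv[[k]]))
      stop("metadata is missing required key '", k, "'", call. = FALSE)

  lag_scale <- switch(if (is.null(kv$lag_unit)) "s" else kv$lag_unit,
                      s = 1, ms = 1e-3,
                      stop("unknown lag_unit: ", kv$lag_unit, call. = FALSE))
  msd_scale <- switch(if (is.null(kv$msd_unit)) "um2" else kv$msd_unit,
                      um2 = 1, nm2 = 1e-6,
                      stop("unknown msd_unit: ", kv$msd_unit, call. = FALSE))

  meta <- pt_metadata(
    sample_name = if (is.null(kv$sample_name)) "sample" else kv$sample_name,
    reference_D = suppressWarnings(as.numeric(kv$reference_D)),
    frame_interval = suppressWarnings(as.numeric(kv$frame_interval)) * lag_scale,
    control_D = if (is.null(kv$control_D)) NULL
                else suppressWarnings(as.numeric(kv$control_D)),
    notes = kv$notes
  )

  lag <- suppressWarnings(as.numeric(dat$lag_s)) * lag_scale
  msd <- suppressWarnings(as.numeric(dat$msd_um2)) * msd_scale
  bad <- !is.finite(lag) | !is.finite(msd)
  if (any(bad)) {
    message(sum(bad), " row(s) with non-numeric lag or MSD rejected")
    dat <- dat[!bad, , drop = FALSE]
    lag <- lag[!bad]; msd <- msd[!bad]
  }
  key <- paste(dat$video_id, dat$particle_id, format(lag, digits = 15),
               sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (video, particle, lag) triple(s) in data table",
         call. = FALSE)

  ord <- order(dat$video_id, dat$particle_id, lag)
  dat <- dat[ord, , drop = FALSE]; lag <- lag[ord]; msd <- msd[ord]
  grp <- paste(dat$video_id, dat$particle_id, sep = "\r")
  idx <- split(seq_along(grp), factor(grp, levels = unique(grp)))
  curves <- lapply(idx, function(ii) {
    msd_curve(lag[ii], msd[ii], video_id = dat$video_id[ii[1]],
              particle_id = dat$particle_id[ii[1]])
  })
  names(curves) <- NULL
  track_dataset(curves, meta)
}

#' Write an MSD dataset as a CSV pair
#'
#' Writes the long-format data table and its metadata companion so that
#' [read_msd_workbook()] reproduces the dataset. Numeric values are written
#' with 17 significant digits, so doubles round-trip bit-exactly.
#'
#' @param ds A [track_dataset].
#' @param path Path of the data CSV; the metadata companion is written next
#'   to it as `<path-without-extension>_metadata.csv`.
#' @return Invisibly, the two paths written.
#' @export
write_msd_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "track_dataset"))
  dat <- as.data.frame(ds)
  dat$lag_s <- sprintf("%.17g", dat$lag_s)
  dat$msd_um2 <- sprintf("%.17g", dat$msd_um2)
  utils::write.csv(dat, path, row.names = FALSE, quote = FALSE)
  md <- ds$metadata
  keys <- c("sample_name", "reference_D", "frame_interval")
  vals <- c(md$sample_name,
            sprintf("%.17g", md$reference_D),
            sprintf("%.17g", md$frame_interval))
  if (!is.null(md$control_D)) {
    keys <- c(keys, "control_D"); vals <- c(vals, sprintf("%.17g", md$control_D))
  }
  if (!is.null(md$notes)) {
    keys <- c(keys, "notes"); vals <- c(vals, md$notes)
  }
  mpath <- paste0(tools::file_path_sans_ext(path), "_metadata.csv")
  utils::write.csv(data.frame(key = keys, value = vals), mpath,
                   row.names = FALSE)
  invisible(c(path, mpath))
}

#' Drop trajectories with too few segments
#'
#' Trajectories shorter than `min_segments` points are removed before
#' fitting; very short tracks are dominated by localisation noise and
#' linking artifacts. The default of 10 segments is the usual
#' particle-tracking minimum. Per-video removal counts are attached as the
#' `"removed_per_video"` attribute for reporting.
#'
#' @param ds A [track_dataset].
#' @param min_segments Minimum number of (lag, MSD) points per curve
#'   (inclusive).
#' @return A filtered [track_dataset]; may contain zero curves.
#' @export
filter_min_segments <- function(ds, min_segments = 10L) {
  stopifnot(inherits(ds, "track_dataset"))
  min_segments <- as.integer(min_segments)
  if (min_segments < 1L) stop("'min_segments' must be >= 1", call. = FALSE)
  n <- vapply(ds$curves, length, integer(1))
  keep <- n >= min_segments
  vids <- dataset_video_ids(ds)
  removed <- table(factor(vids[!keep], levels = sort(unique(vids))))
  out <- structure(list(metadata = ds$metadata, curves = ds$curves[keep]),
                   class = "track_dataset")
  attr(out, "removed_per_video") <- as.data.frame(removed,
                                                  responseName = "n_removed",
                                                  stringsAsFactors = FALSE)
  out
}

#' Write the per-particle results table
#'
#' One row per particle with fit estimates, diagnostics, transport class and
#' screening verdict, in the column order `video_id`, `particle_id`,
#' `n_segments`, `alpha_star`, `D`, `D_short`, `D_over_Dref`, `R2`, `RSS`,
#' `RMSE`, `transport_class`, `kept`, `discard_reason`. Only CSV output is
#' produced; the file re-reads losslessly with [utils::read.csv()].
#'
#' @param results Data frame of per-particle records (e.g. from
#'   [fit_dataset()] after [screen_particles()]).
#' @param path Output file path.
#' @param format Output format; `"csv"`.
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(results, path, format = c("csv")) {
  format <- match.arg(format)
  cols <- c("video_id", "particle_id", "n_segments", "alpha_star", "D",
            "D_short", "D_over_Dref", "R2", "RSS", "RMSE",
            "transport_class", "kept", "discard_reason")
  out <- data.frame(matrix(nrow = nrow(results), ncol = 0))
  for (cc in cols)
    out[[cc]] <- if (cc %in% names(results)) results[[cc]]
                 else rep(NA, nrow(results))
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), NA, format(v, digits = 15, trim = TRUE))
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
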