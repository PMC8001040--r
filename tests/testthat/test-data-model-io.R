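test_that("container constructors enforce their invariants", {
  expect_error(msd_curve(c(0.1, 0.1), c(1, 2)), "strictly increasing")
  expect_error(msd_curve(c(0.1, 0.2), c(1, -1)), ">= 0")
  expect_error(msd_curve(c(0, 0.1), c(1, 2)), "> 0")
  expect_error(msd_curve(0.1, c(1, 2)), "same length")
  expect_error(position_track(c(0, 0), c(0, 1), c(0, 1)), "strictly increasing")
  expect_error(position_track(0, 0, 0), "at least 2")
  expect_error(pt_metadata("s", reference_D = -1, frame_interval = 0.01),
               "reference_D")
  expect_error(pt_metadata("s", reference_D = 1, frame_interval = 0),
               "frame_interval")
  cu <- msd_curve(c(0.1, 0.2), c(1, 2), video_id = "v1", particle_id = 1)
  md <- pt_metadata("s", 2, 0.01)
  expect_error(track_dataset(list(cu, cu), md), "duplicate")
})

test_that("a toy workbook round-trips with exact counts and values", {
  ds <- toy_dataset(nv = 2, np = 3, nl = 10)
  expect_length(ds$curves, 6L)
  expect_true(all(vapply(ds$curves, length, integer(1)) == 10L))

  path <- file.path(withr::local_tempdir(), "toy.csv")
  write_msd_dataset(ds, path)
  ds2 <- read_msd_workbook(path)
  expect_length(ds2$curves, 6L)
  for (i in seq_along(ds$curves)) {
    expect_identical(ds2$curves[[i]]$lags, ds$curves[[i]]$lags)
    expect_identical(ds2$curves[[i]]$msd, ds$curves[[i]]$msd)
  }
  expect_equal(ds2$metadata$reference_D, ds$metadata$reference_D)
  expect_equal(ds2$metadata$frame_interval, ds$metadata$frame_interval)
  expect_identical(ds2$metadata$sample_name, ds$metadata$sample_name)
})

test_that("a simulated dataset round-trips bit-exactly through CSV", {
  mix <- simulate_mixture(mixture_spec(n_particles = 30, seed = 11))
  path <- file.path(withr::local_tempdir(), "mix.csv")
  write_msd_dataset(mix$dataset, path)
  ds2 <- read_msd_workbook(path)
  expect_length(ds2$curves, length(mix$dataset$curves))
  key <- function(cu) paste(cu$video_id, cu$particle_id)
  orig <- setNames(mix$dataset$curves,
                   vapply(mix$dataset$curves, key, character(1)))
  for (cu in ds2$curves) {
    expect_identical(cu$msd, orig[[key(cu)]]$msd)
    expect_identical(cu$lags, orig[[key(cu)]]$lags)
  }
})

test_that("reader rejects malformed inputs with informative errors", {
  dir <- withr::local_tempdir()
  dat <- data.frame(video_id = "v1", particle_id = 1,
                    lag_s = c(0.01, 0.02), msd_um2 = c(0.1, 0.2))
  write.csv(dat, file.path(dir, "d.csv"), row.names = FALSE)

  # no metadata companion at all
  expect_error(read_msd_workbook(file.path(dir, "d.csv")), "metadata")

  # metadata missing the required reference_D key
  write.csv(data.frame(key = "frame_interval", value = "0.01"),
            file.path(dir, "d_metadata.csv"), row.names = FALSE)
  expect_error(read_msd_workbook(file.path(dir, "d.csv")), "reference_D")

  # duplicate (video, particle, lag) triple
  write.csv(data.frame(key = c("reference_D", "frame_interval"),
                       value = c("2", "0.01")),
            file.path(dir, "d_metadata.csv"), row.names = FALSE)
  dup <- rbind(dat, dat[1, ])
  write.csv(dup, file.path(dir, "d.csv"), row.names = FALSE)
  expect_error(read_msd_workbook(file.path(dir, "d.csv")), "duplicate")

  # non-numeric MSD rows are dropped with a reported count
  bad <- dat
  bad$msd_um2 <- as.character(bad$msd_um2)
  bad$msd_um2[2] <- "not-a-number"
  write.csv(bad, file.path(dir, "d.csv"), row.names = FALSE)
  expect_message(ds <- read_msd_workbook(file.path(dir, "d.csv")),
                 "1 row")
  expect_length(ds$curves[[1]]$lags, 1L)
})

test_that("declared input units are converted to seconds and um^2", {
  dir <- withr::local_tempdir()
  dat <- data.frame(video_id = "v1", particle_id = 1,
                    lag_s = c(10, 20), msd_um2 = c(1e6, 2e6))
  write.csv(dat, file.path(dir, "d.csv"), row.names = FALSE)
  write.csv(data.frame(key = c("reference_D", "frame_interval",
                               "lag_unit", "msd_unit"),
                       value = c("2", "10", "ms", "nm2")),
            file.path(dir, "d_metadata.csv"), row.names = FALSE)
  ds <- read_msd_workbook(file.path(dir, "d.csv"))
  expect_equal(ds$curves[[1]]$lags, c(0.01, 0.02))
  expect_equal(ds$curves[[1]]$msd, c(1, 2))
  expect_equal(ds$metadata$frame_interval, 0.01)
})

test_that("minimum-segment filter keeps the boundary and is idempotent", {
  md <- pt_metadata("s", 2, 0.01)
  mk <- function(n, id) msd_curve(seq_len(n) * 0.01, rep(0.1, n),
                                  particle_id = id)
  ds <- track_dataset(list(mk(9, 1), mk(10, 2), mk(11, 3)), md)
  f <- filter_min_segments(ds, 10)
  expect_length(f$curves, 2L)
  expect_setequal(vapply(f$curves, `[[`, character(1), "particle_id"),
                  c("2", "3"))
  # identity at min_segments = 1
  expect_length(filter_min_segments(ds, 1)$curves, 3L)
  # idempotent
  f2 <- filter_min_segments(f, 10)
  expect_identical(lapply(f2$curves, `[[`, "msd"),
                   lapply(f$curves, `[[`, "msd"))
})

test_that("minimum-segment filter agrees with brute-force counting", {
  set.seed(77)
  md <- pt_metadata("s", 2, 0.01)
  lens <- pmax(1L, rgeom(500, 0.08))
  curves <- lapply(seq_along(lens), function(i) {
    msd_curve(seq_len(lens[i]) * 0.01, runif(lens[i]),
              video_id = sprintf("v%d", i %% 7), particle_id = i)
  })
  ds <- track_dataset(curves, md)
  f <- filter_min_segments(ds, 10)
  expect_identical(length(f$curves), sum(lens >= 10L))
  removed <- attr(f, "removed_per_video")
  expect_identical(sum(removed$n_removed), sum(lens < 10L))
})

test_that("results table export writes the documented schema", {
  dir <- withr::local_tempdir()
  rec <- data.frame(video_id = "v1", particle_id = as.character(1:3),
                    n_segments = 100L, alpha_star = c(0.1, 0.8, 1.0),
                    D = c(0.001, 0.5, 1.2), D_short = NA_real_,
                    D_over_Dref = c(5e-4, 0.25, 0.6),
                    R2 = c(0.02, 0.9, 0.95), RSS = c(0.01, 2, 3),
                    RMSE = c(0.01, 0.14, 0.17),
                    transport_class = c("immobile", "subdiffusive", "diffusive"),
                    kept = TRUE, discard_reason = "none",
                    stringsAsFactors = FALSE)
  path <- file.path(dir, "res.csv")
  write_results_table(rec, path)
  back <- read.csv(path)
  expect_identical(nrow(back), 3L)
  expect_identical(names(back)[1:3], c("video_id", "particle_id", "n_segments"))
  expect_equal(back$D, rec$D)
  expect_equal(back$R2, rec$R2)

  # degenerate: empty record set gives a header-only file
  write_results_table(rec[0, ], path)
  empty <- read.csv(path)
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("alpha_star", "kept") %in% names(empty)))
})
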