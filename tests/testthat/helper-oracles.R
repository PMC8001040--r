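# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities with naive double loops so they share no code with the
# package implementations they check.

# time-averaged MSD by explicit double loop over ordered frame pairs
brute_force_msd <- function(track, max_lag = NULL) {
  dt <- track$times[2] - track$times[1]
  n <- length(track$times)
  K <- n - 1L
  if (!is.null(max_lag)) K <- min(K, floor(max_lag / dt + 1e-9))
  msd <- numeric(K)
  for (k in seq_len(K)) {
    acc <- 0
    cnt <- 0L
    for (i in seq_len(n - k)) {
      acc <- acc + (track$x[i + k] - track$x[i])^2 +
        (track$y[i + k] - track$y[i])^2
      cnt <- cnt + 1L
    }
    msd[k] <- acc / cnt
  }
  list(lags = seq_len(K) * dt, msd = msd)
}

# per-lag median across curves, looping over every distinct lag value
brute_force_prototype <- function(curves) {
  all_lags <- sort(unique(unlist(lapply(curves, `[[`, "lags"))))
  med <- vapply(all_lags, function(l) {
    vals <- unlist(lapply(curves, function(cu) cu$msd[abs(cu$lags - l) < 1e-12]))
    stats::median(vals)
  }, numeric(1))
  list(lags = all_lags, msd = med)
}

# quick random fit-record table for screening property tests
random_fit_table <- function(n) {
  data.frame(
    video_id = "v1", particle_id = as.character(seq_len(n)),
    n_segments = 100L,
    D = rlnorm(n, log(0.1), 1),
    alpha_hat = runif(n, -0.2, 1.5),
    alpha_star = NA_real_,
    R2 = runif(n, 0, 1),
    RSS = rlnorm(n, log(2), 2),
    RMSE = NA_real_,
    unfit = runif(n) < 0.03,
    stringsAsFactors = FALSE
  ) -> f
  f$alpha_star <- pmax(0, f$alpha_hat)
  f$RMSE <- sqrt(f$RSS / f$n_segments)
  f
}

# small deterministic dataset: nv videos x np particles x nl lags
toy_dataset <- function(nv = 2, np = 3, nl = 10, reference_D = 2) {
  curves <- list()
  for (v in seq_len(nv)) for (p in seq_len(np)) {
    lags <- seq_len(nl) * 0.01
    curves[[length(curves) + 1L]] <-
      msd_curve(lags, 4 * 0.1 * (v + p) * lags^0.8,
                video_id = paste0("v", v), particle_id = p)
  }
  track_dataset(curves, pt_metadata("toy", reference_D = reference_D,
                                    frame_interval = 0.01))
}
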