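mk_fits <- function(R2, RSS, alpha = 0.8, unfit = FALSE) {
  n <- max(length(R2), length(RSS))
  data.frame(video_id = "v", particle_id = as.character(seq_len(n)),
             n_segments = 100L, D = 0.1, alpha_hat = alpha,
             alpha_star = pmax(0, alpha), R2 = R2, RSS = RSS,
             RMSE = sqrt(RSS / 100), unfit = unfit,
             stringsAsFactors = FALSE)
}

test_that("conventional screening applies the R2 and alpha rules", {
  out <- screen_conventional(mk_fits(c(0.95, 0.4), c(1, 1)), r2_min = 0.5)
  expect_identical(out$n_kept, 1L)
  expect_identical(out$records$discard_reason, c("none", "low_r2"))

  # r2_min = 0 keeps every alpha-valid particle
  f <- random_fit_table(200)
  all_in <- screen_conventional(f, r2_min = 0)
  expect_identical(all_in$n_kept,
                   sum(!f$unfit & f$alpha_star <= 1.1))
})

test_that("combined screening keeps flat low-residual particles", {
  fits <- mk_fits(R2 = c(0.05, 0.2, 0.95), RSS = c(0.3, 20, 8))
  out <- screen_combined(fits, r2_min = 0.5, rss_max = 5)
  # mucoadhesive-like: terrible R2 but tiny residuals -> kept
  # erratic: fails both -> discarded
  # diffusive: kept through the R2 branch despite RSS > 5
  expect_identical(out$records$kept, c(TRUE, FALSE, TRUE))
  expect_identical(out$records$discard_reason[2], "erratic_high_rss")
})

test_that("alpha validity is strict above the threshold and keeps immobile", {
  fits <- mk_fits(rep(0.9, 3), rep(0.1, 3), alpha = c(1.2, 1.1, 0))
  out <- screen_combined(fits)
  expect_identical(out$records$kept, c(FALSE, TRUE, TRUE))
  expect_identical(out$records$discard_reason[1], "alpha_superdiffusive")
  expect_identical(alpha_validity_filter(c(1.2, 1.1, 0)), c(TRUE, FALSE, FALSE))
})

test_that("unfit particles are excluded from both schemes and counted", {
  fits <- mk_fits(c(0.9, NA), c(0.1, NA), unfit = c(FALSE, TRUE))
  fits$alpha_star[2] <- NA
  for (mode in c("conventional", "combined")) {
    out <- screen_particles(fits, screening_config(mode = mode))
    expect_identical(out$records$discard_reason[2], "unfit")
    expect_identical(out$n_kept, 1L)
  }
})

test_that("retention percentages match published table arithmetic", {
  expect_equal(retention_percentage(6681, 6965), 95.9)
  expect_equal(retention_percentage(1113, 1167), 95.4)
  expect_equal(retention_percentage(0, 100), 0)
  expect_error(retention_percentage(1, 0), "n_total")
  expect_error(retention_percentage(5, 3), "between")
})

test_that("empty fit sets yield an outcome with undefined retention", {
  out <- screen_combined(mk_fits(0.9, 1)[0, ])
  expect_identical(out$n_total, 0L)
  expect_true(is.nan(out$retention_pct))
})

test_that("conventional-kept is always a subset of combined-kept", {
  set.seed(404)
  for (i in 1:50) {
    f <- random_fit_table(sample(20:200, 1))
    cfg_args <- list(r2_min = runif(1, 0, 0.95), rss_max = rlnorm(1, log(3), 1))
    conv <- do.call(screen_conventional, c(list(f), cfg_args))
    comb <- do.call(screen_combined, c(list(f), cfg_args))
    expect_true(all(!conv$records$kept | comb$records$kept))
    expect_gte(comb$retention_pct, conv$retention_pct)
    # strict_and is the most restrictive of the three
    strict <- screen_particles(f, do.call(screening_config,
                                          c(cfg_args, mode = "strict_and")))
    expect_true(all(!strict$records$kept | conv$records$kept))
  }
})

test_that("retention is monotone in the thresholds", {
  set.seed(17)
  f <- random_fit_table(300)
  conv_ret <- vapply(seq(0, 0.9, 0.1), function(t)
    screen_conventional(f, r2_min = t)$retention_pct, numeric(1))
  expect_true(all(diff(conv_ret) <= 0))
  comb_ret_r2 <- vapply(seq(0, 0.9, 0.1), function(t)
    screen_combined(f, r2_min = t)$retention_pct, numeric(1))
  expect_true(all(diff(comb_ret_r2) <= 0))
  comb_ret_rss <- vapply(c(0.1, 1, 5, 20, 100), function(m)
    screen_combined(f, rss_max = m)$retention_pct, numeric(1))
  expect_true(all(diff(comb_ret_rss) >= 0))
})

test_that("discard reasons account for every particle", {
  set.seed(23)
  f <- random_fit_table(250)
  for (mode in c("conventional", "combined", "strict_and")) {
    out <- screen_particles(f, screening_config(mode = mode))
    expect_identical(out$n_kept + sum(out$records$discard_reason != "none"),
                     out$n_total)
  }
})

test_that("the RSS threshold can be applied to RMSE instead", {
  fits <- mk_fits(R2 = c(0.1, 0.1), RSS = c(4, 4))
  fits$RMSE <- c(0.05, 0.5)
  out <- screen_particles(fits, screening_config(rss_max = 0.1,
                                                 rss_metric = "rmse"))
  expect_identical(out$records$kept, c(TRUE, FALSE))
})

test_that("threshold sweep reproduces the screening-table structure", {
  set.seed(99)
  mix <- simulate_mixture(mixture_spec(n_particles = 250, seed = 5))
  fits <- fit_dataset(mix$dataset)
  sw <- threshold_sweep(fits, r2_grid = seq(0, 0.9, 0.1),
                        config = screening_config())
  expect_identical(nrow(sw), 11L)
  expect_identical(sw$approach[11], "R2 + RSS")
  # the 0.0 row is the unscreened population
  expect_identical(sw$retention_pct[1],
                   retention_percentage(sum(!fits$unfit & fits$alpha_star <= 1.1),
                                        nrow(fits)))
  # combined keeps at least as many as any conventional row
  expect_true(all(sw$n_kept[11] >= sw$n_kept[2:10]))
  # retention never increases along the grid
  expect_true(all(diff(sw$retention_pct[1:10]) <= 0))

  # single-point grid at 0 reports the full population
  sw0 <- threshold_sweep(fits, r2_grid = 0)
  expect_identical(sw0$n_kept[1], sum(!fits$unfit & fits$alpha_star <= 1.1))
})
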