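#' Specification of one simulated MSD curve
#'
#' Parameters of the generative model for a single particle's MSD curve:
#' a power law MSD = 4 D tau^alpha observed on a regular lag grid, a
#' "stop-diffusing" lag beyond which the MSD plateaus at its stop-lag value,
#' and multiplicative log-normal observation noise of a given coefficient of
#' variation.
#'
#' @param D_true Diffusion coefficient, um^2/s (> 0).
#' @param alpha_true Anomalous exponent (>= 0).
#' @param n_lags Number of lag points (>= 3).
#' @param dt Lag spacing in seconds (> 0).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0; 0 = noiseless).
#' @param stop_lag Lag (s) beyond which the particle stops diffusing and the
#'   clean MSD stays constant; `Inf` for no plateau.
#' @param seed Optional integer seed making the curve reproducible.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(D_true = 0.1, alpha_true = 0.8, n_lags = 100L,
                     dt = 0.01, noise_cv = 0.05, stop_lag = Inf,
                     seed = NULL) {
  stopifnot(D_true > 0, alpha_true >= 0, n_lags >= 3L, dt > 0,
            noise_cv >= 0, stop_lag > 0)
  structure(list(D_true = D_true, alpha_true = alpha_true,
                 n_lags = as.integer(n_lags), dt = dt, noise_cv = noise_cv,
                 stop_lag = stop_lag, seed = seed),
            class = "sim_spec")
}

# multiplicative log-normal noise with unit mean and coefficient of
# variation cv: m * exp(sigma Z - sigma^2/2), sigma^2 = log(1 + cv^2)
apply_lognormal_noise <- function(m, cv) {
  if (cv <= 0) return(m)
  sigma <- sqrt(log(1 + cv^2))
  m * exp(stats::rnorm(length(m), mean = -sigma^2 / 2, sd = sigma))
}

#' Simulate one MSD curve
#'
#' Draws an MSD curve from a [sim_spec]: clean values
#' `4 * D_true * min(tau, stop_lag)^alpha_true` on the lag grid, times
#' multiplicative log-normal noise with unit mean. The returned truth record
#' carries all generative parameters for label-aware testing.
#'
#' @param spec A [sim_spec].
#' @param video_id,particle_id Identifiers for the generated curve.
#' @return A list with elements `curve` ([msd_curve]) and `truth` (one-row
#'   data frame).
#' @examples
#' sim <- simulate_msd_curve(sim_spec(D_true = 0.5, alpha_true = 1,
#'                                    noise_cv = 0, seed = 1))
#' sim$curve
#' @export
simulate_msd_curve <- function(spec, video_id = "sim", particle_id = 1L) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  lags <- seq_len(spec$n_lags) * spec$dt
  clean <- 4 * spec$D_true * pmin(lags, spec$stop_lag)^spec$alpha_true
  obs <- apply_lognormal_noise(clean, spec$noise_cv)
  truth <- data.frame(video_id = as.character(video_id),
                      particle_id = as.character(particle_id),
                      D_true = spec$D_true, alpha_true = spec$alpha_true,
                      noise_cv = spec$noise_cv, stop_lag = spec$stop_lag,
                      stringsAsFactors = FALSE)
  list(curve = msd_curve(lags, obs, video_id = video_id,
                         particle_id = particle_id),
       truth = truth)
}

# fractional Gaussian noise by Davies-Harte circulant embedding.
# n values with Hurst exponent H and unit step variance.
fgn_davies_harte <- function(n, H) {
  stopifnot(n >= 1, H > 0, H < 1)
  k <- 0:n
  g <- 0.5 * ((k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
  circ <- c(g, g[n:2])                     # length 2n, circulant first row
  lam <- Re(stats::fft(circ))
  if (min(lam) < -1e-8 * max(lam))
    warning("circulant embedding not nonnegative definite; clipping")
  lam <- pmax(lam, 0)
  m <- 2L * n
  w <- complex(length.out = m)
  w[1] <- sqrt(lam[1]) * stats::rnorm(1)
  w[n + 1] <- sqrt(lam[n + 1]) * stats::rnorm(1)
  if (n > 1) {
    j <- 2:n
    zr <- stats::rnorm(n - 1)
    zi <- stats::rnorm(n - 1)
    w[j] <- sqrt(lam[j] / 2) * complex(real = zr, imaginary = zi)
    w[m - j + 2] <- Conj(w[j])
  }
  x <- Re(stats::fft(w)) / sqrt(m)
  x[seq_len(n)]
}

#' Simulate a 2-D fractional Brownian track
#'
#' Generates a position track whose per-axis displacement process is
#' fractional Brownian motion with Hurst exponent H = alpha_true / 2,
#' scaled so the ensemble MSD at lag tau equals 4 D_true tau^alpha_true
#' (2 D_true tau^alpha_true per axis). alpha_true = 1 gives an ordinary
#' Brownian track. Increments are generated by Davies-Harte circulant
#' embedding, so long tracks are cheap.
#'
#' @param D_true Diffusion coefficient, um^2/s.
#' @param alpha_true Anomalous exponent in (0, 2).
#' @param n_steps Number of steps (track has `n_steps + 1` frames).
#' @param dt Frame interval, s.
#' @param seed Optional integer seed.
#' @param video_id,particle_id Identifiers.
#' @return A [position_track] starting at the origin at t = 0.
#' @export
simulate_track_2d <- function(D_true, alpha_true, n_steps, dt = 0.01,
                              seed = NULL, video_id = "sim",
                              particle_id = 1L) {
  if (!(alpha_true > 0 && alpha_true < 2))
    stop("'alpha_true' must be in (0, 2)", call. = FALSE)
  stopifnot(D_true >= 0, n_steps >= 1, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  H <- alpha_true / 2
  scale <- sqrt(2 * D_true * dt^alpha_true)  # per-axis step std deviation
  dx <- scale * fgn_davies_harte(n_steps, H)
  dy <- scale * fgn_davies_harte(n_steps, H)
  position_track(times = (0:n_steps) * dt,
                 x = c(0, cumsum(dx)), y = c(0, cumsum(dy)),
                 video_id = video_id, particle_id = particle_id)
}

#' Default mixture components
#'
#' The three trajectory populations of the default simulated experiment.
#' Each component draws per-particle parameters from the given ranges
#' (log-normal for D, uniform for the rest), emulating the heterogeneity of
#' a real formulation:
#'
#' * `diffusive` — mobile particles, alpha near 1, D of the order of the
#'   reference medium;
#' * `adhesive` — mucus-trapped particles: D about three orders of magnitude
#'   below the reference, nearly flat curves (small alpha) that stop
#'   diffusing within the observation window — near-zero R2 but tiny RSS;
#' * `erratic` — experimental artifacts: very large observation noise, so
#'   both R2 and RSS screening criteria fail.
#'
#' @return Named list of component parameter sets.
#' @export
default_mixture_components <- function() {
  list(
    diffusive = list(D_meanlog = log(1.0), D_sdlog = 0.5,
                     alpha_range = c(0.45, 1.05),
                     noise_cv_range = c(0.1, 0.3),
                     stop_lag_range = c(Inf, Inf)),
    adhesive = list(D_meanlog = log(0.002), D_sdlog = 0.7,
                    alpha_range = c(0, 0.25),
                    noise_cv_range = c(0.1, 0.4),
                    stop_lag_range = c(0.1, 0.5)),
    erratic = list(D_meanlog = log(0.5), D_sdlog = 0.5,
                   alpha_range = c(0.3, 1.1),
                   noise_cv_range = c(1.2, 2.5),
                   stop_lag_range = c(Inf, Inf))
  )
}

#' Specification of a labelled mixed population
#'
#' Defines a simulated experiment: `n_particles` trajectories assigned to
#' the `diffusive` / `adhesive` / `erratic` components with the given
#' weights, spread over `n_videos` videos, all observed on the same lag
#' grid. Component parameter ranges default to
#' [default_mixture_components()].
#'
#' @param n_particles Number of trajectories (default 1200).
#' @param weights Named numeric weights over the three components; must sum
#'   to 1.
#' @param components Component parameter list.
#' @param n_videos Number of videos the particles are spread over.
#' @param n_lags,dt Lag grid (default 100 lags at 0.01 s, i.e. a 1 s curve
#'   at 100 fps).
#' @param reference_D Reference diffusion coefficient stored in the
#'   dataset's metadata, um^2/s.
#' @param seed Integer seed (default 1).
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(n_particles = 1200L,
                         weights = c(diffusive = 0.40, adhesive = 0.55,
                                     erratic = 0.05),
                         components = default_mixture_components(),
                         n_videos = 10L, n_lags = 100L, dt = 0.01,
                         reference_D = 2, seed = 1L) {
  stopifnot(n_particles >= 1L, n_videos >= 1L, n_lags >= 3L, dt > 0,
            reference_D > 0)
  if (!setequal(names(weights), c("diffusive", "adhesive", "erratic")))
    stop("'weights' must be named diffusive/adhesive/erratic", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("'weights' must sum to 1", call. = FALSE)
  structure(list(n_particles = as.integer(n_particles), weights = weights,
                 components = components, n_videos = as.integer(n_videos),
                 n_lags = as.integer(n_lags), dt = dt,
                 reference_D = reference_D, seed = as.integer(seed)),
            class = "mixture_spec")
}

#' Simulate a labelled mixed population
#'
#' Draws a full [track_dataset] from a [mixture_spec], together with the
#' per-particle ground-truth labels and generative parameters. Identical
#' specs (including the seed) produce bit-identical datasets.
#'
#' @param spec A [mixture_spec].
#' @return A list with elements `dataset` ([track_dataset]) and `labels`
#'   (data frame with `video_id`, `particle_id`, `label`, `D_true`,
#'   `alpha_true`, `noise_cv`, `stop_lag`).
#' @examples
#' mix <- simulate_mixture(mixture_spec(n_particles = 20, seed = 7))
#' table(mix$labels$label)
#' @export
simulate_mixture <- function(spec = mixture_spec()) {
  stopifnot(inherits(spec, "mixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_particles
  labels <- sample(names(spec$weights), n, replace = TRUE,
                   prob = as.numeric(spec$weights))
  vids <- sprintf("v%02d", 1L + (seq_len(n) - 1L) %% spec$n_videos)
  curves <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    cmp <- spec$components[[labels[i]]]
    D_i <- stats::rlnorm(1, cmp$D_meanlog, cmp$D_sdlog)
    a_i <- stats::runif(1, cmp$alpha_range[1], cmp$alpha_range[2])
    cv_i <- stats::runif(1, cmp$noise_cv_range[1], cmp$noise_cv_range[2])
    sl_i <- if (all(is.infinite(cmp$stop_lag_range))) Inf
            else stats::runif(1, cmp$stop_lag_range[1], cmp$stop_lag_range[2])
    s <- sim_spec(D_true = D_i, alpha_true = a_i, n_lags = spec$n_lags,
                  dt = spec$dt, noise_cv = cv_i, stop_lag = sl_i,
                  seed = NULL)
    sim <- simulate_msd_curve(s, video_id = vids[i],
                              particle_id = sprintf("p%04d", i))
    curves[[i]] <- sim$curve
    truth[[i]] <- cbind(sim$truth, label = labels[i],
                        stringsAsFactors = FALSE)
  }
  meta <- pt_metadata("simulated mixture", reference_D = spec$reference_D,
                      frame_interval = spec$dt)
  list(dataset = track_dataset(curves, meta),
       labels = do.call(rbind, truth))
}
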