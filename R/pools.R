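#' Match pool of candidate acoustic equivalents
#'
#' A pool of synthesized sounds (ripples or sound textures) together with the
#' per-member feature matrix used for nearest-neighbour matching. Ripple pools
#' use a 6-dimensional space (mean and SD of jitter, shimmer and spectral
#' flux); texture pools use a 2-dimensional space (mean and SD of the
#' harmonics-to-noise ratio). Features are z-scored over the pool plus the
#' probe before distances are computed, so the space is scale-free.
#'
#' @name match_pool
#' @return Objects of class `match_pool` with fields `kind`, `members`,
#'   `member_features` (matrix), and `params` (per-member sampled parameters).
NULL

new_match_pool <- function(kind, members, member_features, params) {
  stopifnot(nrow(member_features) == length(members))
  structure(list(kind = kind, members = members,
                 member_features = member_features, params = params),
            class = "match_pool")
}

#' @export
print.match_pool <- function(x, ...) {
  cat(sprintf("<match_pool %s: %d members, %d feature dims>\n", x$kind,
              length(x$members), ncol(x$member_features)))
  invisible(x)
}

#' Generate a pool of dynamic moving ripple sounds
#'
#' Each member is a broadband carrier (log-spaced tones with random phases)
#' whose per-component envelope follows a sinusoidal spectro-temporal
#' modulation with sampled velocity (temporal modulation rate, Hz), density
#' (spectral modulation, cycles/octave) and modulation depth. Parameters are
#' sampled log-uniformly (depth uniformly) from the given ranges.
#'
#' @param n Number of members (>= 1; the full-scale pool uses 10000).
#' @param velocity_range Temporal rate range in Hz (default `c(1, 30)`).
#' @param density_range Spectral density range in cyc/oct (default
#'   `c(0.25, 4)`).
#' @param depth_range Modulation depth range in `[0, 1]` (default
#'   `c(0.2, 1)`).
#' @param duration_ms,sample_rate Member duration and rate (500 ms, 16 kHz).
#' @param seed Integer seed.
#' @param n_carriers Number of carrier tones (default 40).
#' @return A `match_pool` of kind `"ripple"`.
#' @export
gen_ripple_pool <- function(n, velocity_range = c(1, 30),
                            density_range = c(0.25, 4),
                            depth_range = c(0.2, 1), duration_ms = 500,
                            sample_rate = 16000, seed = 1, n_carriers = 40) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  members <- vector("list", n)
  params <- matrix(NA_real_, n, 3,
                   dimnames = list(NULL, c("velocity", "density", "depth")))
  for (i in seq_len(n)) {
    vel <- exp(runif(1, log(velocity_range[1]), log(velocity_range[2])))
    den <- exp(runif(1, log(density_range[1]), log(density_range[2])))
    dep <- runif(1, depth_range[1], depth_range[2])
    params[i, ] <- c(vel, den, dep)
    x <- ripple_sound(vel, den, dep, duration_ms, sample_rate, n_carriers)
    members[[i]] <- finalize_sound(
      sound_token(x, sample_rate, "nonvoice", id = sprintf("rip%05d", i)))
  }
  feats <- t(vapply(members, pool_features_ripple, numeric(6)))
  new_match_pool("ripple", members, feats, params)
}

#' Synthesize one dynamic moving ripple
#'
#' @inheritParams gen_ripple_pool
#' @param velocity,density,depth Ripple parameters.
#' @return Numeric waveform with peak 0.9.
#' @export
ripple_sound <- function(velocity, density, depth, duration_ms = 500,
                         sample_rate = 16000, n_carriers = 40,
                         f_lo = 250, f_hi = 6000) {
  n <- round(duration_ms * sample_rate / 1000)
  t <- (seq_len(n) - 1) / sample_rate
  freqs <- exp(seq(log(f_lo), log(f_hi), length.out = n_carriers))
  x_oct <- log2(freqs / f_lo)
  phi <- runif(n_carriers, 0, 2 * pi)
  ripple_phase <- runif(1, 0, 2 * pi)
  x <- numeric(n)
  for (k in seq_len(n_carriers)) {
    env <- 1 + depth * sin(2 * pi * (velocity * t + density * x_oct[k]) +
                             ripple_phase)
    x <- x + env * sin(2 * pi * freqs[k] * t + phi[k]) / sqrt(n_carriers)
  }
  0.9 * x / max(abs(x))
}

#' Generate a pool of Gaussian sound textures (TSPs)
#'
#' Members are Gaussian-process textures on a time-by-frequency-band grid:
#' a log-envelope surface is drawn from a separable squared-exponential
#' Gaussian process with sampled temporal and spectral correlation lengths
#' (seconds and octaves, both log-uniform within `corr_range`), then rendered
#' by modulating band-limited noise in each band and summing. Member features
#' are the mean and SD of the harmonics-to-noise-ratio contour.
#'
#' @param n Number of members (>= 1; the full-scale pool uses 10000).
#' @param corr_range Correlation-length range, default `c(0.01, 2)`.
#' @param duration_ms,sample_rate Member duration and rate (500 ms, 16 kHz).
#' @param seed Integer seed.
#' @param n_bands,n_frames Envelope grid size (default 24 x 50).
#' @return A `match_pool` of kind `"tsp"`.
#' @export
gen_tsp_pool <- function(n, corr_range = c(0.01, 2), duration_ms = 500,
                         sample_rate = 16000, seed = 1, n_bands = 24,
                         n_frames = 50) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  members <- vector("list", n)
  params <- matrix(NA_real_, n, 2,
                   dimnames = list(NULL, c("temporal_corr", "spectral_corr")))
  dur_s <- duration_ms / 1000
  t_grid <- seq(0, dur_s, length.out = n_frames)
  b_grid <- seq(0, log2(6000 / 100), length.out = n_bands)
  for (i in seq_len(n)) {
    lt <- exp(runif(1, log(corr_range[1]), log(corr_range[2])))
    lb <- exp(runif(1, log(corr_range[1]), log(corr_range[2])))
    params[i, ] <- c(lt, lb)
    x <- tsp_sound(lt, lb, t_grid, b_grid, duration_ms, sample_rate)
    members[[i]] <- finalize_sound(
      sound_token(x, sample_rate, "nonvoice", id = sprintf("tsp%05d", i)))
  }
  feats <- t(vapply(members, pool_features_tsp, numeric(2)))
  new_match_pool("tsp", members, feats, params)
}

## Render one texture: separable GP log-envelope (chol of small covariances),
## applied to partition-of-unity band noises.
tsp_sound <- function(temporal_corr, spectral_corr, t_grid, b_grid,
                      duration_ms, sample_rate) {
  n <- round(duration_ms * sample_rate / 1000)
  Kt <- sq_exp_cov(t_grid, temporal_corr)
  Kb <- sq_exp_cov(b_grid, spectral_corr)
  G <- t(chol(Kb)) %*% matrix(rnorm(length(b_grid) * length(t_grid)),
                              length(b_grid)) %*% chol(Kt)
  env <- exp(0.8 * G)                      # bands x frames, positive envelope
  noise <- rnorm(n)
  bands <- band_split(noise, sample_rate, length(b_grid))
  x <- numeric(n)
  grid_t <- seq(0, 1, length.out = ncol(env))
  sample_t <- seq(0, 1, length.out = n)
  for (b in seq_along(bands)) {
    e <- approx(grid_t, env[b, ], xout = sample_t)$y
    x <- x + bands[[b]] * e
  }
  0.9 * x / max(abs(x))
}

sq_exp_cov <- function(g, len) {
  d <- outer(g, g, "-")
  exp(-d^2 / (2 * len^2)) + diag(1e-8, length(g))
}

pool_features_ripple <- function(token) {
  fv <- extract_features(token)
  unname(fv[c("jitter_mean", "jitter_sd", "shimmer_mean", "shimmer_sd",
              "flux_mean", "flux_sd")])
}

pool_features_tsp <- function(token) {
  fv <- extract_features(token)
  unname(fv[c("hnr_mean", "hnr_sd")])
}

#' Probe features in a pool's matching space
#'
#' @param token A `sound_token`.
#' @param pool A `match_pool`.
#' @return Numeric feature vector in the pool's space.
#' @export
pool_probe_features <- function(token, pool) {
  switch(pool$kind,
         ripple = pool_features_ripple(token),
         tsp = pool_features_tsp(token),
         stop("unknown pool kind"))
}

#' Select the best-matching pool member for an original sound
#'
#' Computes the original's features in the pool's matching space, z-scores
#' each dimension over the pool members plus the probe, and returns the member
#' with minimal Euclidean distance to the probe (ties broken by lowest member
#' index). The selected member is relabeled with the original's category and
#' source id.
#'
#' @param original A `sound_token` with `variant == "orig"`.
#' @param pool A `match_pool`.
#' @return A `sound_token` with variant `"rip"` or `"tsp"`.
#' @export
match_from_pool <- function(original, pool) {
  check_original(original)
  stopifnot(inherits(pool, "match_pool"), length(pool$members) >= 1)
  probe <- pool_probe_features(original, pool)
  all_f <- rbind(pool$member_features, probe)
  ctr <- colMeans(all_f)
  scl <- apply(all_f, 2, sd)
  scl[scl == 0] <- 1
  z <- sweep(sweep(all_f, 2, ctr), 2, scl, "/")
  zp <- z[nrow(z), ]
  d2 <- rowSums(sweep(z[-nrow(z), , drop = FALSE], 2, zp)^2)
  best <- unname(which.min(d2))                       # which.min = lowest index on ties
  m <- pool$members[[best]]
  variant <- if (pool$kind == "ripple") "rip" else "tsp"
  out <- ae_token(original, m$samples, variant)
  out$matched_member <- best
  out$match_distance <- sqrt(d2[best])
  out
}
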