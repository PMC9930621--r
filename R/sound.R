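#' @useDynLib vaparc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx fft qt pt rnorm runif sd var quantile setNames
#' @importFrom utils head tail
NULL

#' Sound token
#'
#' A fixed-duration mono waveform carrying the bookkeeping the pipeline needs:
#' its category (voice or nonvoice), its variant (`orig` or one of the five
#' acoustic-equivalent classes) and the id of the original token it derives
#' from. Original tokens are their own source.
#'
#' @param samples Numeric vector of samples in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz.
#' @param category `"voice"` or `"nonvoice"`.
#' @param variant One of `"orig"`, `"e_s"`, `"scr"`, `"p_a"`, `"rip"`, `"tsp"`.
#' @param id Token identifier.
#' @param source_id Identifier of the original the token derives from; defaults
#'   to `id` for originals.
#' @param flags Optional character vector of processing flags (e.g. an
#'   unvoiced-fallback warning).
#' @return An object of class `sound_token`.
#' @export
sound_token <- function(samples, sample_rate, category, variant = "orig",
                        id = "tok", source_id = NULL, flags = character()) {
  stopifnot(is.numeric(samples), length(samples) > 0L, sample_rate > 0)
  category <- match.arg(category, c("voice", "nonvoice"))
  variant <- match.arg(variant, va_variants())
  if (is.null(source_id)) {
    if (variant != "orig")
      stop("source_id must be given for acoustic-equivalent variants")
    source_id <- id
  }
  if (variant == "orig" && !identical(source_id, id))
    stop("an original token must be its own source (source_id == id)")
  if (max(abs(samples)) > 1 + 1e-9)
    stop("samples exceed full scale [-1, 1]")
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         duration_ms = 1000 * length(samples) / sample_rate,
         category = category, variant = variant, id = id,
         source_id = source_id, flags = flags),
    class = "sound_token")
}

#' @export
print.sound_token <- function(x, ...) {
  cat(sprintf("<sound_token %s: %s/%s, %.1f ms @ %g Hz, rms %.4f>\n",
              x$id, x$category, x$variant, x$duration_ms, x$sample_rate,
              rms(x$samples)))
  invisible(x)
}

#' Variant labels used throughout the package
#'
#' `"orig"` denotes the original recordings; the remaining five are the
#' acoustic-equivalent classes: envelope/spectrum (`e_s`), scrambled (`scr`),
#' pitch/amplitude (`p_a`), ripple (`rip`) and sound-texture (`tsp`).
#' @return Character vector of length 6.
#' @export
va_variants <- function() c("orig", "e_s", "scr", "p_a", "rip", "tsp")

#' AE variant labels (the five acoustic-equivalent classes)
#' @return Character vector of length 5.
#' @export
ae_variants <- function() setdiff(va_variants(), "orig")

#' The 12 experimental condition labels
#'
#' Six sound sets (original plus five acoustic equivalents) crossed with the
#' voice/nonvoice category, in the canonical order used by every beta array,
#' design matrix and contrast in the package.
#' @return Character vector of length 12, e.g. `"orig_voice"`.
#' @export
va_conditions <- function() {
  as.vector(t(outer(va_variants(), c("voice", "nonvoice"), paste, sep = "_")))
}

#' Root-mean-square amplitude
#' @param x Numeric vector or a `sound_token`.
#' @return RMS value.
#' @export
rms <- function(x) {
  if (inherits(x, "sound_token")) x <- x$samples
  sqrt(mean(x^2))
}

## Analytic-signal magnitude (Hilbert envelope) via the FFT construction.
hilbert_env <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

## Moving-average smoothing of an envelope with a window in ms.
smooth_env <- function(env, sample_rate, window_ms = 10) {
  w <- max(1L, round(window_ms * sample_rate / 1000))
  k <- rep(1 / w, w)
  as.numeric(stats::filter(c(rep(env[1], w), env, rep(env[length(env)], w)),
                           k, sides = 2))[(w + 1):(w + length(env))]
}

#' Amplitude envelope of a token
#'
#' Hilbert (analytic-signal) envelope, optionally smoothed with a moving
#' average.
#' @param token A `sound_token` or numeric vector.
#' @param sample_rate Required when `token` is a bare vector.
#' @param smooth_ms Moving-average window in ms (0 = no smoothing).
#' @return Numeric envelope, same length as the input.
#' @export
sound_envelope <- function(token, sample_rate = NULL, smooth_ms = 10) {
  if (inherits(token, "sound_token")) {
    x <- token$samples; sample_rate <- token$sample_rate
  } else x <- token
  env <- hilbert_env(x)
  if (smooth_ms > 0) env <- smooth_env(env, sample_rate, smooth_ms)
  env
}

## Digital reference: RMS 0.05 full scale corresponds to the 70 dB SPL
## presentation level; other levels scale by 10^((L - 70)/20).
REF_RMS_70DB <- 0.05

#' Finalize a sound token (ramps and presentation level)
#'
#' Applies raised-cosine onset/offset ramps and scales the waveform so its RMS
#' equals the package's digital reference for the target level. The reference
#' is RMS 0.05 (full scale) at 70 dB; other levels scale linearly in amplitude
#' (`10^((level-70)/20)`).
#'
#' @param token A `sound_token`.
#' @param ramp_ms Ramp duration in ms (default 5).
#' @param target_level_db Presentation level in dB (default 70).
#' @return The finalized `sound_token`.
#' @export
finalize_sound <- function(token, ramp_ms = 5, target_level_db = 70) {
  stopifnot(inherits(token, "sound_token"))
  x <- token$samples
  if (all(x == 0)) stop("cannot set the level of an all-zero token")
  n <- length(x)
  nr <- round(ramp_ms * token$sample_rate / 1000)
  if (2 * nr > n) stop("ramps longer than the token")
  if (nr > 1) {
    ramp <- 0.5 - 0.5 * cos(pi * (seq_len(nr) - 1) / (nr - 1))
    x[seq_len(nr)] <- x[seq_len(nr)] * ramp
    x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(ramp)
  }
  target_rms <- REF_RMS_70DB * 10^((target_level_db - 70) / 20)
  g <- target_rms / rms(x)
  if (max(abs(x)) * g > 1)
    stop(sprintf(
      "headroom check failed: peak %.3f would clip at the target level",
      max(abs(x)) * g))
  token$samples <- x * g
  token
}

#' Generate a seeded set of voice and nonvoice sound tokens
#'
#' Voice tokens are harmonic complexes with a time-varying fundamental
#' (default 100-300 Hz), a formant-like spectral envelope, slow amplitude
#' modulation and a weak aspiration-noise floor. Nonvoice tokens are drawn from
#' four families -- noise bursts, pure tones, chirps and jittered click trains
#' -- each mixed with a stronger noise component, reflecting the lower
#' harmonicity of environmental sounds. All tokens are finalized (5 ms ramps,
#' 70 dB reference level) and deterministic given the seed.
#'
#' @param n_voice,n_nonvoice Token counts (>= 0).
#' @param duration_ms Token duration in ms (default 500).
#' @param sample_rate Sampling rate in Hz (default 16000).
#' @param seed Integer seed.
#' @param f0_range_hz Voice fundamental range (default `c(100, 300)`).
#' @return List of `sound_token`s, voices first.
#' @export
gen_sound_set <- function(n_voice, n_nonvoice, duration_ms = 500,
                          sample_rate = 16000, seed = 1,
                          f0_range_hz = c(100, 300)) {
  if (duration_ms <= 0) stop("duration_ms must be positive")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  stopifnot(n_voice >= 0, n_nonvoice >= 0)
  set.seed(seed)
  n <- round(duration_ms * sample_rate / 1000)
  t <- (seq_len(n) - 1) / sample_rate
  out <- vector("list", n_voice + n_nonvoice)
  for (i in seq_len(n_voice)) {
    f0 <- f0_contour(n, sample_rate, f0_range_hz)
    x <- harmonic_complex(f0, sample_rate)
    am <- 1 + runif(1, 0.2, 0.6) * sin(2 * pi * runif(1, 3, 7) * t +
                                         runif(1, 0, 2 * pi))
    x <- x * am
    snr_db <- runif(1, 18, 30)
    x <- mix_at_snr(x, rnorm(n), snr_db)
    tok <- sound_token(0.9 * x / max(abs(x)), sample_rate, "voice",
                       id = sprintf("v%03d", i))
    out[[i]] <- finalize_sound(tok)
  }
  kinds <- c("noise", "tone", "chirp", "clicks")
  for (j in seq_len(n_nonvoice)) {
    kind <- kinds[(j - 1) %% 4 + 1]
    x <- switch(kind,
      noise = band_noise(n, sample_rate, sort(runif(2, 200, 6000))),
      tone = sin(2 * pi * runif(1, 300, 2000) * t + runif(1, 0, 2 * pi)),
      chirp = {
        f1 <- runif(1, 200, 1000); f2 <- runif(1, 1500, 5000)
        sin(2 * pi * (f1 * t + (f2 - f1) * t^2 / (2 * max(t))))
      },
      clicks = click_train(n, sample_rate, rate_hz = runif(1, 20, 60),
                           jitter = 0.4))
    am <- 1 + runif(1, 0, 0.5) * sin(2 * pi * runif(1, 2, 10) * t +
                                       runif(1, 0, 2 * pi))
    snr_db <- runif(1, -2, 8)
    x <- mix_at_snr(x * am, rnorm(n), snr_db)
    tok <- sound_token(0.9 * x / max(abs(x)), sample_rate, "nonvoice",
                       id = sprintf("n%03d", j))
    out[[n_voice + j]] <- finalize_sound(tok)
  }
  out
}

## Slowly varying F0 contour: random-walk in log-F0, clamped to the range.
f0_contour <- function(n, sample_rate, f0_range_hz) {
  n_knots <- 8
  lf <- log(runif(1, f0_range_hz[1] * 1.1, f0_range_hz[2] * 0.9))
  knots <- numeric(n_knots)
  knots[1] <- lf
  for (k in 2:n_knots)
    knots[k] <- min(max(knots[k - 1] + rnorm(1, 0, 0.08),
                        log(f0_range_hz[1])), log(f0_range_hz[2]))
  exp(approx(seq(0, 1, length.out = n_knots), knots,
             xout = seq(0, 1, length.out = n))$y)
}

## Harmonic complex following an F0 contour, harmonics weighted by a
## formant-like spectral envelope (three resonances + tilt).
harmonic_complex <- function(f0, sample_rate, max_hz = 5000) {
  n <- length(f0)
  phase <- 2 * pi * cumsum(f0) / sample_rate
  formants <- c(500, 1500, 2500) * runif(3, 0.85, 1.15)
  bw <- c(120, 180, 250)
  x <- numeric(n)
  k <- 1
  while (k * min(f0) < max_hz) {
    fk <- k * f0
    w <- exp(-((mean(fk) - formants[1]) / bw[1])^2 / 2) +
      0.6 * exp(-((mean(fk) - formants[2]) / bw[2])^2 / 2) +
      0.4 * exp(-((mean(fk) - formants[3]) / bw[3])^2 / 2) + 0.05
    w <- w / k^0.5
    x <- x + w * sin(k * phase)
    k <- k + 1
    if (k > 40) break
  }
  x / max(abs(x))
}

band_noise <- function(n, sample_rate, band_hz) {
  X <- fft(rnorm(n))
  f <- (seq_len(n) - 1) * sample_rate / n
  f <- pmin(f, sample_rate - f)
  X[f < band_hz[1] | f > band_hz[2]] <- 0
  x <- Re(fft(X, inverse = TRUE) / n)
  x / max(abs(x))
}

click_train <- function(n, sample_rate, rate_hz, jitter = 0.4) {
  x <- numeric(n)
  ipi <- sample_rate / rate_hz
  pos <- 1
  while (pos <= n) {
    x[round(pos)] <- 1
    pos <- pos + ipi * (1 + runif(1, -jitter, jitter))
  }
  ## ring each click through a short decaying resonance so it has bandwidth
  k <- exp(-(0:63) / 12) * sin(2 * pi * 2000 * (0:63) / sample_rate)
  y <- as.numeric(stats::filter(c(x, numeric(64)), k, method = "convolution",
                                sides = 1))
  y <- y[seq_len(n)]
  y[is.na(y)] <- 0
  y / max(abs(y))
}

## Mix signal with noise at the given SNR (dB); unit-peak output not enforced.
mix_at_snr <- function(signal, noise, snr_db) {
  noise <- noise * rms(signal) / rms(noise) / 10^(snr_db / 20)
  signal + noise
}
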