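## Shared fixtures, built once per test run and cached.
.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

make_tone <- function(freq_hz = 200, duration_ms = 500, sample_rate = 16000,
                      amp = 0.5, category = "voice", id = "tone") {
  t <- (seq_len(round(duration_ms * sample_rate / 1000)) - 1) / sample_rate
  sound_token(amp * sin(2 * pi * freq_hz * t), sample_rate, category, id = id)
}

make_noise_token <- function(duration_ms = 500, sample_rate = 16000,
                             seed = 1, category = "nonvoice", id = "noise") {
  set.seed(seed)
  n <- round(duration_ms * sample_rate / 1000)
  x <- rnorm(n)
  sound_token(0.5 * x / max(abs(x)), sample_rate, category, id = id)
}

## Harmonic complex plus noise at a known harmonics-to-noise ratio (dB):
## the analytic oracle for HNR checks.
make_known_hnr <- function(hnr_db, duration_ms = 500, sample_rate = 16000,
                           f0 = 150, seed = 1) {
  set.seed(seed)
  t <- (seq_len(round(duration_ms * sample_rate / 1000)) - 1) / sample_rate
  h <- sin(2 * pi * f0 * t) + 0.5 * sin(2 * pi * 2 * f0 * t) +
    0.25 * sin(2 * pi * 3 * f0 * t)
  h <- h / rms(h)
  nz <- rnorm(length(t))
  nz <- nz / rms(nz) * 10^(-hnr_db / 20)
  x <- h + nz
  sound_token(0.5 * x / max(abs(x)), sample_rate, "voice", id = "hnrprobe")
}

## Small high-signal cohort for recovery-style tests.
small_gt <- function() fixture("small_gt", function()
  gen_ground_truth(c(12, 12, 8), seed = 5))

## High SNR here means both low run noise and low between-subject spread
## (a cohort of unusually consistent subjects), so recovery checks probe the
## pipeline rather than sampling variability.
small_cohort_hisnr <- function() fixture("small_cohort_hisnr", function()
  gen_subject_betas(small_gt(), effect = 1, noise_sd = 0.1, n_runs = 8,
                    n_subjects = 12, seed = 7, subject_sd = 0.05))

## Same grid under the default study conditions (run noise 0.5, subject
## spread 0.2), the regime in which the conjunction threshold separates core
## from accessory voxels.
small_cohort_default <- function() fixture("small_cohort_default", function()
  gen_subject_betas(small_gt(), effect = 1, noise_sd = 0.5, n_runs = 8,
                    n_subjects = 12, seed = 9))

small_neigh <- function() fixture("small_neigh", function()
  searchlight_indices(small_gt()$grid, 5))

## Narrowband envelope modulation spectrum peak (Hz), used for ripple checks.
modulation_peak <- function(x, sample_rate = 16000, band = c(950, 1250),
                            search = c(0.5, 40), smooth_ms = 10) {
  n <- length(x)
  X <- fft(x)
  f <- (seq_len(n) - 1) * sample_rate / n
  f <- pmin(f, sample_rate - f)
  X[f < band[1] | f > band[2]] <- 0
  xb <- Re(fft(X, inverse = TRUE) / n)
  env <- sound_envelope(xb, sample_rate, smooth_ms = smooth_ms)
  sp <- Mod(fft(env - mean(env)))
  fr <- (seq_len(n) - 1) * sample_rate / n
  sel <- fr > search[1] & fr < search[2]
  fr[sel][which.max(sp[sel])]
}

## Envelope autocorrelation width: first lag (samples) where the normalized
## autocorrelation of the mean-removed envelope drops below 1/e.
env_acf_width <- function(x, sample_rate = 16000, smooth_ms = 25,
                          lag_max = 7000) {
  env <- sound_envelope(x, sample_rate, smooth_ms = smooth_ms)
  ac <- stats::acf(env - mean(env), lag.max = lag_max, plot = FALSE,
                   demean = FALSE)$acf
  w <- which(ac < exp(-1))[1]
  if (is.na(w)) lag_max else w
}
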