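## Brute-force DFT magnitude, the independent spectrum oracle (O(n^2); only
## for short tokens).
dft_mag <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  W <- exp(-2i * pi * outer(k, k) / n)
  Mod(as.vector(W %*% x))
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

test_that("envelope/spectrum chimera preserves duration, envelope and spectrum", {
  toks <- gen_sound_set(3, 2, 100, 8000, seed = 11)
  for (i in seq_along(toks)) {
    ae <- synth_env_spec(toks[[i]], seed = i)
    expect_equal(ae$duration_ms, toks[[i]]$duration_ms)
    expect_equal(ae$sample_rate, toks[[i]]$sample_rate)
    expect_identical(ae$category, toks[[i]]$category)
    expect_identical(ae$source_id, toks[[i]]$id)
    ## spectrum component: magnitude spectrum equals the original's
    ## (checked against a brute-force DFT, not the implementation's FFT)
    sim <- cosine_sim(dft_mag(ae$components$spec), dft_mag(toks[[i]]$samples))
    expect_gt(sim, 0.99)
  }
})

test_that("the envelope component carries the input's temporal profile", {
  ## modulated input: the envelope component tracks the modulator
  sr <- 16000
  t <- (0:7999) / sr
  am <- sound_token(0.5 * (1 + 0.8 * sin(2 * pi * 3 * t)) *
                      sin(2 * pi * 900 * t), sr, "voice", id = "am")
  ae <- synth_env_spec(am, seed = 3)
  e_in <- sound_envelope(am, smooth_ms = 20)
  e_out <- sound_envelope(ae$components$env, sr, smooth_ms = 20)
  expect_gt(cor(e_in, e_out), 0.9)
  ## constant-envelope white noise stays (approximately) flat: the relative
  ## envelope spread of the component is comparable to the input's
  wn <- make_noise_token(seed = 2)
  ae_wn <- synth_env_spec(wn, seed = 3)
  cv <- function(e) sd(e) / mean(e)
  cv_in <- cv(sound_envelope(wn, smooth_ms = 20))
  cv_out <- cv(sound_envelope(ae_wn$components$env, sr, smooth_ms = 20))
  expect_lt(cv_out, 3 * cv_in + 0.05)
})

test_that("silent input to the chimera is rejected", {
  tok <- make_tone()
  tok$samples <- rep(0, length(tok$samples))
  expect_error(synth_env_spec(tok), "silent")
})

test_that("scrambling preserves the long-run spectrum but destroys envelope order", {
  ## band-averaged magnitude spectrum correlation
  toks <- gen_sound_set(2, 2, 500, 16000, seed = 13)
  band_avg_spec <- function(x, n_bands = 40) {
    m <- Mod(fft(x))[2:(length(x) / 2)]
    edges <- round(seq(1, length(m) + 1, length.out = n_bands + 1))
    vapply(seq_len(n_bands), function(b)
      mean(m[edges[b]:(edges[b + 1] - 1)]), 0)
  }
  for (tok in toks) {
    scr <- synth_scrambled(tok, seed = 5)
    expect_equal(scr$duration_ms, tok$duration_ms)
    expect_gt(cor(band_avg_spec(tok$samples), band_avg_spec(scr$samples)),
              0.95)
  }
  ## strongly amplitude-modulated tone: autocorrelation of the envelope at
  ## lags beyond the local window drops relative to the input
  sr <- 16000
  t <- (0:(sr / 2 - 1)) / sr
  am <- sound_token(0.5 * (1 + 0.95 * sin(2 * pi * 3 * t)) *
                      sin(2 * pi * 1000 * t), sr, "voice", id = "am")
  scr <- synth_scrambled(am, segment_ms = 25, local_window_ms = 100, seed = 2)
  lag <- round(0.15 * sr)                    # beyond the 100 ms window
  env_ac <- function(x) {
    e <- sound_envelope(x, sr, smooth_ms = 10)
    e <- e - mean(e)
    sum(head(e, -lag) * tail(e, -lag)) / sum(e^2)
  }
  expect_lt(abs(env_ac(scr$samples)), abs(env_ac(am$samples)))
})

test_that("degenerate scramble (one segment, one band) is the identity", {
  tok <- make_tone(440, 250)
  out <- synth_scrambled(tok, segment_ms = 250, local_window_ms = 250,
                         n_bands = 1, seed = 1)
  expect_lt(max(abs(out$samples - tok$samples)), 0.05)
  expect_error(synth_scrambled(tok, segment_ms = 300, local_window_ms = 250),
               "segment_ms")
})

test_that("pitch/amplitude equivalent tracks the contour and the envelope", {
  tone <- make_tone(200, 500)
  pa <- synth_pitch_amp(tone, seed = 4)
  expect_equal(pa$duration_ms, 500)
  ## contour oracle: zero-crossing rate of a pure tone gives its frequency
  zc <- sum(diff(sign(tone$samples)) != 0) / 2 / (500 / 1000)
  tr <- vaparc:::track_f0(tone$samples, tone$sample_rate, c(75, 500))
  expect_lt(max(abs(tr$f0[!is.na(tr$f0)] - zc)), 2)
  ## dominant spectral peak of the output near 200 Hz
  m <- Mod(fft(pa$samples))[2:4000]
  fr <- (1:3999) * 16000 / length(pa$samples)
  expect_lt(abs(fr[which.max(m)] - 200), 10)
  ## intensity envelope preserved
  sr <- 16000
  t <- (0:(sr / 2 - 1)) / sr
  mod <- sound_token(0.5 * (1 + 0.9 * sin(2 * pi * 2 * t)) *
                       sin(2 * pi * 180 * t), sr, "voice", id = "mod")
  pam <- synth_pitch_amp(mod, seed = 6)
  e_in <- sound_envelope(mod, smooth_ms = 10)
  e_out <- sound_envelope(pam, smooth_ms = 10)
  expect_gt(cor(e_in, e_out), 0.9)
})

test_that("unvoiced input falls back to the noise component with a flag", {
  nz <- make_noise_token(seed = 9)
  expect_warning(pa <- synth_pitch_amp(nz, seed = 1), "no voiced frames")
  expect_true("no_voiced_frames" %in% pa$flags)
  expect_equal(pa$duration_ms, nz$duration_ms)
})

test_that("acoustic equivalents refuse non-original inputs", {
  tok <- make_tone()
  ae <- synth_env_spec(tok, seed = 1)
  expect_error(synth_env_spec(ae), "original")
  expect_error(synth_scrambled(ae), "original")
})
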