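#' Envelope/spectrum-preserving acoustic equivalent
#'
#' Builds the chimera of two noise components: the envelope component is
#' broadband white noise multiplied by the original's Hilbert envelope (flat
#' spectrum, original temporal profile), and the spectrum component is white
#' noise whose Fourier magnitudes are replaced by the original's magnitude
#' spectrum while keeping the noise phases (original spectral profile, flat
#' temporal structure). The two are summed at equal RMS and rescaled to unit
#' headroom; duration and sample rate are preserved.
#'
#' @param original A `sound_token` with `variant == "orig"`.
#' @param seed Integer seed for the noise carriers.
#' @return A `sound_token` with variant `"e_s"`.
#' @export
synth_env_spec <- function(original, seed = 1) {
  check_original(original)
  x <- original$samples
  if (all(x == 0)) stop("silent input: envelope undefined up to scale")
  set.seed(seed)
  n <- length(x)
  env <- hilbert_env(x)
  env_comp <- env * rnorm(n)
  noise <- rnorm(n)
  Y <- fft(noise)
  mag <- Mod(fft(x))
  ph <- Y / ifelse(Mod(Y) == 0, 1, Mod(Y))
  spec_comp <- Re(fft(mag * ph, inverse = TRUE) / n)
  y <- env_comp / rms(env_comp) + spec_comp / rms(spec_comp)
  y <- 0.9 * y / max(abs(y))
  out <- ae_token(original, y, "e_s")
  out$components <- list(env = env_comp, spec = spec_comp)
  out
}

#' Temporally scrambled acoustic equivalent
#'
#' Decomposes the signal into log-spaced frequency bands (partition-of-unity
#' FFT masks), cuts each band into short segments, permutes the segments only
#' within a local window, and overlap-adds them with raised-cosine crossfades
#' before recombining the bands. Long-timescale spectral content is preserved;
#' short-timescale temporal order is destroyed.
#'
#' @param original A `sound_token` with `variant == "orig"`.
#' @param segment_ms Segment length in ms (default 25).
#' @param local_window_ms Window within which segments may move (default 250).
#' @param n_bands Number of log-spaced frequency bands (default 8).
#' @param seed Integer seed for the permutations.
#' @param identity If `TRUE`, keep segment order (degenerate scramble used for
#'   validation).
#' @return A `sound_token` with variant `"scr"`.
#' @export
synth_scrambled <- function(original, segment_ms = 25, local_window_ms = 250,
                            n_bands = 8, seed = 1, identity = FALSE) {
  check_original(original)
  sr <- original$sample_rate
  x <- original$samples
  n <- length(x)
  if (!(segment_ms <= local_window_ms && local_window_ms <= original$duration_ms))
    stop("need segment_ms <= local_window_ms <= duration")
  set.seed(seed)
  seg <- max(2L, round(segment_ms * sr / 1000))
  win <- max(seg, round(local_window_ms * sr / 1000))
  xf <- max(2L, round(seg / 4))                       # crossfade length
  bands <- band_split(x, sr, n_bands)
  y <- numeric(n)
  for (b in bands) y <- y + scramble_band(b, seg, win, xf, identity)
  peak <- max(abs(y))
  if (peak > 0.95) y <- 0.95 * y / peak
  ae_token(original, y, "scr")
}

## Partition-of-unity split into n log-spaced bands via FFT masks; the masks
## sum to one at every bin so the bands recombine to the input exactly.
band_split <- function(x, sample_rate, n_bands) {
  n <- length(x)
  X <- fft(x)
  f <- (seq_len(n) - 1) * sample_rate / n
  f <- pmin(f, sample_rate - f)                       # mirrored frequency axis
  lo <- 50
  hi <- sample_rate / 2
  edges <- exp(seq(log(lo), log(hi), length.out = n_bands + 1))
  edges[1] <- 0
  edges[n_bands + 1] <- hi + 1
  lapply(seq_len(n_bands), function(b) {
    m <- f >= edges[b] & f < edges[b + 1]
    Re(fft(X * m, inverse = TRUE) / n)
  })
}

## Permute fixed-length segments within local windows, overlap-adding with
## trapezoid windows (flat top, raised-cosine edges of length xf) and
## normalizing by the summed window so the degenerate permutation is exact.
scramble_band <- function(x, seg, win, xf, identity = FALSE) {
  n <- length(x)
  starts <- seq(1L, n, by = seg)
  n_seg <- length(starts)
  perm <- seq_len(n_seg)
  if (!identity) {
    w_id <- (starts - 1L) %/% win                     # local-window index
    for (w in unique(w_id)) {
      idx <- which(w_id == w)
      if (length(idx) > 1) perm[idx] <- idx[sample(length(idx))]
    }
  }
  y <- numeric(n)
  wsum <- numeric(n)
  ramp <- 0.5 - 0.5 * cos(pi * seq_len(xf) / (xf + 1))
  for (k in seq_len(n_seg)) {
    src <- starts[perm[k]]
    dst <- starts[k]
    len <- min(seg, n - src + 1L, n - dst + 1L)
    piece <- x[src:(src + len - 1L)]
    w <- rep(1, len)
    ne <- min(xf, floor(len / 2))
    if (ne > 0) {
      w[seq_len(ne)] <- ramp[seq_len(ne)]
      w[(len - ne + 1):len] <- rev(ramp[seq_len(ne)])
    }
    sel <- dst:(dst + len - 1L)
    y[sel] <- y[sel] + piece * w
    wsum[sel] <- wsum[sel] + w
  }
  y / pmax(wsum, 1e-12)
}

#' Pitch/amplitude-contour acoustic equivalent
#'
#' Estimates the frame-wise fundamental-frequency contour of the original
#' (autocorrelation method), fills unvoiced gaps by linear interpolation,
#' renders the contour as a sinusoid by phase accumulation, and overlays it
#' with broadband white noise amplitude-modulated by the original's intensity
#' envelope. The two components are summed at equal RMS. If no voiced frame is
#' found, the token falls back to the noise component alone and carries the
#' flag `"no_voiced_frames"`.
#'
#' @param original A `sound_token` with `variant == "orig"`.
#' @param f0_range_hz Search range for the pitch tracker (default 75-500 Hz).
#' @param seed Integer seed for the noise carrier.
#' @return A `sound_token` with variant `"p_a"`.
#' @export
synth_pitch_amp <- function(original, f0_range_hz = c(75, 500), seed = 1) {
  check_original(original)
  x <- original$samples
  if (all(x == 0)) stop("silent input")
  set.seed(seed)
  sr <- original$sample_rate
  n <- length(x)
  tr <- track_f0(x, sr, f0_range_hz)
  env <- smooth_env(hilbert_env(x), sr, 10)
  noise <- rnorm(n) * env
  flags <- character()
  if (all(is.na(tr$f0))) {
    y <- noise
    flags <- "no_voiced_frames"
    warning("no voiced frames found; falling back to noise component only")
  } else {
    f0 <- interp_contour(tr$f0, tr$centers, n)
    tone <- sin(2 * pi * cumsum(f0) / sr)
    y <- tone / rms(tone) + noise / rms(noise)
  }
  y <- 0.9 * y / max(abs(y))
  ae_token(original, y, "p_a", flags = flags)
}

## Frame-wise autocorrelation pitch tracker. Returns per-frame F0 (NA when
## unvoiced), frame centers in samples, and the voicing strength (normalized
## autocorrelation peak).
track_f0 <- function(x, sample_rate, f0_range_hz = c(75, 500),
                     frame_ms = 40, hop_ms = 10, voicing_threshold = 0.45) {
  fl <- round(frame_ms * sample_rate / 1000)
  hp <- round(hop_ms * sample_rate / 1000)
  if (length(x) < fl) stop("signal shorter than one analysis frame")
  starts <- seq(1L, length(x) - fl + 1L, by = hp)
  lag_min <- max(2L, floor(sample_rate / f0_range_hz[2]))
  lag_max <- min(fl - 1L, ceiling(sample_rate / f0_range_hz[1]))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(fl) / (fl + 1))  # Hann
  ## the window's own autocorrelation; dividing by it undoes the taper bias
  ## so a perfectly periodic frame reaches a normalized peak near 1
  acw <- acf_fft(w)
  f0 <- rep(NA_real_, length(starts))
  strength <- numeric(length(starts))
  for (i in seq_along(starts)) {
    fr <- x[starts[i]:(starts[i] + fl - 1L)]
    fr <- (fr - mean(fr)) * w
    if (all(fr == 0)) next
    ac <- acf_fft(fr)
    r0 <- ac[1]
    if (r0 <= 0) next
    seg <- (ac[(lag_min + 1):(lag_max + 1)] / r0) /
      (acw[(lag_min + 1):(lag_max + 1)] / acw[1])
    pk <- which.max(seg)
    strength[i] <- seg[pk]
    if (seg[pk] >= voicing_threshold) {
      lag <- lag_min + pk - 1L
      ## parabolic interpolation around the peak for sub-sample lag
      if (pk > 1 && pk < length(seg)) {
        a <- seg[pk - 1]; b <- seg[pk]; cc <- seg[pk + 1]
        denom <- a - 2 * b + cc
        if (abs(denom) > 1e-12) lag <- lag + 0.5 * (a - cc) / denom
      }
      f0[i] <- sample_rate / lag
    }
  }
  list(f0 = f0, centers = starts + fl / 2, strength = strength,
       n_frames = length(starts))
}

acf_fft <- function(fr) {
  n <- length(fr)
  m <- 2^ceiling(log2(2 * n))
  X <- fft(c(fr, numeric(m - n)))
  Re(fft(Mod(X)^2, inverse = TRUE) / m)[seq_len(n)]
}

## Linearly interpolate a frame contour (with NA gaps) onto the sample grid.
interp_contour <- function(v, centers, n) {
  ok <- !is.na(v)
  approx(centers[ok], v[ok], xout = seq_len(n), rule = 2)$y
}

ae_token <- function(original, samples, variant, flags = character()) {
  sound_token(samples, original$sample_rate, original$category,
              variant = variant, id = paste(original$id, variant, sep = "_"),
              source_id = original$id, flags = flags)
}

check_original <- function(token) {
  stopifnot(inherits(token, "sound_token"))
  if (token$variant != "orig")
    stop("input must be an original token (variant 'orig')")
  invisible(token)
}
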