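## 14 frame-wise low-level descriptors x 6 functionals (mean, sd, min, max,
## q25, q75) + 4 global descriptors = 88 feature slots.
LLD_NAMES <- c("f0", "hnr", "jitter", "shimmer", "flux", "centroid",
               "spread", "skew", "kurtosis", "rolloff", "flatness",
               "entropy", "zcr", "frame_rms")
FUNCTIONALS <- c("mean", "sd", "min", "max", "q25", "q75")
GLOBAL_NAMES <- c("voiced_fraction", "modulation_depth", "attack_slope",
                  "decay_slope")

#' Names of the 88 acoustic feature slots
#'
#' 14 frame-wise low-level descriptors (F0, HNR, jitter and shimmer proxies,
#' spectral flux, spectral moments and shape statistics, zero-crossing rate,
#' frame RMS) summarized by 6 functionals each, plus 4 global descriptors
#' (voiced fraction, envelope modulation depth, attack and decay slope).
#'
#' @return Character vector of length 88, in fixed order.
#' @export
feature_names <- function() {
  c(as.vector(t(outer(LLD_NAMES, FUNCTIONALS, paste, sep = "_"))),
    GLOBAL_NAMES)
}

#' Extract the 88-slot acoustic feature vector from a token
#'
#' Frame-wise contours are computed with a Hann window (default 40 ms frames,
#' 10 ms hop): F0 and voicing via the autocorrelation method; HNR from the
#' normalized autocorrelation peak `r` as `10*log10(r/(1-r))`; jitter and
#' shimmer as frame-to-frame proxies (relative change of period and of frame
#' amplitude over voiced frames); spectral flux, moments (centroid, spread,
#' skewness, kurtosis), 85% rolloff, flatness and entropy from the magnitude
#' spectrum; plus zero-crossing rate and frame RMS. Contours are summarized by
#' mean, SD, min, max and quartiles. Descriptors undefined on a frame (e.g.
#' F0 on unvoiced frames) are imputed as 0 before summarizing; the voiced
#' fraction records how often that happened for the periodicity family.
#' Extraction is pure: the same token always yields the same vector.
#'
#' @param token A `sound_token`.
#' @param frame_ms,hop_ms Analysis frame and hop in ms (defaults 40 and 10).
#' @param f0_range_hz Pitch search range (default 75-500 Hz).
#' @return Named numeric vector of length 88 (see [feature_names()]).
#' @export
extract_features <- function(token, frame_ms = 40, hop_ms = 10,
                             f0_range_hz = c(75, 500)) {
  stopifnot(inherits(token, "sound_token"))
  x <- token$samples
  sr <- token$sample_rate
  fl <- round(frame_ms * sr / 1000)
  hp <- round(hop_ms * sr / 1000)
  if (length(x) < fl + 2 * hp)
    stop("token too short: need at least 3 analysis frames")
  tr <- track_f0(x, sr, f0_range_hz, frame_ms, hop_ms)
  starts <- seq(1L, length(x) - fl + 1L, by = hp)
  nf <- length(starts)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(fl) / (fl + 1))
  nyq_bins <- floor(fl / 2)
  freqs <- (seq_len(nyq_bins)) * sr / fl
  lld <- matrix(0, nf, length(LLD_NAMES), dimnames = list(NULL, LLD_NAMES))
  prev_mag <- NULL
  amps <- numeric(nf)
  for (i in seq_len(nf)) {
    fr <- x[starts[i]:(starts[i] + fl - 1L)]
    amps[i] <- sqrt(mean(fr^2))
    mag <- Mod(fft(fr * w))[2:(nyq_bins + 1)]
    p <- mag / max(sum(mag), 1e-12)
    centroid <- sum(freqs * p)
    spread <- sqrt(sum((freqs - centroid)^2 * p))
    lld[i, "centroid"] <- centroid
    lld[i, "spread"] <- spread
    lld[i, "skew"] <- if (spread > 0) sum(((freqs - centroid) / spread)^3 * p) else 0
    lld[i, "kurtosis"] <- if (spread > 0) sum(((freqs - centroid) / spread)^4 * p) else 0
    cum <- cumsum(mag^2)
    lld[i, "rolloff"] <- freqs[which(cum >= 0.85 * cum[nyq_bins])[1]]
    pw <- mag^2 / max(sum(mag^2), 1e-12)
    lld[i, "entropy"] <- -sum(ifelse(pw > 0, pw * log(pw), 0)) / log(nyq_bins)
    gm <- exp(mean(log(mag^2 + 1e-12)))
    lld[i, "flatness"] <- gm / max(mean(mag^2), 1e-12)
    lld[i, "flux"] <- if (is.null(prev_mag)) 0 else
      sqrt(sum((mag / max(sqrt(sum(mag^2)), 1e-12) -
                  prev_mag / max(sqrt(sum(prev_mag^2)), 1e-12))^2))
    prev_mag <- mag
    lld[i, "zcr"] <- mean(diff(sign(fr)) != 0)
    lld[i, "frame_rms"] <- amps[i]
  }
  f0 <- tr$f0[seq_len(nf)]
  voiced <- !is.na(f0)
  lld[, "f0"] <- ifelse(voiced, f0, 0)
  r <- pmin(pmax(tr$strength[seq_len(nf)], 0), 1 - 1e-6)
  lld[, "hnr"] <- ifelse(r > 0, 10 * log10(r / (1 - r)), -20)
  per <- ifelse(voiced, 1 / f0, NA)
  jit <- abs(diff(per)) / ((head(per, -1) + tail(per, -1)) / 2)
  lld[2:nf, "jitter"] <- ifelse(is.na(jit), 0, jit)
  shim <- abs(diff(amps)) / pmax((head(amps, -1) + tail(amps, -1)) / 2, 1e-12)
  shim[!(head(voiced, -1) & tail(voiced, -1))] <- 0
  lld[2:nf, "shimmer"] <- shim
  funs <- apply(lld, 2, function(v)
    c(mean(v), sd(v), min(v), max(v),
      quantile(v, 0.25, names = FALSE), quantile(v, 0.75, names = FALSE)))
  env <- sound_envelope(token, smooth_ms = 10)
  peak_i <- which.max(env)
  glob <- c(
    voiced_fraction = mean(voiced),
    modulation_depth = (max(env) - min(env)) / max(max(env) + min(env), 1e-12),
    attack_slope = max(env) / max(peak_i / sr, 1e-4),
    decay_slope = (env[length(env)] - max(env)) /
      max((length(env) - peak_i) / sr, 1e-4))
  out <- c(as.vector(funs), glob)
  names(out) <- feature_names()
  out[!is.finite(out)] <- 0
  out
}

#' Feature table for a list of tokens
#'
#' @param tokens List of `sound_token`s.
#' @param ... Passed to [extract_features()].
#' @return A tibble with token metadata columns (`id`, `source_id`,
#'   `category`, `variant`) followed by the 88 feature columns.
#' @export
feature_table <- function(tokens, ...) {
  feats <- t(vapply(tokens, extract_features, numeric(88), ...))
  meta <- tibble::tibble(
    id = vapply(tokens, `[[`, "", "id"),
    source_id = vapply(tokens, `[[`, "", "source_id"),
    category = vapply(tokens, `[[`, "", "category"),
    variant = vapply(tokens, `[[`, "", "variant"))
  cbind(meta, tibble::as_tibble(feats))
}
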