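#' Plot axial slices of a parcellation
#'
#' @param x A `va_parcellation`.
#' @param slices Which z slices to show (default: every other slice).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.va_parcellation <- function(x, slices = NULL, ...) {
  d <- x$grid$dims
  slices <- slices %||% seq(1, d[3], by = 2)
  co <- grid_coords(x$grid)
  df <- data.frame(x = co[, 1], y = co[, 2], z = co[, 3],
                   label = as.vector(x$labels))
  df <- df[df$z %in% slices & df$label != "outside", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_manual(values = c(core = "#d7301f",
                                          acoustic = "#31a354",
                                          accessory = "#3182bd")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "subfield", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.va_parcellation
#' @export
autoplot <- function(x, ...) UseMethod("autoplot")

#' Plot per-subfield effect sizes
#'
#' Bar chart of group Cohen's d per subfield and sound set.
#'
#' @param es Tibble from [effect_sizes()].
#' @return A ggplot object.
#' @export
plot_effect_sizes <- function(es) {
  es <- es[!is.na(es$cohens_d), ]
  es$sound_set <- factor(es$sound_set, levels = va_variants())
  ggplot2::ggplot(es, ggplot2::aes(x = .data$sound_set, y = .data$cohens_d,
                                   fill = .data$subfield)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "sound set", y = "Cohen's d (voice - nonvoice)") +
    ggplot2::theme_minimal()
}

#' Plot a spectrogram-style overview of a sound token
#'
#' Frame-wise log magnitude spectrum (Hann window) as a tile map.
#'
#' @param token A `sound_token`.
#' @param frame_ms,hop_ms Analysis frame and hop (defaults 20 and 5 ms).
#' @return A ggplot object.
#' @export
plot_spectrogram <- function(token, frame_ms = 20, hop_ms = 5) {
  x <- token$samples
  sr <- token$sample_rate
  fl <- round(frame_ms * sr / 1000)
  hp <- round(hop_ms * sr / 1000)
  starts <- seq(1L, length(x) - fl + 1L, by = hp)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(fl) / (fl + 1))
  nb <- floor(fl / 2)
  S <- vapply(starts, function(s0)
    20 * log10(Mod(fft(x[s0:(s0 + fl - 1)] * w))[2:(nb + 1)] + 1e-9),
    numeric(nb))
  df <- expand.grid(freq = (seq_len(nb)) * sr / fl,
                    time = (starts - 1 + fl / 2) / sr)
  df$db <- as.vector(S)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq,
                                   fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)", fill = "dB",
                  title = token$id) +
    ggplot2::theme_minimal()
}
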