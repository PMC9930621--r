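#' Build the block experiment schedule
#'
#' Each run contains one mini-block per condition (12 = 6 sound sets x 2
#' categories) in randomized order. A block presents `sounds_per_block`
#' 500 ms sounds with inter-sound onset gaps jittered in `jitter_s`; blocks
#' are separated by `gap_s` of silence (gaps occur between blocks only, so a
#' default run is exactly `12 * 12.5 + 11 * 15 = 315` s). Jitter values are
#' drawn antithetically (pairs `u`, `sum(jitter_s) - u`) so every block lasts
#' exactly its nominal duration while individual gaps remain jittered.
#' Exactly `n_repetition_blocks` blocks (sampled across the whole experiment)
#' contain one immediate repetition of a sound identity in one of the slots;
#' a button-press event is placed at the end of each repetition block.
#'
#' @param n_runs Number of runs (default 8).
#' @param blocks_per_run Number of mini-blocks per run; must equal the number
#'   of conditions (default 12).
#' @param sounds_per_block Sounds per block (default 9).
#' @param jitter_s Inter-sound gap interval in seconds (default
#'   `c(0.8, 1.2)`).
#' @param gap_s Silence between blocks in seconds (default 15).
#' @param n_repetition_blocks Total repetition blocks across the experiment
#'   (default 24).
#' @param sound_s Sound duration in seconds (default 0.5).
#' @param seed Integer seed.
#' @return An `experiment_schedule`: a list with `blocks` (tibble of run,
#'   block, condition, onset, duration, repetition), `sound_onsets`,
#'   `button_presses`, and timing metadata.
#' @export
build_schedule <- function(n_runs = 8, blocks_per_run = 12,
                           sounds_per_block = 9, jitter_s = c(0.8, 1.2),
                           gap_s = 15, n_repetition_blocks = 24,
                           sound_s = 0.5, seed = 1) {
  conditions <- va_conditions()
  if (blocks_per_run != length(conditions))
    stop("blocks_per_run must equal the number of conditions (12)")
  total_blocks <- n_runs * blocks_per_run
  if (n_repetition_blocks > total_blocks)
    stop("more repetition blocks than blocks")
  set.seed(seed)
  n_gaps <- sounds_per_block - 1
  block_dur <- sounds_per_block * sound_s + n_gaps * mean(jitter_s)
  run_dur <- blocks_per_run * block_dur + (blocks_per_run - 1) * gap_s
  rep_blocks <- sort(sample(total_blocks, n_repetition_blocks))
  blocks <- vector("list", total_blocks)
  sound_onsets <- vector("list", total_blocks)
  bi <- 0L
  for (r in seq_len(n_runs)) {
    order_r <- sample(conditions)
    onset <- 0
    for (b in seq_len(blocks_per_run)) {
      bi <- bi + 1L
      gaps <- antithetic_jitter(n_gaps, jitter_s)
      onsets <- onset + cumsum(c(0, gaps + sound_s))
      is_rep <- bi %in% rep_blocks
      blocks[[bi]] <- tibble::tibble(
        run = r, block = b, condition = order_r[b], onset = onset,
        duration = block_dur, repetition = is_rep)
      sound_onsets[[bi]] <- onsets
      onset <- onset + block_dur + gap_s
    }
    if (abs((onset - gap_s) - run_dur) > 1e-9)
      stop("internal timing error")                   # construction invariant
  }
  blocks <- do.call(rbind, blocks)
  button <- blocks[blocks$repetition, c("run", "onset", "duration")]
  button$time <- button$onset + button$duration + 0.5
  structure(list(
    blocks = blocks, sound_onsets = sound_onsets,
    button_presses = button[, c("run", "time")],
    conditions = conditions, n_runs = n_runs,
    sounds_per_block = sounds_per_block, jitter_s = jitter_s,
    gap_s = gap_s, sound_s = sound_s, block_dur = block_dur,
    run_duration = run_dur, n_repetition_blocks = n_repetition_blocks,
    seed = seed), class = "experiment_schedule")
}

## n jitter gaps in [lo, hi] with pairwise antithetic draws so the sum is
## exactly n * mean(range); the odd element (if any) is the midpoint.
antithetic_jitter <- function(n, jitter_s) {
  half <- n %/% 2
  u <- runif(half, jitter_s[1], jitter_s[2])
  g <- c(rbind(u, sum(jitter_s) - u))
  if (n %% 2 == 1) g <- c(g, mean(jitter_s))
  sample(g)
}

#' @export
print.experiment_schedule <- function(x, ...) {
  cat(sprintf("<experiment_schedule: %d runs x %d blocks (%d repetition), run %.1f s>\n",
              x$n_runs, nrow(x$blocks) / x$n_runs, x$n_repetition_blocks,
              x$run_duration))
  invisible(x)
}

#' Trial count of the perceptual similarity-rating experiment
#'
#' Every original sound is paired once with each of its acoustic equivalents,
#' so the rating experiment has `n_originals * n_variants` trials (700 for the
#' full 140-sound set and 5 AE classes).
#'
#' @param n_originals Number of original sounds (default 140).
#' @param n_variants Number of AE classes (default 5).
#' @return Integer trial count.
#' @export
rating_trial_count <- function(n_originals = 140,
                               n_variants = length(ae_variants())) {
  as.integer(n_originals) * as.integer(n_variants)
}
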