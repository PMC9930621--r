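#' Generate a synthetic multi-subject beta cohort
#'
#' Per subject, run and condition the voxel betas are the ground-truth class
#' means plus i.i.d. Gaussian noise. Class means follow the ground-truth
#' profiles: core voxels load `effect` on the original voice condition only;
#' accessory voxels load `effect/3` on original voice and `effect/6` on the
#' envelope/spectrum and scrambled voice conditions; acoustic voxels load
#' `+/- (effect/2) * v_i` on the voice/nonvoice conditions of the original,
#' envelope/spectrum and scrambled sets (shared pattern). Each subject draws
#' one random amplitude offset per class (`subject_sd`, default 20% of
#' `effect`) applied along the class profile, giving meaningful
#' between-subject variance for group tests. Noise is independent across
#' runs, conditions and subjects.
#'
#' @param gt A `ground_truth_map`.
#' @param effect Nominal effect amplitude (default 1).
#' @param noise_sd Gaussian noise SD on run-level betas (default 0.5).
#' @param n_runs Runs per subject (>= 2; default 8).
#' @param n_subjects Number of subjects (default 25).
#' @param seed Integer seed.
#' @param subject_sd Between-subject SD of the class amplitude (default
#'   `0.2 * effect`).
#' @return A `synthetic_cohort`: list with `betas` (per subject an array
#'   voxels x 12 conditions x runs), `ground_truth`, and the parameters.
#' @export
gen_subject_betas <- function(gt, effect = 1, noise_sd = 0.5, n_runs = 8,
                              n_subjects = 25, seed = 1,
                              subject_sd = 0.2 * effect) {
  stopifnot(inherits(gt, "ground_truth_map"))
  if (n_runs < 2) stop("n_runs must be >= 2 (cross-validation needs folds)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  conds <- va_conditions()
  n_vox <- prod(gt$grid$dims)
  prof <- gt$class_profiles
  cls <- gt$voxel_class
  ## voxel x condition loading matrix in units of the class primary amplitude
  load_core <- outer(as.numeric(cls == "core"), prof$core)
  load_acc <- outer(as.numeric(cls == "accessory"), prof$accessory)
  load_ac <- outer(gt$pattern_weights, prof$acoustic_sign)
  amp <- c(core = effect, accessory = effect / 3, acoustic = effect / 2)
  betas <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    z <- rnorm(3, 0, subject_sd)
    mu <- (amp[["core"]] + z[1]) * load_core +
      (amp[["accessory"]] + z[2]) * load_acc +
      (amp[["acoustic"]] + z[3]) * load_ac
    arr <- array(rnorm(n_vox * 12 * n_runs, 0, noise_sd),
                 dim = c(n_vox, 12, n_runs),
                 dimnames = list(NULL, conds, NULL))
    arr <- arr + as.vector(mu)                        # recycled over runs
    betas[[s]] <- arr
  }
  structure(list(betas = betas, ground_truth = gt, grid = gt$grid,
                 conditions = conds, n_subjects = n_subjects,
                 n_runs = n_runs, effect = effect, noise_sd = noise_sd,
                 subject_sd = subject_sd, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d subjects x %d runs, grid %s, effect %g, noise %g>\n",
              x$n_subjects, x$n_runs, paste(x$grid$dims, collapse = "x"),
              x$effect, x$noise_sd))
  invisible(x)
}

#' Run-averaged betas for one subject
#' @param cohort A `synthetic_cohort`.
#' @param subject Subject index.
#' @return Matrix voxels x 12 conditions.
#' @export
subject_mean_betas <- function(cohort, subject) {
  arr <- cohort$betas[[subject]]
  m <- apply(arr, c(1, 2), mean)
  colnames(m) <- cohort$conditions
  m
}

#' Simulate a BOLD run from betas and a schedule
#'
#' Time series = task design (HRF-convolved condition boxcars) times the
#' voxel betas, plus Gaussian noise and, optionally, sinusoidal physiological
#' confounds generated from RETROICOR-style cardiac/respiratory phases with
#' random per-voxel weights. 197 volumes at TR 1.6 s by default.
#'
#' @param schedule An `experiment_schedule`.
#' @param betas Matrix voxels x 12 conditions (columns named as
#'   [va_conditions()]).
#' @param run Which run of the schedule to simulate (default 1).
#' @param noise_sd Temporal noise SD (default 0).
#' @param physio If `TRUE`, add physiological confounds; the phases used are
#'   returned so they can be included in the fitting design.
#' @param tr_s,n_volumes Acquisition timing (defaults 1.6 s, 197).
#' @param seed Integer seed.
#' @return List with `timeseries` (volumes x voxels), `design` (task-only
#'   design used for generation) and `physio` (phases or `NULL`).
#' @export
gen_bold_run <- function(schedule, betas, run = 1, noise_sd = 0,
                         physio = FALSE, tr_s = 1.6, n_volumes = 197,
                         seed = 1) {
  stopifnot(inherits(schedule, "experiment_schedule"))
  betas <- as.matrix(betas)
  if (!all(va_conditions() %in% colnames(betas)))
    stop("betas must carry the 12 condition labels matching the schedule")
  set.seed(seed)
  X <- build_design(schedule, run = run, tr_s = tr_s, n_volumes = n_volumes)
  task <- unclass(X)[, va_conditions(), drop = FALSE]
  Y <- task %*% t(betas[, va_conditions(), drop = FALSE])
  phases <- NULL
  if (physio) {
    phases <- synth_physio_phases(n_volumes, tr_s, seed = seed + 1)
    Xp <- cbind(sin(phases$cardiac), cos(phases$cardiac),
                sin(phases$resp), cos(phases$resp))
    W <- matrix(rnorm(4 * ncol(Y), 0, 0.5), 4)
    Y <- Y + Xp %*% W
  }
  if (noise_sd > 0) Y <- Y + rnorm(length(Y), 0, noise_sd)
  list(timeseries = Y, design = X, physio = phases)
}
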