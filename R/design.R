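#' Canonical two-gamma haemodynamic response function
#'
#' Difference of two gamma densities (response delay 6, undershoot delay 16,
#' undershoot ratio 6, unit time constants; no derivatives), the standard
#' canonical shape peaking about 5 s after onset.
#'
#' @param t Time in seconds (vector).
#' @return HRF values, peak-normalized to 1.
#' @export
hrf_canonical <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h / max(h)
}

#' Synthesize cardiac and respiratory phase traces
#'
#' Monotone phases for a slowly drifting cardiac (~1 Hz) and respiratory
#' (~0.3 Hz) rhythm, sampled at the volume acquisition times. Used to build
#' RETROICOR-style nuisance regressors for simulated runs.
#'
#' @param n_volumes Number of volumes.
#' @param tr_s Repetition time in seconds.
#' @param cardiac_hz,resp_hz Mean rates.
#' @param seed Integer seed.
#' @return List with `cardiac` and `resp` phase vectors (radians).
#' @export
synth_physio_phases <- function(n_volumes, tr_s = 1.6, cardiac_hz = 1.05,
                                resp_hz = 0.3, seed = 1) {
  set.seed(seed)
  t <- (seq_len(n_volumes) - 1) * tr_s
  drift <- function(f) f * (1 + 0.1 * sin(2 * pi * runif(1, 0.005, 0.02) * t +
                                            runif(1, 0, 2 * pi)))
  list(cardiac = 2 * pi * cumsum(drift(cardiac_hz)) * tr_s,
       resp = 2 * pi * cumsum(drift(resp_hz)) * tr_s)
}

#' Build the run design matrix
#'
#' Task regressors are per-condition block boxcars convolved with the
#' canonical two-gamma HRF and sampled at the TR, plus one button-press event
#' regressor: 13 task columns. Optional nuisance blocks: 6 motion columns
#' (supplied) and 18 RETROICOR columns built as sine/cosine Fourier
#' expansions of the cardiac phase (order 3: 6 columns), respiratory phase
#' (order 4: 8 columns) and their interaction phases (order 1: 4 columns).
#' A constant column is always appended.
#'
#' @param schedule An `experiment_schedule`.
#' @param run Which run of the schedule to build (default 1).
#' @param tr_s Repetition time in seconds (default 1.6).
#' @param n_volumes Volumes per run (default 197).
#' @param motion Optional `n_volumes` x 6 matrix of motion parameters.
#' @param physio Optional list with `cardiac` and `resp` phase vectors (as
#'   from [synth_physio_phases()]) and optionally `orders`
#'   (default `c(cardiac = 3, resp = 4, interaction = 1)`).
#' @return A `design_matrix`: numeric matrix (volumes x regressors) with
#'   attributes `task_cols`, `nuisance_cols`, `tr_s`.
#' @export
build_design <- function(schedule, run = 1, tr_s = 1.6, n_volumes = 197,
                         motion = NULL, physio = NULL) {
  stopifnot(inherits(schedule, "experiment_schedule"))
  if (n_volumes * tr_s < schedule$run_duration)
    stop("n_volumes x tr_s shorter than the scheduled run")
  blocks <- schedule$blocks[schedule$blocks$run == run, ]
  if (nrow(blocks) == 0) stop("schedule has no blocks for run ", run)
  if (all(blocks$duration <= 0)) stop("degenerate schedule: no events")
  dt <- 0.1                                           # convolution grid (s)
  t_hi <- seq(0, n_volumes * tr_s, by = dt)
  hrf <- hrf_canonical(seq(0, 32, by = dt))
  vol_t <- (seq_len(n_volumes) - 1) * tr_s
  cols <- list()
  for (cond in schedule$conditions) {
    bc <- numeric(length(t_hi))
    for (i in which(blocks$condition == cond)) {
      on <- blocks$onset[i]
      bc[t_hi >= on & t_hi < on + blocks$duration[i]] <- 1
    }
    conv <- stats::convolve(bc, rev(hrf), type = "open")[seq_along(t_hi)] * dt
    cols[[cond]] <- approx(t_hi, conv, xout = vol_t, rule = 2)$y
  }
  press <- numeric(length(t_hi))
  bp <- schedule$button_presses
  for (tt in bp$time[bp$run == run]) {
    press[which.min(abs(t_hi - tt))] <- 1 / dt        # unit-area event
  }
  conv <- stats::convolve(press, rev(hrf), type = "open")[seq_along(t_hi)] * dt
  cols[["button_press"]] <- approx(t_hi, conv, xout = vol_t, rule = 2)$y
  task_cols <- names(cols)
  if (any(vapply(cols[schedule$conditions], function(v) all(v == 0), TRUE)))
    stop("all-zero task column: condition missing from the run")
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == n_volumes, ncol(motion) == 6)
    colnames(motion) <- paste0("motion_", 1:6)
    for (j in 1:6) cols[[colnames(motion)[j]]] <- motion[, j]
  }
  if (!is.null(physio)) {
    if (is.null(physio$cardiac) || is.null(physio$resp))
      stop("physio regressors requested but phase traces are missing")
    orders <- physio$orders %||% c(cardiac = 3, resp = 4, interaction = 1)
    pc <- physio$cardiac[seq_len(n_volumes)]
    pr <- physio$resp[seq_len(n_volumes)]
    for (k in seq_len(orders[["cardiac"]])) {
      cols[[paste0("cardiac_sin", k)]] <- sin(k * pc)
      cols[[paste0("cardiac_cos", k)]] <- cos(k * pc)
    }
    for (k in seq_len(orders[["resp"]])) {
      cols[[paste0("resp_sin", k)]] <- sin(k * pr)
      cols[[paste0("resp_cos", k)]] <- cos(k * pr)
    }
    for (k in seq_len(orders[["interaction"]])) {
      cols[[paste0("inter_sin_plus", k)]] <- sin(k * (pc + pr))
      cols[[paste0("inter_cos_plus", k)]] <- cos(k * (pc + pr))
      cols[[paste0("inter_sin_minus", k)]] <- sin(k * (pc - pr))
      cols[[paste0("inter_cos_minus", k)]] <- cos(k * (pc - pr))
    }
  }
  cols[["constant"]] <- rep(1, n_volumes)
  X <- do.call(cbind, cols)
  structure(X, task_cols = task_cols,
            nuisance_cols = setdiff(colnames(X), task_cols),
            tr_s = tr_s, class = c("design_matrix", class(X)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit voxel-wise ordinary-least-squares GLMs
#'
#' @param timeseries Matrix (time x voxels) or vector (one voxel).
#' @param design A `design_matrix` (or any numeric matrix with named
#'   columns).
#' @return List with `betas` (regressor x voxel matrix), `residual_variance`
#'   (per voxel, df = T - rank) and `df`.
#' @export
fit_glm <- function(timeseries, design) {
  Y <- as.matrix(timeseries)
  X <- unclass(design)
  if (nrow(Y) != nrow(X))
    stop("time dimension of the data does not match the design")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  betas <- qr.coef(qrX, Y)
  res <- Y - X %*% betas
  df <- nrow(X) - qrX$rank
  rownames(betas) <- colnames(X)
  list(betas = betas, residual_variance = colSums(res^2) / df, df = df)
}
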