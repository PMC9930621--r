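#' Statistical map
#'
#' Voxel grid of group statistics with thresholding metadata. `t` and `p`
#' (one-sided, in the direction of the contrast weights) are stored as 3-D
#' arrays; the significance mask follows the threshold rule.
#'
#' @name stat_map
NULL

new_stat_map <- function(t, p, df, mask, threshold, contrast, grid) {
  structure(list(t = t, p = p, df = df, mask = mask, threshold = threshold,
                 contrast = contrast, grid = grid), class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map '%s': %d significant voxels at %s alpha=%g (df %s)>\n",
              x$contrast, sum(x$mask), x$threshold$rule, x$threshold$alpha,
              format(x$df)))
  invisible(x)
}

#' Threshold rule descriptor
#'
#' @param rule `"uncorrected"`, `"fwe"` (Bonferroni over in-mask voxels) or
#'   `"fdr"` (Benjamini-Hochberg).
#' @param alpha Significance level (defaults: 0.001 uncorrected, 0.05
#'   fwe/fdr).
#' @return List describing the rule.
#' @export
va_threshold <- function(rule = c("fwe", "uncorrected", "fdr"),
                         alpha = NULL) {
  rule <- match.arg(rule)
  alpha <- alpha %||% switch(rule, uncorrected = 0.001, fwe = 0.05,
                             fdr = 0.05)
  list(rule = rule, alpha = alpha)
}

apply_threshold <- function(p, threshold) {
  n <- length(p)
  switch(threshold$rule,
         uncorrected = p < threshold$alpha,
         fwe = p < threshold$alpha / n,
         fdr = {
           adj <- stats::p.adjust(p, "BH")
           adj < threshold$alpha
         })
}

#' Isotropic Gaussian smoothing on the voxel grid
#'
#' Separable convolution with a truncated (3 sigma), renormalized Gaussian
#' kernel; FWHM is converted to sigma by `fwhm / (2*sqrt(2*log(2)))`.
#'
#' @param arr 3-D numeric array.
#' @param fwhm_mm Kernel FWHM in mm (0 = no smoothing).
#' @param voxel_size_mm Voxel edge in mm.
#' @return Smoothed array of the same dimensions.
#' @export
gaussian_smooth_3d <- function(arr, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm <= 0) return(arr)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  for (axis in 1:3) arr <- convolve_axis(arr, k, axis)
  arr
}

## 1-D convolution along one axis with edge renormalization (kernel mass
## outside the grid is redistributed, so constants stay constant).
convolve_axis <- function(arr, k, axis) {
  d <- dim(arr)
  r <- (length(k) - 1L) / 2L
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- dim(a)[1]
  m <- matrix(a, nrow = n)
  pad <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
  ones <- c(rep(0, r), rep(1, n), rep(0, r))
  out <- matrix(0, n, ncol(m))
  wsum <- numeric(n)
  for (j in seq_along(k)) {
    idx <- (seq_len(n)) + (j - 1L)
    out <- out + k[j] * pad[idx, , drop = FALSE]
    wsum <- wsum + k[j] * ones[idx]
  }
  out <- out / wsum
  aperm(array(out, dim(a)), order(perm))
}

## One-sample t over subjects (rows = subjects); one-sided p in the positive
## direction. Zero-variance voxels: t = +/-Inf if the mean is nonzero, else 0.
one_sample_t <- function(mat, mu = 0) {
  n <- nrow(mat)
  m <- colMeans(mat) - mu
  s <- apply(mat, 2, sd)
  t <- ifelse(s > 0, m / (s / sqrt(n)), ifelse(m > 0, Inf,
                                               ifelse(m < 0, -Inf, 0)))
  list(t = t, p = pt(t, df = n - 1, lower.tail = FALSE), df = n - 1)
}

#' Group contrast map over a cohort
#'
#' Computes the weighted combination of run-averaged condition betas per
#' subject, optionally smooths each subject's contrast image, and runs a
#' voxel-wise one-sample t-test over subjects (one-sided in the contrast
#' direction), thresholded by the given rule.
#'
#' @param cohort A `synthetic_cohort` (or list with `betas`, `grid`,
#'   `conditions`).
#' @param weights Numeric vector of length 12, named by condition or in
#'   [va_conditions()] order. Difference contrasts must sum to 0.
#' @param threshold A [va_threshold()] (default FWE 0.05).
#' @param smoothing_fwhm_mm Smoothing of subject contrast images in mm
#'   (default 8; use 4 for the replication setting and 0 for voxel-exact
#'   recovery scoring).
#' @param contrast_name Label stored in the map.
#' @return A `stat_map`.
#' @export
group_contrast <- function(cohort, weights, threshold = va_threshold("fwe"),
                           smoothing_fwhm_mm = 8,
                           contrast_name = "contrast") {
  if (cohort$n_subjects < 3) stop("need at least 3 subjects")
  w <- align_weights(weights, cohort$conditions)
  if (any(w < 0) && abs(sum(w)) > 1e-9)
    stop("difference contrasts must have weights summing to 0")
  d <- cohort$grid$dims
  n_vox <- prod(d)
  subj <- matrix(0, cohort$n_subjects, n_vox)
  for (s in seq_len(cohort$n_subjects)) {
    cimg <- as.vector(subject_mean_betas(cohort, s) %*% w)
    if (smoothing_fwhm_mm > 0)
      cimg <- as.vector(gaussian_smooth_3d(array(cimg, d), smoothing_fwhm_mm,
                                           cohort$grid$voxel_size_mm))
    subj[s, ] <- cimg
  }
  tt <- one_sample_t(subj)
  mask <- apply_threshold(tt$p, threshold)
  new_stat_map(array(tt$t, d), array(tt$p, d), tt$df, array(mask, d),
               threshold, contrast_name, cohort$grid)
}

align_weights <- function(weights, conditions) {
  if (!is.null(names(weights))) {
    w <- setNames(rep(0, length(conditions)), conditions)
    if (!all(names(weights) %in% conditions))
      stop("unknown condition in contrast weights")
    w[names(weights)] <- weights
    w
  } else {
    stopifnot(length(weights) == length(conditions))
    setNames(as.numeric(weights), conditions)
  }
}

#' Interaction contrast weights for one AE class
#'
#' The contrast `(original voice > original nonvoice) minus (AE voice > AE
#' nonvoice)`: weights (+1, -1, -1, +1) on (orig_voice, orig_nonvoice,
#' AE_voice, AE_nonvoice), zero elsewhere. Negate for the reversed
#' interaction.
#'
#' @param ae_variant One of `"e_s"`, `"scr"`, `"p_a"`, `"rip"`, `"tsp"`.
#' @return Named weight vector of length 12.
#' @export
interaction_contrast <- function(ae_variant) {
  ae_variant <- match.arg(ae_variant, ae_variants())
  w <- setNames(rep(0, 12), va_conditions())
  w["orig_voice"] <- 1
  w["orig_nonvoice"] <- -1
  w[paste0(ae_variant, "_voice")] <- -1
  w[paste0(ae_variant, "_nonvoice")] <- 1
  w
}

#' Minimum-statistic conjunction of statistical maps
#'
#' Tests against the conjunction null: a voxel survives only if every
#' component map is individually significant. The conjunction statistic is
#' the voxel-wise minimum t.
#'
#' @param stat_maps List of `stat_map`s on one grid with a shared threshold
#'   rule.
#' @return A `stat_map` whose mask is the intersection of the component
#'   masks.
#' @export
conjunction_mask <- function(stat_maps) {
  stopifnot(length(stat_maps) >= 1)
  g <- stat_maps[[1]]$grid
  for (m in stat_maps) {
    if (!identical(m$grid$dims, g$dims)) stop("grid mismatch")
  }
  tmin <- Reduce(pmin, lapply(stat_maps, `[[`, "t"))
  pmax_ <- Reduce(pmax, lapply(stat_maps, `[[`, "p"))
  mask <- Reduce(`&`, lapply(stat_maps, `[[`, "mask"))
  new_stat_map(tmin, pmax_, stat_maps[[1]]$df, mask,
               stat_maps[[1]]$threshold,
               paste0("conjunction(",
                      paste(vapply(stat_maps, `[[`, "", "contrast"),
                            collapse = ", "), ")"), g)
}

#' Scaled voice-selectivity maps
#'
#' Per subject and voxel, each condition's run-averaged beta is rescaled so
#' the original nonvoice condition maps to 0 and the original voice condition
#' to 1: `scaled(c) = (beta_c - beta_orig_nonvoice) / (beta_orig_voice -
#' beta_orig_nonvoice)`. A voxel is voice-selective for a subject when all 10
#' AE conditions stay strictly below the criterion (default 1/3, the 66%
#' selectivity criterion). Voxels with a zero denominator are marked invalid
#' and excluded from the group sum.
#'
#' @param cohort A `synthetic_cohort`.
#' @param criterion Scaled-magnitude criterion (default `1/3`).
#' @param eps Denominator tolerance (default 1e-12).
#' @return List with `subject_maps` (voxels x subjects logical),
#'   `group_sum` (3-D array of per-voxel counts over valid subjects),
#'   `n_invalid` (excluded voxel-subject pairs) and `criterion`.
#' @export
selectivity_map <- function(cohort, criterion = 1 / 3, eps = 1e-12) {
  conds <- cohort$conditions
  ae_conds <- setdiff(conds, c("orig_voice", "orig_nonvoice"))
  n_vox <- prod(cohort$grid$dims)
  sel <- matrix(NA, n_vox, cohort$n_subjects)
  for (s in seq_len(cohort$n_subjects)) {
    b <- subject_mean_betas(cohort, s)
    denom <- b[, "orig_voice"] - b[, "orig_nonvoice"]
    valid <- abs(denom) > eps
    scaled <- (b[, ae_conds, drop = FALSE] - b[, "orig_nonvoice"]) / denom
    ok <- rowSums(scaled < criterion) == length(ae_conds)
    sel[, s] <- ifelse(valid, ok, NA)
  }
  group_sum <- array(rowSums(sel, na.rm = TRUE), cohort$grid$dims)
  list(subject_maps = sel, group_sum = group_sum,
       n_invalid = sum(is.na(sel)), criterion = criterion)
}

#' Scaled condition magnitudes at given betas
#'
#' The selectivity scaling applied to one voxel's condition betas; exposed for
#' direct verification (anchoring identities and affine invariance).
#'
#' @param betas Named vector of 12 condition betas.
#' @return Named vector of scaled magnitudes (orig_nonvoice -> 0,
#'   orig_voice -> 1), or all-`NA` when the denominator is zero.
#' @export
scaled_magnitudes <- function(betas) {
  betas <- align_weights(betas, va_conditions())
  denom <- betas[["orig_voice"]] - betas[["orig_nonvoice"]]
  if (abs(denom) < 1e-12) return(setNames(rep(NA_real_, 12), va_conditions()))
  (betas - betas[["orig_nonvoice"]]) / denom
}
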