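#' Voxel grid geometry
#'
#' @param dims Integer vector of 3 voxel counts (default `c(20, 20, 12)`).
#' @param voxel_size_mm Isotropic voxel edge in mm (default 2.75, the
#'   in-plane acquisition resolution).
#' @param hemi_axis Axis along which hemispheres are split (default 1).
#' @param hemi_split Index dividing left from right; voxels with coordinate
#'   `<= hemi_split` on the split axis are left (default `dims[hemi_axis]/2`).
#' @return A `va_grid` list.
#' @export
va_grid <- function(dims = c(20, 20, 12), voxel_size_mm = 2.75,
                    hemi_axis = 1, hemi_split = NULL) {
  stopifnot(length(dims) == 3, all(dims >= 1), voxel_size_mm > 0)
  structure(list(dims = as.integer(dims), voxel_size_mm = voxel_size_mm,
                 hemi_axis = hemi_axis,
                 hemi_split = hemi_split %||% floor(dims[hemi_axis] / 2)),
            class = "va_grid")
}

grid_coords <- function(grid) {
  d <- grid$dims
  cbind(x = rep(seq_len(d[1]), times = d[2] * d[3]),
        y = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
        z = rep(seq_len(d[3]), each = d[1] * d[2]))
}

#' Hemisphere label per voxel
#' @param grid A `va_grid`.
#' @return Character vector (`"left"`/`"right"`), voxels on the split plane
#'   go left.
#' @export
hemisphere_of <- function(grid) {
  co <- grid_coords(grid)[, grid$hemi_axis]
  ifelse(co <= grid$hemi_split, "left", "right")
}

#' Generate a ground-truth voxel class map
#'
#' Places one contiguous, quasi-spherical blob per class (`core`, `acoustic`,
#' `accessory`) in each hemisphere, with at least `margin` voxels of null
#' space between blobs of different classes and from the hemisphere split, so
#' that boundary effects of smoothing or searchlight neighbourhoods are
#' attributable to a single region. Remaining voxels are null. Acoustic-class
#' voxels additionally carry a per-voxel pattern weight `v_i`, drawn uniformly
#' in `[0.5, 1.5]`: voice conditions of the original, envelope/spectrum and
#' scrambled sound sets load `+v_i` and their nonvoice counterparts `-v_i`
#' (in units of half the nominal effect), giving these voxels a shared
#' univariate effect across the three sound sets plus a voxel-specific
#' multivoxel pattern. Reproducible under the seed.
#'
#' @param grid_dims 3-vector of voxel counts or a [va_grid()].
#' @param region_fractions Named fractions for `core`, `acoustic`,
#'   `accessory` (of the total voxel count; defaults 0.05, 0.04, 0.08).
#' @param seed Integer seed.
#' @param margin Minimum empty-voxel separation between classes (default 2).
#' @return A `ground_truth_map`: list with `grid`, `voxel_class` (character
#'   vector over voxels), `pattern_weights`, `class_profiles` and bookkeeping.
#' @export
gen_ground_truth <- function(grid_dims = c(20, 20, 12),
                             region_fractions = c(core = 0.05,
                                                  acoustic = 0.04,
                                                  accessory = 0.08),
                             seed = 1, margin = 2) {
  grid <- if (inherits(grid_dims, "va_grid")) grid_dims else va_grid(grid_dims)
  fr <- region_fractions[c("core", "acoustic", "accessory")]
  fr[is.na(fr)] <- 0
  names(fr) <- c("core", "acoustic", "accessory")
  if (any(fr < 0) || sum(fr) > 1) stop("fractions must be >= 0 and sum <= 1")
  set.seed(seed)
  n_vox <- prod(grid$dims)
  co <- grid_coords(grid)
  hemi <- hemisphere_of(grid)
  lab <- rep("null", n_vox)
  for (h in c("left", "right")) {
    in_hemi <- hemi == h
    ## keep a margin from the split plane so regions never straddle it
    dist_split <- abs(co[, grid$hemi_axis] -
                        (grid$hemi_split + if (h == "left") 0 else 1))
    allowed_hemi <- in_hemi & dist_split >= 1
    for (cls in c("core", "acoustic", "accessory")) {
      target <- round(fr[[cls]] * n_vox / 2)
      if (target == 0) next
      lab <- grow_blob(lab, co, allowed_hemi, cls, target, margin, grid$dims)
    }
  }
  pattern_weights <- numeric(n_vox)
  ac <- lab == "acoustic"
  pattern_weights[ac] <- runif(sum(ac), 0.5, 1.5)
  structure(list(
    grid = grid, voxel_class = lab, pattern_weights = pattern_weights,
    region_fractions = fr, margin = margin, seed = seed,
    class_profiles = class_profiles()), class = "ground_truth_map")
}

## Condition-loading profiles per class, in units of the class's primary
## amplitude (core: effect; acoustic: effect/2; accessory: effect/3).
class_profiles <- function() {
  conds <- va_conditions()
  prof <- function(v) setNames(v, conds)
  zero <- rep(0, 12)
  core <- zero; core[match("orig_voice", conds)] <- 1
  acc <- zero
  acc[match("orig_voice", conds)] <- 1
  acc[match(c("e_s_voice", "scr_voice"), conds)] <- 0.5
  ac_sign <- zero
  ac_sign[match(c("orig_voice", "e_s_voice", "scr_voice"), conds)] <- 1
  ac_sign[match(c("orig_nonvoice", "e_s_nonvoice", "scr_nonvoice"), conds)] <- -1
  list(core = prof(core), accessory = prof(acc), acoustic_sign = prof(ac_sign),
       null = prof(zero))
}

## Grow a quasi-spherical contiguous blob of `target` voxels for class `cls`,
## forbidding voxels within `margin` (Euclidean, in voxels) of other classes.
grow_blob <- function(lab, co, allowed_hemi, cls, target, margin, dims) {
  other <- which(lab != "null")
  forbidden <- rep(FALSE, length(lab))
  if (length(other)) {
    for (ov in other) {
      d2 <- (co[, 1] - co[ov, 1])^2 + (co[, 2] - co[ov, 2])^2 +
        (co[, 3] - co[ov, 3])^2
      forbidden <- forbidden | d2 <= margin^2
    }
  }
  ok <- allowed_hemi & !forbidden & lab == "null"
  ## seed away from grid edges when possible
  interior <- ok & co[, 1] > 1 & co[, 1] < dims[1] & co[, 2] > 2 &
    co[, 2] < dims[2] - 1 & co[, 3] > 2 & co[, 3] < dims[3] - 1
  cand <- which(if (any(interior)) interior else ok)
  if (!length(cand)) stop("grid too small to host the requested regions")
  seed_vox <- cand[sample(length(cand), 1)]
  d2seed <- (co[, 1] - co[seed_vox, 1])^2 + (co[, 2] - co[seed_vox, 2])^2 +
    (co[, 3] - co[seed_vox, 3])^2
  ord <- order(d2seed, seq_along(d2seed))
  ord <- ord[ok[ord]]
  ## nearest-first growth gives a compact blob; contiguity follows because
  ## Euclidean balls around the seed are connected on the voxel lattice
  if (length(ord) < target)
    stop("grid too small to host the requested regions")
  lab[ord[seq_len(target)]] <- cls
  lab
}

#' @export
print.ground_truth_map <- function(x, ...) {
  tab <- table(factor(x$voxel_class,
                      levels = c("core", "acoustic", "accessory", "null")))
  cat(sprintf("<ground_truth_map %s: core %d, acoustic %d, accessory %d, null %d>\n",
              paste(x$grid$dims, collapse = "x"), tab["core"], tab["acoustic"],
              tab["accessory"], tab["null"]))
  invisible(x)
}
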