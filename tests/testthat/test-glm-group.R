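test_that("a null contrast yields t = 0 everywhere and an empty mask", {
  co <- small_cohort_hisnr()
  m <- group_contrast(co, rep(0, 12), smoothing_fwhm_mm = 0,
                      threshold = va_threshold("uncorrected"))
  expect_true(all(m$t == 0))
  expect_false(any(m$mask))
})

test_that("FWE masks nest within uncorrected 0.001 masks", {
  co <- small_cohort_hisnr()
  w <- c(orig_voice = 1, orig_nonvoice = -1)
  m_unc <- group_contrast(co, w, va_threshold("uncorrected", 0.001), 0)
  m_fwe <- group_contrast(co, w, va_threshold("fwe", 0.05), 0)
  expect_true(all(!m_fwe$mask | m_unc$mask))
  expect_gt(sum(m_unc$mask), 0)
})

test_that("the voice contrast recovers the amplitude-coding regions at high SNR", {
  co <- small_cohort_hisnr()
  gt <- small_gt()
  m <- define_original_va(co, va_threshold("fwe"), smoothing_fwhm_mm = 0)
  target <- gt$voxel_class %in% c("core", "accessory")
  recall <- sum(m$mask & array(target, gt$grid$dims)) / sum(target)
  expect_gte(recall, 0.9)
})

test_that("smoothing preserves constants and the FWHM conversion", {
  arr <- array(2.5, c(8, 8, 6))
  sm <- gaussian_smooth_3d(arr, 8, 2.75)
  expect_equal(sm, arr, tolerance = 1e-12)
  ## a delta spreads: centre value drops, interior mass is preserved
  d <- array(0, c(13, 13, 13)); d[7, 7, 7] <- 1
  sd_ <- gaussian_smooth_3d(d, 6, 2.75)
  expect_lt(sd_[7, 7, 7], 1)
  expect_equal(sum(sd_), 1, tolerance = 1e-9)
})

test_that("interaction contrasts have the (+1,-1,-1,+1) structure", {
  for (v in ae_variants()) {
    w <- interaction_contrast(v)
    expect_equal(sum(w), 0)
    expect_equal(sum(w != 0), 4)
    expect_equal(w[["orig_voice"]], 1)
    expect_equal(w[[paste0(v, "_nonvoice")]], 1)
  }
  expect_error(interaction_contrast("orig"))
})

test_that("core voxels show positive interaction t for every AE; reversed interactions are empty", {
  co <- small_cohort_hisnr()
  gt <- small_gt()
  core <- array(gt$voxel_class == "core", gt$grid$dims)
  for (v in ae_variants()) {
    m <- group_contrast(co, interaction_contrast(v), va_threshold("fwe"), 0)
    expect_true(all(m$t[core] > 0))
    expect_true(all(m$mask[core]))
    rev_m <- group_contrast(co, -interaction_contrast(v),
                            va_threshold("fwe"), 0)
    expect_equal(sum(rev_m$mask), 0)
  }
})

test_that("conjunction equals the exhaustive mask intersection", {
  co <- small_cohort_hisnr()
  maps <- lapply(c("e_s", "p_a"), function(v)
    group_contrast(co, interaction_contrast(v), va_threshold("fwe"), 0))
  conj <- conjunction_mask(maps)
  expect_identical(conj$mask, maps[[1]]$mask & maps[[2]]$mask)
  expect_true(all(!conj$mask | maps[[1]]$mask))
  expect_true(all(!conj$mask | maps[[2]]$mask))
  ## identity on a single map
  expect_identical(conjunction_mask(maps[1])$mask, maps[[1]]$mask)
  bad <- maps[[1]]
  bad$grid <- va_grid(c(2, 2, 2))
  expect_error(conjunction_mask(list(maps[[1]], bad)), "grid")
})

test_that("selectivity scaling anchors and affine invariance hold", {
  set.seed(8)
  for (i in 1:20) {
    b <- setNames(rnorm(12), va_conditions())
    s <- scaled_magnitudes(b)
    expect_equal(s[["orig_nonvoice"]], 0)
    expect_equal(s[["orig_voice"]], 1)
    s2 <- scaled_magnitudes(runif(1, 0.1, 5) * b + rnorm(1))
    expect_equal(unname(s), unname(s2), tolerance = 1e-8)
  }
  ## hand-computed example: all AEs at or below 0.6 of a 0..2 range scale
  ## to <= 0.3, below the 1/3 criterion
  b <- setNames(rep(0.6, 12), va_conditions())
  b["orig_voice"] <- 2; b["orig_nonvoice"] <- 0
  s <- scaled_magnitudes(b)
  ae_conds <- setdiff(va_conditions(), c("orig_voice", "orig_nonvoice"))
  expect_true(all(s[ae_conds] <= 0.3))
  expect_true(all(s[ae_conds] < 1 / 3))
  ## zero denominator flagged
  expect_true(all(is.na(scaled_magnitudes(setNames(rep(1, 12),
                                                   va_conditions())))))
})

test_that("selectivity maps count selective subjects and exclude invalid voxels", {
  gt <- small_gt()
  co <- gen_subject_betas(gt, 1, 0, 2, 4, seed = 2, subject_sd = 0)
  sel <- selectivity_map(co)
  core_idx <- which(gt$voxel_class == "core")
  ## noiseless core voxels: denominator 1, all AEs 0 -> all subjects selective
  expect_true(all(sel$group_sum[core_idx] == 4))
  ## null voxels have zero denominator -> invalid, excluded
  null_idx <- which(gt$voxel_class == "null")
  expect_true(all(sel$group_sum[null_idx] == 0))
  expect_gt(sel$n_invalid, 0)
  ## accessory voxels: denominator 1/3, scaled e_s = (1/6)/(1/3) = 0.5 > 1/3
  acc_idx <- which(gt$voxel_class == "accessory")
  expect_true(all(sel$group_sum[acc_idx] == 0))
})
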