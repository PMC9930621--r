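test_that("ground-truth regions are disjoint, hemispheric and reproducible", {
  gt <- gen_ground_truth(c(20, 20, 12), seed = 3)
  expect_s3_class(gt, "ground_truth_map")
  ## per-voxel labels are single-valued by construction; check counts and
  ## per-hemisphere placement instead
  hemi <- hemisphere_of(gt$grid)
  for (cl in c("core", "acoustic", "accessory")) {
    n_l <- sum(gt$voxel_class == cl & hemi == "left")
    n_r <- sum(gt$voxel_class == cl & hemi == "right")
    expect_equal(n_l, n_r)
    expect_gt(n_l, 0)
  }
  ## classes pairwise disjoint: exhaustive per-voxel check on index sets
  idx <- lapply(c("core", "acoustic", "accessory", "null"),
                function(cl) which(gt$voxel_class == cl))
  for (i in 1:3) for (j in (i + 1):4)
    expect_length(intersect(idx[[i]], idx[[j]]), 0)
  expect_equal(sum(lengths(idx)), prod(gt$grid$dims))
  ## inter-class margin: no two voxels of different signal classes adjacent
  co <- vaparc:::grid_coords(gt$grid)
  sig <- which(gt$voxel_class != "null")
  for (v in sig[seq(1, length(sig), by = 7)]) {
    d2 <- colSums((t(co[sig, , drop = FALSE]) - co[v, ])^2)
    close <- sig[d2 <= gt$margin^2 & d2 > 0]
    expect_true(all(gt$voxel_class[close] == gt$voxel_class[v]))
  }
  expect_identical(gt, gen_ground_truth(c(20, 20, 12), seed = 3))
})

test_that("zero fractions give an all-null map; impossible requests error", {
  gt0 <- gen_ground_truth(c(10, 10, 6),
                          c(core = 0, acoustic = 0, accessory = 0), seed = 1)
  expect_true(all(gt0$voxel_class == "null"))
  expect_error(gen_ground_truth(c(4, 4, 2), c(core = 0.5, acoustic = 0.3,
                                              accessory = 0.2), seed = 1),
               "too small")
  expect_error(gen_ground_truth(c(10, 10, 6), c(core = 0.9, acoustic = 0.9,
                                                accessory = 0)),
               "sum")
})

test_that("any AE-loading voxel also carries an original-sound effect", {
  ## nesting by construction: the class condition profiles give every
  ## AE-responsive class a (larger) original-voice response
  gt <- small_gt()
  pr <- gt$class_profiles
  expect_gt(pr$accessory[["orig_voice"]], pr$accessory[["e_s_voice"]])
  expect_equal(pr$acoustic_sign[["orig_voice"]],
               pr$acoustic_sign[["e_s_voice"]])
  ae_cols <- grep("^(e_s|scr|p_a|rip|tsp)_", va_conditions(), value = TRUE)
  for (p in pr[c("core", "accessory")]) {
    if (any(p[ae_cols] != 0)) expect_gt(p[["orig_voice"]], 0)
  }
})

test_that("zero-noise cohorts equal the deterministic class means", {
  gt <- small_gt()
  co <- gen_subject_betas(gt, effect = 1, noise_sd = 0, n_runs = 3,
                          n_subjects = 2, seed = 1, subject_sd = 0)
  arr <- co$betas[[1]]
  expect_equal(dim(arr), c(prod(gt$grid$dims), 12, 3))
  core <- which(gt$voxel_class == "core")
  expect_true(all(arr[core, "orig_voice", ] == 1))
  expect_true(all(arr[core, "orig_nonvoice", ] == 0))
  acc <- which(gt$voxel_class == "accessory")
  expect_true(all(arr[acc, "orig_voice", ] == 1 / 3))
  expect_true(all(abs(arr[acc, "e_s_voice", ] - 1 / 6) < 1e-12))
  ac <- which(gt$voxel_class == "acoustic")
  w <- gt$pattern_weights[ac] / 2
  for (v in c("orig", "e_s", "scr")) {
    expect_equal(arr[ac, paste0(v, "_voice"), 1], w)
    expect_equal(arr[ac, paste0(v, "_nonvoice"), 1], -w)
  }
  expect_true(all(arr[gt$voxel_class == "null", , ] == 0))
  ## identical across subjects and runs in the noiseless case
  expect_identical(co$betas[[1]], co$betas[[2]])
})

test_that("cohort generation enforces its preconditions and determinism", {
  gt <- small_gt()
  expect_error(gen_subject_betas(gt, n_runs = 1), "n_runs")
  expect_error(gen_subject_betas(gt, noise_sd = -1), "noise_sd")
  a <- gen_subject_betas(gt, 1, 0.4, 2, 2, seed = 6)
  b <- gen_subject_betas(gt, 1, 0.4, 2, 2, seed = 6)
  expect_identical(a$betas, b$betas)
  expect_equal(length(a$betas), 2)
  expect_equal(dim(a$betas[[1]])[3], 2)
})

test_that("the empirical core effect size matches the closed form", {
  gt <- fixture("gt_default", function() gen_ground_truth(seed = 3))
  co <- gen_subject_betas(gt, effect = 1, noise_sd = 0.5, n_runs = 8,
                          n_subjects = 25, seed = 11)
  core <- which(gt$voxel_class == "core")
  diffs <- vapply(seq_len(25), function(s) {
    b <- subject_mean_betas(co, s)
    mean(b[core, "orig_voice"] - b[core, "orig_nonvoice"])
  }, 0)
  d_emp <- mean(diffs) / stats::sd(diffs)
  ## closed form: subject SD dominates; run noise attenuates with
  ## sqrt(2 / (n_runs * n_vox))
  d_pred <- 1 / sqrt(0.2^2 + 2 * 0.5^2 / (8 * length(core)))
  expect_lt(abs(d_emp - d_pred) / d_pred, 0.3)
})
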