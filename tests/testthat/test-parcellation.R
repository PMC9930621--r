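test_that("coverage percentages reproduce the worked arithmetic", {
  expect_equal(coverage_percent(549, 1653), 33.2)
  expect_equal(coverage_percent(480, 1572), 30.5)
  expect_equal(coverage_percent(323, 1653), 19.5)
  expect_equal(coverage_percent(0, 10), 0)
  expect_true(is.na(coverage_percent(0, 0)))
})

test_that("parcellation partitions the original VA with consistent percentages", {
  grid <- va_grid(c(8, 8, 4))
  n <- prod(grid$dims)
  va <- array(FALSE, grid$dims); va[1:120] <- TRUE
  core <- array(FALSE, grid$dims); core[1:30] <- TRUE
  ac <- array(FALSE, grid$dims); ac[41:60] <- TRUE
  p <- assemble_parcellation(va, core, ac, grid)
  expect_identical(sort(unique(as.vector(p$labels))),
                   sort(c("outside", "core", "acoustic", "accessory")))
  ## labels partition the VA
  expect_equal(sum(p$labels != "outside"), sum(va))
  expect_equal(sum(p$labels == "accessory"), sum(va) - sum(core) - sum(ac))
  for (h in 1:2) {
    row <- p$coverage[h, ]
    expect_equal(row$n_core + row$n_acoustic + row$n_accessory,
                 row$n_original)
    expect_lt(abs(row$percent_core + row$percent_acoustic +
                    row$percent_accessory - 100), 0.1 + 1e-9)
  }
  ## saturation: core = VA
  p2 <- assemble_parcellation(va, va, array(FALSE, grid$dims), grid)
  expect_equal(p2$coverage$percent_core, c(100, 100))
  expect_equal(sum(p2$labels == "accessory"), 0)
  ## violated preconditions are rejected with counts
  bad_core <- array(FALSE, grid$dims); bad_core[n] <- TRUE
  expect_error(assemble_parcellation(va, bad_core, ac, grid),
               "1 core/acoustic voxel")
  expect_error(assemble_parcellation(va, core, core, grid), "overlap")
})

test_that("core and acoustic definitions respect their set algebra", {
  co <- small_cohort_hisnr()
  va <- define_original_va(co, va_threshold("fwe"), 0)
  inter <- lapply(ae_variants(), function(v)
    group_contrast(co, interaction_contrast(v), va_threshold("fwe"), 0))
  names(inter) <- ae_variants()
  core <- define_core_va(inter, va)
  expect_true(all(!core$mask | va$mask))
  ## an empty component empties the conjunction
  empty <- inter[[1]]
  empty$mask <- array(FALSE, dim(empty$mask))
  inter2 <- inter; inter2[["e_s"]] <- empty
  core2 <- define_core_va(inter2, va)
  expect_equal(sum(core2$mask), 0)
  expect_error(define_core_va(inter[1:4], va), "5")
  ## acoustic excludes core and stays inside the VA
  avg <- average_cross_maps(setNames(rep(list(inter[[1]]), 5),
                                     ae_variants()))
  ac <- define_acoustic_va(avg, va, core$mask)
  expect_equal(sum(ac & core$mask), 0)
  expect_true(all(!ac | va$mask))
  ## an empty averaged map gives an empty acoustic VA
  avg0 <- avg; avg0$mask <- array(FALSE, dim(avg0$mask))
  expect_equal(sum(define_acoustic_va(avg0, va, core$mask)), 0)
})

test_that("raising the threshold never grows a mask", {
  co <- small_cohort_hisnr()
  w <- c(orig_voice = 1, orig_nonvoice = -1)
  m_loose <- group_contrast(co, w, va_threshold("uncorrected", 0.01), 0)
  m_tight <- group_contrast(co, w, va_threshold("uncorrected", 0.0001), 0)
  expect_true(all(!m_tight$mask | m_loose$mask))
  expect_lte(sum(m_tight$mask), sum(m_loose$mask))
})

test_that("effect sizes flag degenerate subfields and zero spread", {
  gt <- small_gt()
  co0 <- gen_subject_betas(gt, 1, 0, 2, 3, seed = 1, subject_sd = 0)
  labels <- array("outside", gt$grid$dims)
  labels[which(gt$voxel_class == "core")] <- "core"
  parc <- structure(list(labels = labels, grid = gt$grid),
                    class = "va_parcellation")
  es <- effect_sizes(co0, parc)
  core_orig <- es[es$subfield == "core" & es$sound_set == "orig", ]
  expect_true(is.na(core_orig$cohens_d))
  expect_match(core_orig$flag, "zero between-subject SD")
  expect_true(all(es$flag[es$subfield == "acoustic"] == "empty subfield"))
})

test_that("mid-scale end-to-end recovery labels the ground truth correctly", {
  ## under the default study conditions: the core/accessory distinction is a
  ## threshold criterion, so recovery is defined at the design's power level
  co <- small_cohort_default()
  gt <- small_gt()
  res <- fixture("small_pipeline", function() run_va_pipeline(co))
  sc <- score_recovery(res$parcellation, gt)
  expect_gte(sc$jaccard[sc$class == "core"], 0.8)
  expect_gte(sc$jaccard[sc$class == "acoustic"], 0.7)
  expect_lte(attr(sc, "null_labeled_fraction"), 0.05)
})
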