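test_that("searchlight neighbourhoods match brute-force enumeration", {
  grid <- va_grid(c(7, 6, 5))
  neigh <- searchlight_indices(grid, 5)
  co <- vaparc:::grid_coords(grid)
  vs <- grid$voxel_size_mm
  for (v in c(1, 50, 107, prod(grid$dims))) {
    d <- sqrt(colSums((t(co) - co[v, ])^2)) * vs
    expect_identical(neigh[[v]], sort(which(d <= 5 + 1e-9)))
  }
  ## radius 0 degenerates to the centre voxel
  n0 <- searchlight_indices(grid, 0)
  expect_true(all(vapply(seq_along(n0), function(i)
    identical(n0[[i]], i), TRUE)))
  ## all neighbour indices within bounds
  expect_true(all(unlist(neigh) >= 1 & unlist(neigh) <= prod(grid$dims)))
  expect_error(searchlight_indices(grid, -1), ">= 0")
})

test_that("masked searchlights restrict centres and neighbours", {
  grid <- va_grid(c(5, 5, 4))
  mask <- rep(FALSE, prod(grid$dims))
  mask[1:10] <- TRUE
  neigh <- searchlight_indices(grid, 5, mask = mask)
  expect_length(neigh, 10)
  expect_true(all(unlist(neigh) <= 10))
})

test_that("decoding is perfect on separable patterns and errs on bad folds", {
  set.seed(1)
  X <- matrix(rnorm(16 * 10, 0, 0.01), 16)
  y <- rep(c(1, -1), 8)
  X[y == 1, ] <- X[y == 1, ] + 1
  run <- rep(1:8, each = 2)
  expect_equal(decode_cv(X, y, run), 1)
  expect_error(decode_cv(X, y, rep(1, 16)), "2 runs")
  expect_error(decode_cv(X, rep(c(1, -1), each = 8), rep(c(1, 2), each = 8)),
               "missing one label")
})

test_that("label-permuted decoding sits at chance", {
  set.seed(21)
  accs <- replicate(20, {
    X <- matrix(rnorm(16 * 25), 16)
    decode_cv(X, sample(rep(c(1, -1), 8)), rep(1:8, 2))
  })
  se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), max(3 * se, 0.06))
})

test_that("cross-classification respects symmetry and the optimism inequality", {
  set.seed(31)
  resub_ge_cv <- vapply(1:20, function(i) {
    X <- matrix(rnorm(16 * 12), 16)
    y <- rep(c(1, -1), 8)
    X[y == 1, 1:3] <- X[y == 1, 1:3] + 0.8
    run <- rep(1:8, each = 2)
    decode_cross(X, y, X, y) - decode_cv(X, y, run)
  }, 0)
  expect_gte(mean(resub_ge_cv), 0)
  X <- matrix(rnorm(16 * 12), 16)
  y <- rep(c(1, -1), 8)
  Xt <- matrix(rnorm(16 * 12), 16)
  a <- decode_cross(X, y, Xt, y)
  a_flip <- decode_cross(X, y, Xt, -y)
  expect_equal(a + a_flip, 1)
  expect_error(decode_cross(X, y, Xt[, 1:5], y), "voxel sets")
})

test_that("decoding is invariant to voxel-wise affine rescaling of the patterns", {
  set.seed(41)
  X <- matrix(rnorm(16 * 15), 16)
  y <- rep(c(1, -1), 8)
  X[y == 1, 1:4] <- X[y == 1, 1:4] + 0.7
  run <- rep(1:8, each = 2)
  sc <- runif(15, 0.05, 20)
  off <- rnorm(15, 0, 3)
  X2 <- sweep(sweep(X, 2, sc, "*"), 2, off, "+")
  expect_identical(decode_cv(X, y, run), decode_cv(X2, y, run))
  Xt <- matrix(rnorm(16 * 15), 16)
  Xt2 <- sweep(sweep(Xt, 2, sc, "*"), 2, off, "+")
  expect_identical(decode_cross(X, y, Xt, y), decode_cross(X2, y, Xt2, y))
})

test_that("cross-decoding separates pattern-sharing from pattern-free AEs", {
  co <- small_cohort_hisnr()
  gt <- small_gt()
  ac <- which(gt$voxel_class == "acoustic")
  shared <- c(e_s = 0, scr = 0); free <- c(p_a = 0, rip = 0, tsp = 0)
  for (s in 1:4) {
    tr <- vaparc:::variant_patterns(co, s, "orig")
    for (v in names(shared)) {
      te <- vaparc:::variant_patterns(co, s, v)
      shared[v] <- shared[v] + decode_cross(tr$X[, ac], tr$y, te$X[, ac], te$y)
    }
    for (v in names(free)) {
      te <- vaparc:::variant_patterns(co, s, v)
      free[v] <- free[v] + decode_cross(tr$X[, ac], tr$y, te$X[, ac], te$y)
    }
  }
  expect_true(all(shared / 4 > 0.8))
  expect_true(all(abs(free / 4 - 0.5) < 0.2))
})

test_that("group accuracy maps behave at chance and match the closed-form t", {
  grid <- va_grid(c(4, 4, 3))
  flat <- lapply(1:5, function(s) array(0.5, grid$dims))
  g <- group_accuracy_map(flat, grid,
                          threshold = va_threshold("uncorrected", 0.001))
  expect_equal(sum(g$mask), 0)
  ## accuracies (.6,.6,.6,.6) against 0.5: mean .1, sd 0 -> t = Inf; perturb
  ## one entry for the finite hand-computed case
  maps <- lapply(c(0.6, 0.6, 0.6, 0.58), function(a) array(a, grid$dims))
  g2 <- group_accuracy_map(maps, grid)
  accs <- c(0.6, 0.6, 0.6, 0.58)
  t_hand <- (mean(accs) - 0.5) / (stats::sd(accs) / 2)
  expect_equal(g2$t[1, 1, 1], t_hand, tolerance = 1e-12)
  expect_error(group_accuracy_map(flat[1:2], grid), "3 subjects")
})

test_that("searchlight decoding of originals recovers the acoustic region", {
  co <- small_cohort_hisnr()
  gt <- small_gt()
  maps <- fixture("cv_maps_hisnr", function()
    lapply(seq_len(co$n_subjects), function(s)
      searchlight_map(co, s, "cv", "orig", neigh = small_neigh())))
  g <- group_accuracy_map(maps, co$grid, threshold = va_threshold("fwe"))
  ac <- gt$voxel_class == "acoustic"
  expect_gte(sum(g$mask[array(ac, gt$grid$dims)]) / sum(ac), 0.9)
})

test_that("averaging cross maps is idempotent and linear", {
  co <- small_cohort_hisnr()
  m <- group_contrast(co, c(orig_voice = 1, orig_nonvoice = -1),
                      va_threshold("fwe"), 0)
  same <- setNames(rep(list(m), 5), ae_variants())
  avg <- average_cross_maps(same)
  expect_equal(avg$t, pmin(pmax(m$t, -100), 100))
  null_map <- m
  null_map$t <- array(0, dim(m$t))
  mix <- c(list(m), rep(list(null_map), 4))
  names(mix) <- ae_variants()
  avg2 <- average_cross_maps(mix)
  expect_equal(avg2$t, pmin(pmax(m$t, -100), 100) / 5)
  expect_error(average_cross_maps(same[1:3]), "5")
})

test_that("functional patches follow the peak/fallback rules", {
  grid <- va_grid(c(12, 12, 6))
  refs <- rbind(a = c(3, 3, 3), m = c(3, 9, 3), p = c(10, 6, 3))
  stat <- array(0, grid$dims)
  for (k in 1:3) stat[refs[k, 1], refs[k, 2], refs[k, 3]] <- 10 + k
  mask <- array(TRUE, grid$dims)
  ps <- define_functional_patches(stat, mask, refs, grid)
  expect_equal(unname(ps$centers), unname(refs))
  expect_equal(nrow(ps$log), 0)
  ## spheres contain exactly the voxels within the radius
  co <- vaparc:::grid_coords(grid)
  for (k in 1:3) {
    d <- sqrt(colSums((t(co) - refs[k, ])^2)) * grid$voxel_size_mm
    expect_identical(sort(ps$rois[[k]]), which(d <= 5 + 1e-9))
  }
  ## flat statistic: full fallback, logged
  flat <- define_functional_patches(array(1, grid$dims), mask, refs, grid)
  expect_equal(unname(flat$centers), unname(refs))
  expect_equal(nrow(flat$log), 3)
  ## two peaks 8.25 mm apart (3 voxels at 2.75 mm): both revert to references
  stat2 <- array(0, grid$dims)
  stat2[4, 4, 3] <- 20
  stat2[7, 4, 3] <- 19
  refs2 <- rbind(a = c(1, 1, 1), m = c(12, 12, 6))
  ps2 <- define_functional_patches(stat2, mask, refs2, grid)
  expect_equal(unname(ps2$centers), unname(refs2))
  expect_gte(nrow(ps2$log), 2)
  expect_error(define_functional_patches(stat, array(FALSE, grid$dims),
                                         refs, grid), "empty")
})

test_that("ROI tables find signal regions, control the null, and apply FDR", {
  co <- small_cohort_hisnr()
  gt <- small_gt()
  rois <- list(acoustic = which(gt$voxel_class == "acoustic"),
               nulls = which(gt$voxel_class == "null")[1:30],
               empty = integer(0))
  tab <- roi_analysis(co, rois, schemes = c("cv_orig", "cross_e_s"))
  expect_true(all(tab$significant[tab$roi == "acoustic"]))
  expect_identical(tab$flag[tab$roi == "empty"], rep("empty ROI", 2))
  ## FDR column equals the hand-applied step-up procedure on the table
  ok <- !is.na(tab$p)
  expect_equal(tab$p_fdr[ok], stats::p.adjust(tab$p[ok], "BH"))
})

test_that("null ROIs stay at their nominal false-positive rate", {
  set.seed(77)
  gt0 <- gen_ground_truth(c(6, 6, 4), c(core = 0, acoustic = 0,
                                        accessory = 0), seed = 1)
  hits <- vapply(1:60, function(i) {
    co <- gen_subject_betas(gt0, 1, 0.5, 4, 8, seed = 1000 + i)
    accs <- vapply(1:8, function(s) {
      p <- vaparc:::variant_patterns(co, s, "orig")
      decode_cv(p$X[, 1:20], p$y, p$run)
    }, 0)
    tt <- vaparc:::one_sample_t(matrix(accs, ncol = 1), mu = 0.5)
    tt$p < 0.05
  }, TRUE)
  expect_lte(mean(hits), 0.1)
})

test_that("the searchlight's linear SVM agrees with an independent implementation", {
  ## e1071 (libsvm) with a linear kernel and C = 1 as the external oracle
  set.seed(51)
  agree <- vapply(1:8, function(i) {
    X <- matrix(rnorm(16 * 8), 16)
    y <- rep(c(1, -1), 8)
    X[y == 1, 1:2] <- X[y == 1, 1:2] + 1.5
    Xte <- matrix(rnorm(30 * 8), 30)
    Xte[rep(c(TRUE, FALSE), 15), 1:2] <- Xte[rep(c(TRUE, FALSE), 15), 1:2] + 1.5
    yte <- rep(c(1, -1), 15)
    mine <- vaparc:::cpp_linsvm_predict(scale(X), as.integer(y),
                                        scale(Xte, center = colMeans(X),
                                              scale = apply(X, 2, sd)))
    fit <- e1071::svm(scale(X), factor(y), kernel = "linear", cost = 1,
                      scale = FALSE)
    ref <- as.numeric(as.character(predict(fit, scale(Xte,
                                                      center = colMeans(X),
                                                      scale = apply(X, 2, sd)))))
    mean(mine == ref)
  }, 0)
  expect_gte(mean(agree), 0.95)
  ## on cleanly separable data both classifiers are perfect
  X <- matrix(rnorm(16 * 5, 0, 0.05), 16)
  y <- rep(c(1, -1), 8)
  X[y == 1, ] <- X[y == 1, ] + 2
  mine <- vaparc:::cpp_linsvm_predict(X, as.integer(y), X)
  fit <- e1071::svm(X, factor(y), kernel = "linear", cost = 1, scale = FALSE)
  expect_equal(mine, as.numeric(as.character(predict(fit, X))))
  expect_equal(mean(mine == y), 1)
})
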