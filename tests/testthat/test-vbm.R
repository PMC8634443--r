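# Voxelwise group statistics, FDR and cluster filtering.

make_maps <- function(Y, dm) {
  # Y: subjects x voxels (filled into the first voxels of the grid)
  lapply(seq_len(nrow(Y)), function(i) {
    a <- array(1, dm)   # background above mask threshold
    a[seq_len(ncol(Y))] <- Y[i, ]
    toy_map(a, subject_id = sprintf("s%02d", i))
  })
}

test_that("identical group values give F = 0, p = 1", {
  dm <- c(4, 4, 4)
  maps <- make_maps(matrix(0.5, nrow = 9, ncol = 8), dm)
  des <- group_design(sprintf("s%02d", 1:9), rep(c("HC", "NSZ", "VSZ"), each = 3))
  sm <- voxelwise_anova(maps, des)
  expect_true(all(sm$stat[sm$mask] == 0))
  expect_true(all(sm$p[sm$mask] == 1))
  expect_equal(sm$df, c(2, 6))
})

test_that("two-group F equals the squared pooled t at every voxel", {
  dm <- c(4, 4, 2)
  Y <- with_test_seed(20, matrix(runif(12 * 20, 0.3, 0.8), nrow = 12))
  maps <- make_maps(Y, dm)
  des <- group_design(sprintf("s%02d", 1:12), rep(c("A", "B"), each = 6))
  sm <- voxelwise_anova(maps, des)
  for (v in 1:20) {
    tt <- pooled_t_from_summary(mean(Y[1:6, v]), sd(Y[1:6, v]), 6,
                                mean(Y[7:12, v]), sd(Y[7:12, v]), 6)
    expect_equal(sm$stat[v], tt$statistic^2, tolerance = 1e-10)
  }
})

test_that("voxelwise ANOVA is calibrated under the null", {
  dm <- c(10, 10, 5)
  Y <- with_test_seed(21, matrix(rnorm(30 * 500, 0.5, 0.1), nrow = 30))
  maps <- make_maps(Y, dm)
  des <- group_design(sprintf("s%02d", 1:30), rep(c("HC", "NSZ", "VSZ"), each = 10))
  sm <- voxelwise_anova(maps, des)
  frac <- mean(sm$p[1:500] < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("missing covariates follow the drop/impute/error policy", {
  dm <- c(3, 3, 3)
  Y <- with_test_seed(22, matrix(runif(9 * 5, 0.3, 0.8), nrow = 9))
  maps <- make_maps(Y, dm)
  des <- group_design(sprintf("s%02d", 1:9), rep(c("HC", "NSZ", "VSZ"), each = 3),
                      PANSS = c(NA, NA, NA, 90, 95, 100, 110, 105, 120))
  expect_error(voxelwise_anova(maps, des, covariates = "PANSS",
                               na_action = "error"), "s01")
  expect_message(sm <- voxelwise_anova(maps, des, covariates = "PANSS",
                                       na_action = "drop"), "dropped")
  expect_equal(sm$df, c(2, 6))          # covariate removed
  sm2 <- voxelwise_anova(maps, des, covariates = "PANSS",
                         na_action = "impute")
  expect_equal(sm2$df, c(2, 5))         # covariate retained
})

test_that("BH survival follows the hand-applied step-up rule", {
  sm <- toy_stat_map(c(0.001, 0.002, 0.9, 0.95))
  surv <- fdr_threshold(sm, 0.05)
  expect_equal(which(surv), c(1L, 2L))
  expect_equal(which(fdr_threshold(toy_stat_map(rep(1, 4)), 0.05)), integer(0))
  expect_equal(which(fdr_threshold(toy_stat_map(rep(0, 4)), 0.05)), 1:4)
})

test_that("BH survival masks nest across q levels", {
  p <- with_test_seed(23, runif(50)^2)
  sm <- toy_stat_map(p, dm = c(50, 1, 1))
  s1 <- fdr_threshold(sm, 0.02)
  s2 <- fdr_threshold(sm, 0.10)
  expect_true(all(s2[s1]))
})

test_that("cluster filtering is strict, idempotent and relabel-invariant", {
  dm <- c(12, 12, 12)
  bm <- array(FALSE, dm)
  bm[1:31] <- TRUE                    # 31-voxel column-major blob
  bm[5:12, 12, 12] <- TRUE            # far-away 8-voxel blob
  cl <- cluster_filter(bm, 30)
  expect_equal(nrow(cl$table), 1)
  expect_equal(cl$table$size, 31)
  # strictly-greater rule: a 30-voxel blob is dropped
  bm2 <- array(FALSE, dm); bm2[1:30] <- TRUE
  expect_equal(nrow(cluster_filter(bm2, 30)$table), 0)
  # single voxel
  bm3 <- array(FALSE, dm); bm3[1] <- TRUE
  expect_equal(nrow(cluster_filter(bm3, 30)$table), 0)
  # idempotence: refiltering the surviving voxels changes nothing
  surv <- array(FALSE, dm); surv[cl$voxels[[1]]] <- TRUE
  cl2 <- cluster_filter(surv, 30)
  expect_identical(cl2$voxels, cl$voxels)
})

test_that("a planted blob survives among scattered voxels with its peak inside", {
  dm <- c(16, 16, 16)
  stat <- array(0, dm)
  bm <- array(FALSE, dm)
  blob <- as.matrix(expand.grid(5:8, 5:8, 5:7))     # 48-voxel block
  bm[blob] <- TRUE
  stat[blob] <- with_test_seed(24, runif(nrow(blob), 5, 10))
  scatter <- with_test_seed(25, sample(which(!bm), 25))
  # keep only isolated scatter voxels
  for (v in scatter) {
    ar <- arrayInd(v, dm)
    if (all(ar > 9 | ar < 4)) { bm[v] <- TRUE; stat[v] <- 20 }
  }
  sm <- structure(list(stat = stat, p = array(0.5, dm), df = c(2, 10),
                       mask = array(TRUE, dm), affine = diag(4),
                       distribution = "F"), class = "stat_map")
  cl <- cluster_filter(bm, 30, statmap = sm)
  expect_equal(nrow(cl$table), 1)
  peak <- cl$table[1, c("peak_x_mm", "peak_y_mm", "peak_z_mm")]
  expect_true(peak$peak_x_mm >= 4 && peak$peak_x_mm <= 7)  # 0-based mm = idx-1
  expect_true(all(bm[cl$voxels[[1]]]))
  expect_equal(cl$table$peak_stat, max(stat[cl$voxels[[1]]]))
})

test_that("post-hoc cluster tests are pairwise Bonferroni pooled t", {
  des <- group_design(sprintf("s%02d", 1:12), rep(c("HC", "NSZ", "VSZ"), each = 4))
  same <- rep(0.5, 12)
  ph <- posthoc_cluster_tests(same, des)
  expect_equal(nrow(ph), 3)
  expect_true(all(ph$statistic == 0))
  expect_true(all(ph$p_adj == 1))
  vals <- with_test_seed(26, rnorm(12, rep(c(0.6, 0.5, 0.4), each = 4), 0.01))
  ph2 <- posthoc_cluster_tests(vals, des)
  expect_equal(ph2$p_adj, pmin(1, ph2$p_raw * 3))
})
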