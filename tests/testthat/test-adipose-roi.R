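test_that("depot thresholding keeps fat-dominant voxels and applies the 30-voxel rule", {
  m <- matrix(TRUE, 2, 3)
  p <- matrix(c(0.2, 0.4, 0.5, 0.6, 0.9, NaN), 2, 3)
  th <- threshold_depot(m, p)
  expect_equal(th$n_kept, 3)          # 0.50 is kept: only "< 50%" excluded
  expect_equal(sort(p[th$kept]), c(0.5, 0.6, 0.9))
  expect_true(th$excluded)

  allwater <- threshold_depot(matrix(TRUE, 5, 5), matrix(0, 5, 5))
  expect_equal(allwater$n_kept, 0)
  expect_true(allwater$excluded)

  ok <- threshold_depot(matrix(TRUE, 5, 6), matrix(1, 5, 6))
  expect_equal(ok$n_kept, 30)
  expect_false(ok$excluded)           # exactly 30 voxels survive

  expect_error(threshold_depot(matrix(TRUE, 2, 2), matrix(1, 3, 3)),
               "mismatch")
})

test_that("raising the PDFF threshold never increases the kept count", {
  set.seed(3)
  m <- matrix(TRUE, 20, 20)
  p <- matrix(runif(400), 20, 20)
  kept <- vapply(seq(0, 1, by = 0.05), function(thr) {
    threshold_depot(m, p, threshold = thr)$n_kept
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("depot summaries are plain means over kept voxels", {
  maps <- list(pdff = matrix(c(0.6, 0.8), 1), t1 = matrix(c(0.7, 0.9), 1),
               sfa = matrix(c(0.4, 0.6), 1), mufa = matrix(c(0.4, 0.3), 1),
               pufa = matrix(c(0.2, 0.1), 1))
  th <- threshold_depot(matrix(TRUE, 1, 2), maps$pdff, min_voxels = 0)
  s <- depot_summary("EAT", th, maps)
  expect_equal(s$mean_sfa, 0.5)
  expect_equal(s$mean_t1, 0.8)

  # brute-force oracle on random inputs
  set.seed(9)
  p <- matrix(runif(100), 10, 10)
  maps <- list(pdff = p, t1 = matrix(runif(100), 10, 10),
               sfa = matrix(runif(100), 10, 10),
               mufa = matrix(runif(100), 10, 10),
               pufa = matrix(runif(100), 10, 10))
  mask <- matrix(runif(100) > 0.4, 10, 10)
  th <- threshold_depot(mask, p, threshold = 0.3, min_voxels = 0)
  s <- depot_summary("SAT", th, maps)
  brute <- 0; n <- 0
  for (i in 1:10) for (j in 1:10) {
    if (mask[i, j] && p[i, j] >= 0.3) { brute <- brute + maps$t1[i, j]; n <- n + 1 }
  }
  expect_equal(s$mean_t1, brute / n, tolerance = 1e-12)
  expect_equal(s$n_voxels_kept, n)

  # empty kept set -> excluded with missing means
  th0 <- threshold_depot(mask, p * 0, threshold = 0.5)
  s0 <- depot_summary("EAT", th0, maps)
  expect_true(s0$excluded)
  expect_true(is.na(s0$mean_pdff))
})

test_that("SFA index is the EAT/SAT ratio with missing-value guards", {
  expect_equal(sfa_index(0.5, 0.5), 1.0)
  expect_equal(sfa_index(0.48, 0.40), 1.2)
  expect_true(is.na(sfa_index(0.48, 0.40, sat_excluded = TRUE)))
  expect_true(is.na(sfa_index(0.48, 0)))
})

test_that("EAT volume scales linearly in pixel count and slice thickness", {
  v1 <- eat_volume_index(matrix(1, 10, 10), 0.2, 1.0, 40)
  v2 <- eat_volume_index(list(matrix(1, 10, 10), matrix(1, 10, 10)),
                         0.2, 1.0, 40)
  expect_equal(v2$volume_ul, 2 * v1$volume_ul)
  v3 <- eat_volume_index(matrix(1, 10, 10), 0.2, 2.0, 40)
  expect_equal(v3$volume_ul, 2 * v1$volume_ul)
  # direct arithmetic: 1000 pixels at 0.038 mm^3, 40 g mouse
  v4 <- eat_volume_index(matrix(1, 25, 40), sqrt(0.038), 1.0, 40)
  expect_equal(v4$volume_ul, 38, tolerance = 1e-12)
  expect_equal(v4$volume_index_ul_per_g, 0.95, tolerance = 1e-12)
  v0 <- eat_volume_index(matrix(0, 5, 5), 0.2, 1.0, 40)
  expect_equal(v0$volume_ul, 0)
  expect_equal(v0$volume_index_ul_per_g, 0)
})

test_that("summarise_depots applies adipose rules but not to myocardium", {
  fitlike <- list(pdff = matrix(0.4, 8, 8), t1 = matrix(1, 8, 8),
                  sfa = matrix(0.5, 8, 8), mufa = matrix(0.3, 8, 8),
                  pufa = matrix(0.2, 8, 8))
  labels <- matrix(0L, 8, 8)
  labels[1:4, ] <- 1L        # EAT, pdff 0.4 < 0.5 -> all excluded
  labels[5:8, ] <- 3L        # myocardium: no threshold
  out <- summarise_depots(labels, fitlike,
                          label_map = c(EAT = 1L, myocardium = 3L),
                          adipose = "EAT")
  eat <- out[out$depot == "EAT", ]
  myo <- out[out$depot == "myocardium", ]
  expect_equal(eat$n_voxels_kept, 0)
  expect_true(eat$excluded)
  expect_equal(myo$n_voxels_kept, 32)
  expect_equal(myo$mean_pdff, 0.4)
  expect_false(myo$excluded)
})
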