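test_that("ideal inversion recovery nulls at TI = t1*ln(2)", {
  t1 <- 0.9
  sched <- acquisition_schedule(ti_list = c(0.05, t1 * log(2), 3),
                                n_te = 5)
  s <- model_signal(sched, W = 1, F = 0, t1 = t1, r2star = 0, psi = 0,
                    beta = 1, phi0 = 0)
  expect_lt(Mod(s[2, 1]), 1e-12)
  # recovery factor is real-scaled 1 - 2exp(-TI/t1) at fixed TE
  expect_equal(Re(s[, 1]), 1 - 2 * exp(-sched$ti_list / t1),
               tolerance = 1e-12)
  # at long TI the factor approaches full recovery
  expect_equal(Re(s[3, 1]), 1 - 2 * exp(-3 / t1), tolerance = 1e-12)
})

test_that("a water-free voxel's echo envelope is the fat factor times R2* decay", {
  sched <- test_schedule()
  p <- tg_params(ndb = 2, nmidb = 0.5)
  r2 <- 40
  s <- model_signal(sched, W = 0, F = 2, t1 = 0.8, r2star = r2, psi = 70,
                    beta = 0.9, phi0 = 1, params = p)
  env <- Mod(s[5, ]) / Mod(1 - 2 * 0.9 * exp(-sched$ti_list[5] / 0.8))
  expect_equal(env,
               2 * Mod(fat_signal(sched$te_list, p)) *
                 exp(-r2 * sched$te_list),
               tolerance = 1e-10)
})

test_that("pdff is the fat share of total signal", {
  expect_equal(pdff(1, 0), 0)
  expect_equal(pdff(0, 2), 1)
  expect_equal(pdff(1, 3), 0.75)
  expect_true(is.nan(pdff(0, 0)))
  expect_error(pdff(-1, 1), "non-negative")
})

test_that("noiseless forward-then-fit roundtrip recovers all parameters", {
  sched <- test_schedule()
  truth <- list(W = 0.25, F = 0.75, t1 = 0.85, r2star = 35, psi = -120,
                beta = 0.92, phi0 = 0.4, ndb = 2.7, nmidb = 0.8)
  s <- model_signal(sched, truth$W, truth$F, truth$t1, truth$r2star,
                    truth$psi, truth$beta, truth$phi0,
                    params = tg_params(ndb = truth$ndb,
                                       nmidb = truth$nmidb))
  fit <- fit_voxel(s, sched)
  expect_true(fit$ok)
  for (nm in c("W", "F", "t1", "r2star", "psi", "beta", "ndb", "nmidb")) {
    expect_equal(fit[[nm]], truth[[nm]], tolerance = 1e-4,
                 label = paste("fitted", nm))
  }
  expect_equal(fit$phi0, truth$phi0, tolerance = 1e-4)
  expect_equal(fit$pdff, 0.75, tolerance = 1e-4)
})

test_that("a pure-water voxel fits to negligible fat fraction", {
  sched <- test_schedule()
  s <- model_signal(sched, W = 1, F = 0, t1 = 1.2, r2star = 30, psi = -40,
                    beta = 0.95, phi0 = 0.3)
  fit <- fit_voxel(s, sched)
  expect_lt(fit$pdff, 0.01)
})

test_that("local refinement never increases the grid-search residual", {
  sched <- test_schedule()
  pre <- cmrquant:::fw_precompute(sched, default_fat_spectrum())
  set.seed(11)
  for (i in 1:20) {
    tg <- random_tg(1, seed = 100 + i)
    W <- runif(1); Fa <- runif(1)
    s <- model_signal(sched, W, Fa, t1 = runif(1, 0.5, 1.5),
                      r2star = runif(1, 0, 80), psi = runif(1, -300, 300),
                      beta = runif(1, 0.8, 1), phi0 = runif(1, -1, 1),
                      params = tg_params(ndb = tg$ndb, nmidb = tg$nmidb))
    s <- s + matrix(complex(real = rnorm(length(s), sd = 0.01),
                            imaginary = rnorm(length(s), sd = 0.01)),
                    nrow(s))
    S2 <- sum(Mod(s)^2)
    theta0 <- c(1, 20, 0, 0.95, 2.5, 0.7)
    grid_rss <- min(vapply(seq(-2500, 2500, length.out = 64), function(p) {
      th <- theta0; th[3] <- p
      cmrquant:::fw_varpro(th, s, pre, 17.3, S2)
    }, numeric(1)))
    fit <- fit_voxel(s, sched)
    expect_lte(fit$resnorm, grid_rss + 1e-12)
  }
})

test_that("field-offset estimates track true offsets across the search range", {
  sched <- test_schedule()
  for (psi_true in c(-900, -200, 0, 350, 1200)) {
    s <- model_signal(sched, W = 0.4, F = 0.6, t1 = 0.8, r2star = 30,
                      psi = psi_true, beta = 0.95, phi0 = 0.2,
                      params = tg_params(ndb = 2.4, nmidb = 0.6))
    fit <- fit_voxel(s, sched)
    expect_equal(fit$psi, psi_true, tolerance = 1e-2,
                 label = sprintf("psi at true %g", psi_true))
    expect_equal(fit$pdff, 0.6, tolerance = 1e-3)
  }
})

test_that("fit_stack maps agree with voxel-wise fits and are order-independent", {
  sched <- test_schedule()
  ph <- make_fatwater_phantom(size = 4, truth = small_truth(),
                              schedule = sched)
  fit1 <- fit_stack(ph, ph$mask)
  fit2 <- fit_stack(ph, ph$mask)   # identical inputs -> bit-identical maps
  expect_identical(fit1$pdff, fit2$pdff)
  expect_identical(fit1$t1, fit2$t1)
  v <- fit_voxel(ph$data[, , 3, 3], sched)
  expect_identical(fit1$pdff[3, 3], v$pdff)
  expect_error(fit_stack(ph, matrix(FALSE, 4, 4)), "empty")
  expect_error(fit_stack(ph, matrix(TRUE, 3, 3)), "geometry")
})

test_that("tidy and glance expose the fitted stack as tables", {
  sched <- test_schedule()
  ph <- make_fatwater_phantom(size = 4, truth = small_truth(),
                              schedule = sched)
  fit <- fit_stack(ph, ph$mask)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 16)
  expect_true(all(c("row", "col", "pdff", "t1", "sfa", "ok") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_voxels, 16)
  expect_equal(gl$mean_pdff, mean(td$pdff), tolerance = 1e-12)
})
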