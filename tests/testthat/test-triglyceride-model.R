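test_that("peak amplitudes vanish for absent double bonds and stay normalised", {
  a0 <- peak_amplitudes(tg_params(ndb = 0, nmidb = 0))
  expect_identical(unname(a0[c("olefinic", "diallylic", "allylic")]),
                   c(0, 0, 0))
  expect_equal(sum(a0), 1, tolerance = 1e-12)

  a1 <- peak_amplitudes(tg_params(ndb = 3, nmidb = 0.7))
  expect_true(all(a1 >= 0))
  expect_equal(sum(a1), 1, tolerance = 1e-12)
})

test_that("trilinolein amplitudes equal its proton counts, normalised", {
  # direct evaluation of the affine amplitude expressions at
  # (cl = 18, ndb = 6, nmidb = 3): proton counts of trilinolein, total 98
  protons <- c(olefinic = 12, glycerol_ch = 1, glycerol_ch2 = 4,
               diallylic = 6, alpha_carboxyl = 6, allylic = 12,
               beta_carboxyl = 6, methylene = 42, methyl = 9)
  a <- peak_amplitudes(tg_params(cl = 18, ndb = 6, nmidb = 3))
  expect_equal(a, protons / 98, tolerance = 1e-12)
})

test_that("amplitude normalisation holds across a randomised domain sweep", {
  tg <- random_tg(200)
  for (i in seq_len(nrow(tg))) {
    a <- peak_amplitudes(tg_params(ndb = tg$ndb[i], nmidb = tg$nmidb[i]))
    expect_true(all(a >= 0))
    expect_equal(sum(a), 1, tolerance = 1e-12)
  }
})

test_that("out-of-domain parameters raise a domain error naming the invariant", {
  expect_error(tg_params(ndb = -1), "ndb < 0")
  expect_error(tg_params(ndb = 1, nmidb = 1), "MUFA")
  expect_error(tg_params(ndb = 5, nmidb = 1), "SFA")
  expect_error(tg_params(cl = 3, ndb = 0, nmidb = 0), "cl")
})

test_that("fatty acid composition map matches the linear relationships", {
  expect_equal(as.numeric(fac_from_bonds(0, 0)), c(1, 0, 0))
  expect_equal(as.numeric(fac_from_bonds(3, 0)), c(0, 1, 0))
  expect_equal(as.numeric(fac_from_bonds(6, 3)), c(0, 0, 1))
  f <- fac_from_bonds(2.1, 0.6)
  expect_equal(c(f$sfa, f$mufa, f$pufa), c(0.5, 0.3, 0.2), tolerance = 1e-12)
  expect_error(fac_from_bonds(1, 2), "domain")
})

test_that("bonds_from_fac is the exact algebraic inverse of fac_from_bonds", {
  b <- bonds_from_fac(0.5, 0.3, 0.2)
  expect_equal(c(b$ndb, b$nmidb), c(2.1, 0.6), tolerance = 1e-12)
  tg <- random_tg(100)
  b <- bonds_from_fac(tg$sfa, tg$mufa, tg$pufa)
  f <- fac_from_bonds(b$ndb, b$nmidb)
  expect_equal(f$sfa, tg$sfa, tolerance = 1e-12)
  expect_equal(f$mufa, tg$mufa, tolerance = 1e-12)
  expect_equal(f$pufa, tg$pufa, tolerance = 1e-12)
  expect_equal(c(as.numeric(bonds_from_fac(1, 0, 0))), c(0, 0))
})

test_that("fat dephasing factor is unity at te = 0 and bounded by 1", {
  tg <- random_tg(20, seed = 7)
  for (i in seq_len(nrow(tg))) {
    p <- tg_params(ndb = tg$ndb[i], nmidb = tg$nmidb[i])
    expect_equal(fat_signal(0, p), 1 + 0i, tolerance = 1e-14)
    te <- seq(0, 10e-3, length.out = 40)
    expect_true(all(Mod(fat_signal(te, p)) <= 1 + 1e-12))
  }
})

test_that("a single-peak spectrum dephases to -1 at half its beat period", {
  sp <- default_fat_spectrum()
  sp$const <- c(0, 0, 0, 0, 0, 0, 0, 1, 0)   # all weight on the methylene peak
  sp$c_cl <- sp$c_ndb <- sp$c_nmidb <- rep(0, 9)
  f0 <- 400.2e6
  df <- abs((1.30 - 4.70) * 1e-6 * f0)
  val <- fat_signal(1 / (2 * df), tg_params(), f0 = f0, spectrum = sp)
  expect_equal(val, -1 + 0i, tolerance = 1e-9)
})

test_that("spectrum JSON roundtrips and rejects incomplete tables", {
  path <- withr::local_tempfile(fileext = ".json")
  write_spectrum_json(default_fat_spectrum(), path)
  back <- read_spectrum_json(path)
  expect_equal(as.data.frame(back), as.data.frame(default_fat_spectrum()))
  jsonlite::write_json(list(peak = "a", shift_ppm = 1), path)
  expect_error(read_spectrum_json(path), "missing fields")
})
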