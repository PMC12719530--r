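test_that("phase converts to displacement by the encoding relation", {
  expect_equal(displacement_from_phase(0, 1), 0)
  expect_equal(displacement_from_phase(pi, 1), 0.5)
  expect_equal(displacement_from_phase(matrix(pi, 2, 2), 2),
               matrix(0.25, 2, 2))
  expect_error(displacement_from_phase(1, -1))
})

test_that("a wrapped smooth ramp is recovered by unwrapping", {
  nr <- 16; nc <- 32
  true_phase <- matrix(rep(seq(0, 6 * pi, length.out = nc), each = nr),
                       nr, nc)
  wrapped <- ((true_phase + pi) %% (2 * pi)) - pi
  un <- unwrap_phase(wrapped)
  # unwrap is defined up to a global 2*pi multiple
  off <- un[1, 1] - true_phase[1, 1]
  expect_equal(un - off, true_phase, tolerance = 1e-10)
  # and the ramp displacement is recovered
  u <- displacement_from_phase(un - off, 1)
  expect_equal(u, true_phase / (2 * pi), tolerance = 1e-10)
})

test_that("disconnected masks unwrap per component with a warning", {
  ph <- matrix(0.1, 6, 6)
  mask <- matrix(FALSE, 6, 6)
  mask[1:2, 1:2] <- TRUE
  mask[5:6, 5:6] <- TRUE
  expect_warning(un <- unwrap_phase(ph, mask), "disconnected")
  expect_true(all(is.na(un[3:4, ])))
  expect_equal(un[1, 1], 0.1)
})

test_that("Lagrangian strain reproduces closed-form uniaxial stretch", {
  n <- 20
  X <- matrix(seq_len(n), n, n)
  u0 <- matrix(0, n, n)
  st0 <- strain_from_displacement(u0, u0)
  expect_equal(max(abs(st0$exx)), 0)
  # x -> 1.1 x: E_xx = (1.1^2 - 1)/2 = 0.105 exactly
  ux <- 0.1 * X
  st <- strain_from_displacement(ux, u0)
  expect_equal(st$exx, matrix(0.105, n, n), tolerance = 1e-12)
  expect_equal(max(abs(st$eyy)), 0, tolerance = 1e-12)
})

test_that("strain vanishes under rigid translation and rotation", {
  n <- 24
  ctr <- (n + 1) / 2
  X <- matrix(seq_len(n) - ctr, n, n)
  Y <- t(X)
  # translation
  st <- strain_from_displacement(matrix(2.5, n, n), matrix(-1, n, n))
  expect_equal(max(abs(st$exx)), 0)
  expect_equal(max(abs(st$exy)), 0)
  # 10 degree rotation about the centre
  a <- 10 * pi / 180
  ux <- cos(a) * X - sin(a) * Y - X
  uy <- sin(a) * X + cos(a) * Y - Y
  st <- strain_from_displacement(ux, uy)
  expect_lt(max(abs(st$exx), abs(st$eyy), abs(st$exy)), 1e-6)
})

test_that("GLS/PDSR summary matches the closed-form prescribed curve", {
  T <- 0.12; dt <- 0.004
  tt <- seq(0, T, by = dt)
  crv <- gls_and_pdsr(-0.15 * sin(pi * tt / T)^2, frame_interval = dt)
  g <- glance(crv)
  expect_equal(g$es_strain, -0.15, tolerance = 1e-6)
  # max recovery rate after end-systole: 0.15*pi/T, discretisation-corrected
  sinc <- sin(2 * pi * dt / T) / (2 * pi * dt / T)
  expect_equal(g$pdsr, 0.15 * pi / T * sinc, tolerance = 0.01)
  expect_equal(g$pdsr, 0.15 * pi / T, tolerance = 0.05 * 0.15 * pi / T)
})

test_that("degenerate and symmetric curves are handled", {
  flat <- gls_and_pdsr(rep(0, 10), frame_interval = 0.01)
  g <- glance(flat)
  expect_equal(g$es_strain, 0)
  expect_true(is.na(g$pdsr))
  # monotone decline with no recovery phase
  mono <- glance(gls_and_pdsr(seq(0, -0.2, length.out = 10), 0.01))
  expect_true(is.na(mono$pdsr))
  # time reversal swaps systolic and diastolic rates
  T <- 0.12; dt <- 0.005
  tt <- seq(0, T, by = dt)
  ell <- -0.15 * sin(pi * tt / T)^2 * seq(1, 1.2, length.out = length(tt))
  fwd <- glance(gls_and_pdsr(ell, dt))
  rev <- glance(gls_and_pdsr(rev(ell), dt))
  d_f <- cmrquant:::strain_rate(ell, dt)
  d_r <- cmrquant:::strain_rate(rev(ell), dt)
  expect_equal(sort(abs(d_f)), sort(abs(d_r)), tolerance = 1e-12)
  expect_equal(fwd$es_strain, rev$es_strain)
})

test_that("PDSR is invariant to uniform strain-curve offsets", {
  T <- 0.12; dt <- 0.005
  tt <- seq(0, T, by = dt)
  ell <- -0.12 * sin(pi * tt / T)^2
  g1 <- glance(gls_and_pdsr(ell, dt))
  g2 <- glance(gls_and_pdsr(ell - 0.03, dt))
  expect_equal(g1$pdsr, g2$pdsr, tolerance = 1e-12)
})

test_that("the end-to-end phantom recovers its prescribed GLS and PDSR", {
  ph <- make_dense_phantom(es_strain = -0.15, period = 0.12, size = 48)
  # wrapping genuinely occurs at this encoding strength
  max_u <- max(abs((sqrt(1 + 2 * min(ph$true_curve$ell)) - 1))) * 5
  expect_gt(max_u * ph$ke, 0.5)
  crv <- analyse_dense(ph)
  g <- glance(crv)
  expect_equal(g$gls, ph$true_gls, tolerance = 0.01)
  expect_equal(g$pdsr, ph$true_pdsr, tolerance = 0.05 * ph$true_pdsr)
})

test_that("phantom recovery degrades gracefully at phase SNR 20", {
  ph <- make_dense_phantom(es_strain = -0.15, size = 48,
                           phase_noise_sd = 0.05, seed = 77)
  g <- glance(analyse_dense(ph))
  expect_equal(g$gls, ph$true_gls, tolerance = 0.02)
  expect_equal(g$pdsr, ph$true_pdsr, tolerance = 0.10 * ph$true_pdsr)
})
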