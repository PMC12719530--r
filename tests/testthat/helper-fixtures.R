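# shared fixtures built in code

# shortened IR schedule: 10 TIs spaced 0.3 s keeps the recovery curve well
# sampled for T1 in 0.5-1.5 s while cutting per-voxel fit cost
test_schedule <- function(n_ti = 10, rr = 0.3) {
  acquisition_schedule(n_ti = n_ti, rr = rr)
}

# random in-domain triglyceride parameters
random_tg <- function(n, seed = 42) {
  set.seed(seed)
  # draw a valid composition first, then map to bonds
  u <- matrix(stats::rexp(3 * n), n, 3)
  fac <- u / rowSums(u)
  b <- bonds_from_fac(fac[, 1], fac[, 2], fac[, 3])
  tibble::tibble(sfa = fac[, 1], mufa = fac[, 2], pufa = fac[, 3],
                 ndb = b$ndb, nmidb = b$nmidb)
}

# small two-region truth table for quick stack fits
small_truth <- function() {
  tibble::tibble(
    region = c("water", "fat_mix"),
    pdff = c(0, 0.8),
    t1 = c(1.2, 0.7),
    sfa = c(0.4, 0.5),
    mufa = c(0.4, 0.3),
    pufa = c(0.2, 0.2),
    r2star = c(30, 25),
    psi = c(-40, 50)
  )
}
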