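#' Forward signal model for inversion-recovery multi-echo imaging
#'
#' The complex voxel signal over the (TI, TE) grid:
#' \deqn{S(TI, TE) = (1 - 2\beta e^{-TI/T_1})\,[W + F\,c_F(TE)]\,
#'   e^{-R_2^* TE}\, e^{i(2\pi\psi TE + \phi_0)}}
#' where \eqn{c_F} is the nine-resonance fat dephasing factor
#' ([fat_signal()]), \eqn{\psi} the field offset in Hz and \eqn{\beta} the
#' inversion efficiency. Water and fat share a single T1.
#'
#' @param schedule An [acquisition_schedule()].
#' @param W,F Water and fat amplitudes (arbitrary units, >= 0).
#' @param t1 Longitudinal relaxation time (s).
#' @param r2star Effective transverse relaxation rate (1/s).
#' @param psi Field offset (Hz).
#' @param beta Inversion efficiency in (0, 1].
#' @param phi0 Global phase (rad).
#' @param params A [tg_params()] object for the fat spectrum.
#' @param spectrum Spectral table; defaults to [default_fat_spectrum()].
#' @return Complex matrix of size `n_ti x n_te`.
#' @examples
#' s <- model_signal(acquisition_schedule(), W = 1, F = 0, t1 = 1)
#' dim(s)
#' @export
model_signal <- function(schedule, W, F, t1, r2star = 0, psi = 0, beta = 1,
                         phi0 = 0, params = tg_params(),
                         spectrum = default_fat_spectrum()) {
  stopifnot(inherits(schedule, "acq_schedule"), W >= 0, F >= 0, t1 > 0,
            r2star >= 0, beta > 0, beta <= 1)
  te <- schedule$te_list
  ti <- schedule$ti_list
  rec <- 1 - 2 * beta * exp(-ti / t1)
  cf <- fat_signal(te, params, f0 = schedule$f0, spectrum = spectrum)
  echo <- (W + F * cf) * exp((-r2star + 2i * pi * psi) * te)
  outer(rec, echo) * exp(1i * phi0)
}

# Precomputed per-schedule quantities for the variable-projection objective.
# E_peaks: n_te x 9 matrix of per-peak phasors exp(i*2*pi*df_p*te_k).
fw_precompute <- function(schedule, spectrum) {
  df <- (spectrum$shift_ppm - water_shift_ppm) * 1e-6 * schedule$f0
  list(
    te = schedule$te_list,
    ti = schedule$ti_list,
    E_peaks = exp(outer(schedule$te_list, df, function(t, f) 2i * pi * f * t)),
    amp_const = spectrum$const + spectrum$c_cl * 17.3, # cl folded in later
    spectrum = spectrum
  )
}

# Normalised fat dephasing per TE for given (cl, ndb, nmidb) using the
# precomputed peak phasors; amplitudes floored at 0 so the objective stays
# defined at the box-bound corners outside the strict triglyceride domain.
fw_fat_vec <- function(pre, cl, ndb, nmidb) {
  sp <- pre$spectrum
  a <- sp$const + sp$c_cl * cl + sp$c_ndb * ndb + sp$c_nmidb * nmidb
  a <- pmax(a, 0)
  drop(pre$E_peaks %*% (a / sum(a)))
}

# Variable-projection objective: given nonlinear parameters theta and the
# measured complex matrix S (n_ti x n_te), profile out the two complex
# amplitudes and return the residual sum of squares plus the solved
# amplitudes. Exploits the separable TI (x) TE structure: the Gram matrix
# entries factor into TI sums times TE sums.
fw_varpro <- function(theta, S, pre, cl, S2, want_amp = FALSE) {
  t1 <- theta[1]; r2 <- theta[2]; psi <- theta[3]; beta <- theta[4]
  ndb <- theta[5]; nmidb <- theta[6]
  r <- 1 - 2 * beta * exp(-pre$ti / t1)
  e <- exp((-r2 + 2i * pi * psi) * pre$te)
  f <- fw_fat_vec(pre, cl, ndb, nmidb)
  sr2 <- sum(r * r)
  ee <- Re(e * Conj(e))                        # |e_k|^2
  g11 <- sr2 * sum(ee)
  g12 <- sr2 * sum(ee * f)                     # <C_w, C_f>
  g22 <- sr2 * sum(ee * Re(f * Conj(f)))
  v <- drop(crossprod(r, S))                   # sum_j r_j S_jk, length n_te
  b1 <- sum(Conj(e) * v)
  b2 <- sum(Conj(e * f) * v)
  # solve hermitian 2x2 [g11 g12; conj(g12) g22] a = b
  det <- g11 * g22 - Re(g12 * Conj(g12))
  if (!is.finite(det) || det <= 1e-30 * max(g11 * g22, 1e-300)) {
    # degenerate design (e.g. r == 0); fall back to water-only projection
    a1 <- if (g11 > 0) b1 / g11 else 0 + 0i
    a2 <- 0 + 0i
  } else {
    a1 <- (g22 * b1 - g12 * b2) / det
    a2 <- (g11 * b2 - Conj(g12) * b1) / det
  }
  rss <- S2 - Re(Conj(a1) * b1 + Conj(a2) * b2)
  rss <- max(rss, 0)
  if (want_amp) list(rss = rss, a_w = a1, a_f = a2) else rss
}

#' Fit a single voxel's inversion-recovery multi-echo signal
#'
#' Joint estimation of water amplitude, fat amplitude, T1, R2*, field offset,
#' inversion efficiency and the fat spectral parameters (ndb, nmidb) from a
#' complex (TI x TE) signal matrix. The two complex amplitudes are profiled
#' out by variable projection; the six nonlinear parameters are initialised
#' from a deterministic field-offset grid search (lowest-residual node,
#' ties broken toward the smallest |psi|) and refined with box-constrained
#' quasi-Newton iterations.
#'
#' @param signal Complex matrix, `n_ti x n_te`.
#' @param schedule An [acquisition_schedule()].
#' @param spectrum Spectral table; defaults to [default_fat_spectrum()].
#' @param cl Fixed mean chain length used during fitting.
#' @param psi_grid_n Number of field-offset grid nodes across
#'   +/- 1/(2*dTE).
#' @param n_restarts Number of grid nodes carried into local refinement.
#' @return A list of class `fw_voxel_fit` with elements `W`, `F`, `t1`,
#'   `r2star`, `psi`, `beta`, `phi0`, `ndb`, `nmidb`, `pdff`, `sfa`, `mufa`,
#'   `pufa`, `resnorm`, `ok` (quality flag; `FALSE` marks a non-converged
#'   voxel rather than raising an error).
#' @examples
#' sched <- acquisition_schedule(n_ti = 8, rr = 0.3)
#' s <- model_signal(sched, W = 0.3, F = 0.7, t1 = 0.8, psi = 40,
#'                   params = tg_params(ndb = 2.4, nmidb = 0.6))
#' fit <- fit_voxel(s, sched)
#' fit$pdff
#' @export
fit_voxel <- function(signal, schedule, spectrum = default_fat_spectrum(),
                      cl = 17.3, psi_grid_n = 64, n_restarts = 2) {
  stopifnot(is.matrix(signal), is.complex(signal) || is.numeric(signal))
  if (length(signal) < 6) stop("need at least 6 (TI, TE) samples", call. = FALSE)
  if (!all(is.finite(Re(signal)) & is.finite(Im(signal))))
    stop("signal must be finite", call. = FALSE)
  signal <- matrix(as.complex(signal), nrow(signal), ncol(signal))
  pre <- fw_precompute(schedule, spectrum)
  S2 <- sum(Re(signal * Conj(signal)))
  if (S2 == 0) return(fw_empty_fit())

  te <- schedule$te_list; ti <- schedule$ti_list
  dte <- stats::median(diff(te))
  psi_max <- 1 / (2 * dte)

  # T1 initialisation from the IR null of the first-echo magnitudes
  mag1 <- Mod(signal[, 1])
  t1_init <- ti[which.min(mag1)] / log(2)
  t1_init <- min(max(t1_init, 0.05), 5)

  theta0 <- c(t1 = t1_init, r2star = 20, psi = 0, beta = 0.95,
              ndb = 2.5, nmidb = 0.7)
  psi_nodes <- seq(-psi_max, psi_max, length.out = psi_grid_n)
  rss_grid <- vapply(psi_nodes, function(p) {
    th <- theta0; th["psi"] <- p
    fw_varpro(th, signal, pre, cl, S2)
  }, numeric(1))
  # rank by residual, ties toward smallest |psi|
  ord <- order(rss_grid, abs(psi_nodes))
  starts <- psi_nodes[ord[seq_len(min(n_restarts, length(ord)))]]

  lower <- c(0.02, 0, -psi_max, 0.5, 0, 0)
  upper <- c(10, 2000, psi_max, 1, 6, 3)
  pscale <- c(0.2, 100, max(psi_max / 50, 1), 0.05, 0.5, 0.2)

  best <- NULL
  for (p0 in starts) {
    th <- theta0; th["psi"] <- p0
    opt <- tryCatch(
      stats::optim(th, fw_varpro, S = signal, pre = pre, cl = cl, S2 = S2,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 300, factr = 1e4,
                                  parscale = pscale,
                                  ndeps = rep(1e-5, 6))),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value ||
        (opt$value == best$value && abs(opt$par[3]) < abs(best$par[3])))
      best <- opt
  }
  if (is.null(best)) {
    out <- fw_empty_fit(); out$ok <- FALSE; return(out)
  }
  # polish from the winning basin
  opt2 <- tryCatch(
    stats::optim(best$par, fw_varpro, S = signal, pre = pre, cl = cl, S2 = S2,
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 300, factr = 1e1, parscale = pscale,
                                ndeps = rep(1e-6, 6))),
    error = function(e) NULL)
  if (!is.null(opt2) && opt2$value <= best$value) best <- opt2

  th <- best$par
  vp <- fw_varpro(th, signal, pre, cl, S2, want_amp = TRUE)
  a_w <- vp$a_w; a_f <- vp$a_f
  W <- Mod(a_w); F <- Mod(a_f)
  phi0 <- if (W >= F) Arg(a_w) else Arg(a_f)
  fac <- fac_clamped(th[5], th[6])
  out <- list(W = W, F = F, t1 = unname(th[1]), r2star = unname(th[2]),
              psi = unname(th[3]), beta = unname(th[4]), phi0 = phi0,
              ndb = unname(th[5]), nmidb = unname(th[6]),
              pdff = pdff(W, F),
              sfa = fac$sfa, mufa = fac$mufa, pufa = fac$pufa,
              resnorm = vp$rss,
              # 52 = line-search stall at machine precision, still a minimum
              ok = is.finite(vp$rss) && best$convergence %in% c(0L, 1L, 52L))
  class(out) <- "fw_voxel_fit"
  out
}

# clamped composition for fitted (ndb, nmidb) that may sit marginally
# outside the strict domain at box bounds
fac_clamped <- function(ndb, nmidb) {
  pufa <- min(max(nmidb / 3, 0), 1)
  mufa <- min(max((ndb - 2 * nmidb) / 3, 0), 1 - pufa)
  list(sfa = 1 - mufa - pufa, mufa = mufa, pufa = pufa)
}

fw_empty_fit <- function() {
  out <- list(W = 0, F = 0, t1 = NA_real_, r2star = NA_real_, psi = NA_real_,
              beta = NA_real_, phi0 = NA_real_, ndb = NA_real_,
              nmidb = NA_real_, pdff = NA_real_, sfa = NA_real_,
              mufa = NA_real_, pufa = NA_real_, resnorm = NA_real_, ok = FALSE)
  class(out) <- "fw_voxel_fit"
  out
}

#' Proton density fat fraction
#'
#' `F / (W + F)`; returns `NaN` where `W + F` is zero. Vectorised.
#'
#' @param W,F Non-negative water and fat amplitudes.
#' @return Fraction(s) in \[0, 1\].
#' @examples
#' pdff(1, 3)  # 0.75
#' @export
pdff <- function(W, F) {
  if (any(W < 0 | F < 0, na.rm = TRUE))
    stop("W and F must be non-negative", call. = FALSE)
  tot <- W + F
  ifelse(tot > 0, F / tot, NaN)
}

#' Fit an inversion-recovery multi-echo image stack voxel-by-voxel
#'
#' Applies [fit_voxel()] to every in-mask voxel of a 4-D complex stack
#' indexed `(ti, te, row, col)` and assembles parametric maps of PDFF, T1,
#' SFA/MUFA/PUFA, field offset and R2*. Voxels outside the mask are `NaN`.
#' Fitting is voxel-independent, so the result does not depend on
#' processing order.
#'
#' @param stack A list with elements `data` (complex array
#'   `n_ti x n_te x nrow x ncol`) and `schedule` (an
#'   [acquisition_schedule()]), e.g. from [make_fatwater_phantom()].
#' @param mask Logical/0-1 matrix `nrow x ncol`, or `NULL` to fit voxels
#'   with non-zero signal.
#' @param ... Passed to [fit_voxel()].
#' @return An object of class `fatwater_fit`: a list of numeric map matrices
#'   (`pdff`, `t1`, `sfa`, `mufa`, `pufa`, `psi`, `r2star`, `beta`, `W`, `F`,
#'   `ndb`, `nmidb`, `resnorm`), a logical `ok` quality-mask matrix, and the
#'   `schedule`. Use [tidy.fatwater_fit()] for a per-voxel tibble.
#' @export
fit_stack <- function(stack, mask = NULL, ...) {
  data <- stack$data
  schedule <- stack$schedule
  stopifnot(length(dim(data)) == 4, inherits(schedule, "acq_schedule"))
  nr <- dim(data)[3]; nc <- dim(data)[4]
  if (is.null(mask)) {
    mask <- apply(Mod(data), c(3, 4), sum) > 0
  } else {
    if (!all(dim(mask) == c(nr, nc)))
      stop("mask geometry does not match the stack", call. = FALSE)
    mask <- matrix(as.logical(mask), nr, nc)
  }
  if (!any(mask)) stop("mask is empty", call. = FALSE)

  map_names <- c("pdff", "t1", "sfa", "mufa", "pufa", "psi", "r2star",
                 "beta", "W", "F", "ndb", "nmidb", "resnorm")
  maps <- lapply(map_names, function(n) matrix(NaN, nr, nc))
  names(maps) <- map_names
  ok <- matrix(FALSE, nr, nc)

  idx <- which(mask, arr.ind = TRUE)
  for (v in seq_len(nrow(idx))) {
    i <- idx[v, 1]; j <- idx[v, 2]
    fit <- fit_voxel(data[, , i, j], schedule, ...)
    for (n in map_names) maps[[n]][i, j] <- fit[[n]]
    ok[i, j] <- fit$ok
  }
  structure(c(maps, list(ok = ok, mask = mask, schedule = schedule)),
            class = "fatwater_fit")
}

#' @export
print.fatwater_fit <- function(x, ...) {
  n <- sum(x$mask)
  cat(sprintf("<fatwater_fit> %d x %d maps, %d fitted voxels (%d flagged)\n",
              nrow(x$pdff), ncol(x$pdff), n, sum(x$mask & !x$ok)))
  cat(sprintf("  PDFF range %.3f-%.3f, T1 range %.3f-%.3f s\n",
              min(x$pdff[x$mask], na.rm = TRUE),
              max(x$pdff[x$mask], na.rm = TRUE),
              min(x$t1[x$mask], na.rm = TRUE),
              max(x$t1[x$mask], na.rm = TRUE)))
  invisible(x)
}
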