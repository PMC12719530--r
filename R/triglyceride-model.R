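#' Triglyceride spectral parameters
#'
#' Bundles the three parameters of the mean triglyceride spectrum: the mean
#' fatty-acid chain length `cl` (carbons), the mean number of double bonds per
#' triglyceride `ndb`, and the mean number of methylene-interrupted
#' double-bond pairs per triglyceride `nmidb`. These determine the relative
#' amplitudes of the nine fat resonances and, through linear relationships,
#' the saturated/monounsaturated/polyunsaturated composition of the depot.
#'
#' The admissible domain requires a non-negative fatty-acid composition:
#' `ndb >= 0`, `nmidb >= 0`, `ndb - 2*nmidb >= 0` (MUFA), `ndb - nmidb <= 3`
#' (SFA), `nmidb <= 3` (PUFA), and `cl > 4` so the methylene peak amplitude
#' stays positive over that domain.
#'
#' @param cl Mean fatty-acid chain length in carbons. Default 17.3, the
#'   conventional estimate for adipose tissue.
#' @param ndb Mean number of double bonds per triglyceride.
#' @param nmidb Mean number of methylene-interrupted double-bond pairs per
#'   triglyceride.
#' @return An object of class `tg_params` (a named list with `cl`, `ndb`,
#'   `nmidb`).
#' @examples
#' tg_params(ndb = 2.7, nmidb = 0.8)
#' @export
tg_params <- function(cl = 17.3, ndb = 2.5, nmidb = 0.7) {
  stopifnot(is.numeric(cl), is.numeric(ndb), is.numeric(nmidb),
            length(cl) == 1, length(ndb) == 1, length(nmidb) == 1)
  check_tg_domain(cl, ndb, nmidb)
  structure(list(cl = cl, ndb = ndb, nmidb = nmidb), class = "tg_params")
}

check_tg_domain <- function(cl, ndb, nmidb) {
  if (ndb < 0) stop("invalid triglyceride parameters: ndb < 0", call. = FALSE)
  if (nmidb < 0) stop("invalid triglyceride parameters: nmidb < 0", call. = FALSE)
  if (ndb - 2 * nmidb < -1e-12)
    stop("invalid triglyceride parameters: ndb - 2*nmidb < 0 (negative MUFA fraction)",
         call. = FALSE)
  if (ndb - nmidb > 3 + 1e-12)
    stop("invalid triglyceride parameters: ndb - nmidb > 3 (negative SFA fraction)",
         call. = FALSE)
  if (nmidb > 3 + 1e-12)
    stop("invalid triglyceride parameters: nmidb > 3 (PUFA fraction > 1)", call. = FALSE)
  if (cl <= 4)
    stop("invalid triglyceride parameters: cl <= 4 (negative methylene amplitude)",
         call. = FALSE)
  invisible(TRUE)
}

#' The nine-resonance triglyceride spectrum table
#'
#' Returns the default spectral table: nine fat resonances with absolute
#' chemical shifts (ppm) and proton-count amplitudes expressed as affine
#' functions of `(cl, ndb, nmidb)`, i.e. amplitude =
#' `const + c_cl*cl + c_ndb*ndb + c_nmidb*nmidb`. Water is referenced at
#' 4.70 ppm. At `(cl = 18, ndb = 6, nmidb = 3)` the amplitudes sum to 98,
#' the proton count of trilinolein, which fixes the table's normalisation.
#'
#' @return A tibble with columns `peak`, `shift_ppm`, `const`, `c_cl`,
#'   `c_ndb`, `c_nmidb`.
#' @seealso [read_spectrum_json()], [write_spectrum_json()] to swap in
#'   alternative literature tables.
#' @export
default_fat_spectrum <- function() {
  tibble::tibble(
    peak = c("olefinic", "glycerol_ch", "glycerol_ch2", "diallylic",
             "alpha_carboxyl", "allylic", "beta_carboxyl", "methylene",
             "methyl"),
    shift_ppm = c(5.29, 5.19, 4.20, 2.75, 2.24, 2.02, 1.60, 1.30, 0.90),
    const   = c(0, 1, 4, 0, 6, 0, 6, -24, 9),
    c_cl    = c(0, 0, 0, 0, 0, 0, 0, 6, 0),
    c_ndb   = c(2, 0, 0, 0, 0, 4, 0, -8, 0),
    c_nmidb = c(0, 0, 0, 2, 0, -4, 0, 2, 0)
  )
}

#' Water reference chemical shift (ppm)
#' @keywords internal
water_shift_ppm <- 4.70

#' Normalised fat peak amplitudes
#'
#' Evaluates the proton-count amplitude of each of the nine fat resonances at
#' the given triglyceride parameters and normalises them to sum to one.
#'
#' @param params A [tg_params()] object.
#' @param spectrum Spectral table; defaults to [default_fat_spectrum()].
#' @return Named numeric vector of nine non-negative relative amplitudes
#'   summing to 1.
#' @examples
#' peak_amplitudes(tg_params(ndb = 0, nmidb = 0))  # no olefinic/diallylic signal
#' @export
peak_amplitudes <- function(params, spectrum = default_fat_spectrum()) {
  stopifnot(inherits(params, "tg_params"))
  a <- spectrum$const + spectrum$c_cl * params$cl +
    spectrum$c_ndb * params$ndb + spectrum$c_nmidb * params$nmidb
  if (any(a < -1e-9))
    stop("negative peak amplitude; parameters outside the spectral domain",
         call. = FALSE)
  a <- pmax(a, 0)
  stats::setNames(a / sum(a), spectrum$peak)
}

#' Fatty acid composition from double-bond counts
#'
#' Maps the spectral double-bond parameters to the fractions of saturated,
#' monounsaturated and polyunsaturated fatty acid chains using the
#' established linear relationships `pufa = nmidb/3`,
#' `mufa = (ndb - 2*nmidb)/3`, `sfa = 1 - mufa - pufa`.
#'
#' @param ndb Mean double bonds per triglyceride.
#' @param nmidb Mean methylene-interrupted double-bond pairs per triglyceride.
#' @return A tibble with columns `sfa`, `mufa`, `pufa`, each in \[0, 1\] and
#'   summing to 1. Vectorised over `ndb`/`nmidb`.
#' @examples
#' fac_from_bonds(0, 0)    # fully saturated
#' fac_from_bonds(6, 3)    # fully polyunsaturated (trilinolein-like)
#' @export
fac_from_bonds <- function(ndb, nmidb) {
  stopifnot(length(ndb) == length(nmidb))
  bad <- ndb < -1e-12 | nmidb < -1e-12 | (ndb - 2 * nmidb) < -1e-12 |
    (ndb - nmidb) > 3 + 1e-12 | nmidb > 3 + 1e-12
  if (any(bad, na.rm = TRUE))
    stop("(ndb, nmidb) outside the triglyceride domain", call. = FALSE)
  pufa <- nmidb / 3
  mufa <- (ndb - 2 * nmidb) / 3
  tibble::tibble(sfa = 1 - mufa - pufa, mufa = mufa, pufa = pufa)
}

#' Double-bond counts from a fatty acid composition
#'
#' Exact algebraic inverse of [fac_from_bonds()]: `nmidb = 3*pufa`,
#' `ndb = 3*mufa + 6*pufa`. Used by the phantom generator to prescribe a
#' composition per region.
#'
#' @param sfa,mufa,pufa Fractions in \[0, 1\] summing to 1 (vectorised).
#' @return A tibble with columns `ndb`, `nmidb`.
#' @examples
#' bonds_from_fac(0.5, 0.3, 0.2)
#' @export
bonds_from_fac <- function(sfa, mufa, pufa) {
  stopifnot(length(sfa) == length(mufa), length(mufa) == length(pufa))
  if (any(sfa < -1e-12 | mufa < -1e-12 | pufa < -1e-12 |
            abs(sfa + mufa + pufa - 1) > 1e-9, na.rm = TRUE))
    stop("fatty acid composition must be non-negative and sum to 1", call. = FALSE)
  tibble::tibble(ndb = 3 * mufa + 6 * pufa, nmidb = 3 * pufa)
}

#' Complex fat dephasing factor
#'
#' The multi-resonance fat signal relative to water:
#' `sum_p a_p * exp(1i * 2*pi * df_p * te)` with normalised amplitudes `a_p`
#' and off-resonance frequencies `df_p = (shift_p - 4.70 ppm) * 1e-6 * f0`.
#' Magnitude is 1 at `te = 0` and never exceeds 1.
#'
#' @param te Echo time(s) in seconds (vectorised).
#' @param params A [tg_params()] object.
#' @param f0 Spectrometer frequency in Hz. Default 400.2e6 (9.4 T).
#' @param spectrum Spectral table; defaults to [default_fat_spectrum()].
#' @return Complex vector, one value per echo time.
#' @examples
#' fat_signal(0, tg_params())         # exactly 1+0i
#' Mod(fat_signal(2e-3, tg_params())) # <= 1
#' @export
fat_signal <- function(te, params, f0 = 400.2e6,
                       spectrum = default_fat_spectrum()) {
  stopifnot(all(te >= 0), f0 > 0)
  a <- peak_amplitudes(params, spectrum)
  df <- (spectrum$shift_ppm - water_shift_ppm) * 1e-6 * f0
  # outer(te, df): n_te x 9 phase matrix
  ph <- outer(te, df, function(t, f) 2 * pi * f * t)
  drop(exp(1i * ph) %*% a)
}

#' Read or write a spectral table as JSON
#'
#' The table is stored as an array of objects with fields `peak`,
#' `shift_ppm`, `const`, `c_cl`, `c_ndb`, `c_nmidb`, so alternative
#' literature amplitude tables can be supplied.
#'
#' @param path File path.
#' @return `read_spectrum_json()` returns the spectrum tibble;
#'   `write_spectrum_json()` returns `path` invisibly.
#' @export
read_spectrum_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("peak", "shift_ppm", "const", "c_cl", "c_ndb", "c_nmidb")
  if (!all(need %in% names(x)))
    stop("spectrum JSON missing fields: ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  tibble::as_tibble(x)[, need]
}

#' @rdname read_spectrum_json
#' @param spectrum Spectrum tibble to write.
#' @export
write_spectrum_json <- function(spectrum, path) {
  jsonlite::write_json(spectrum, path, digits = NA, pretty = TRUE)
  invisible(path)
}
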