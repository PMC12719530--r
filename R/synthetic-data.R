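#' Synthetic fat-water-T1 phantom
#'
#' Generates an inversion-recovery multi-echo image stack from the forward
#' model ([model_signal()]) over a schematic region map with prescribed
#' per-region PDFF, T1, fatty acid composition, R2* and field offset, plus
#' optional complex Gaussian noise. Every region's ground truth is returned
#' alongside the data, so the joint fitter can be checked by parameter
#' recovery. The default regions cover water (PDFF 0), myocardium-like
#' lipid (PDFF 0.3), EAT-like (PDFF 0.8) and pure fat (PDFF 1.0) with T1 in
#' 0.7-1.3 s and SFA in 0.3-0.6.
#'
#' @param size Image side length in pixels (square); regions are laid out
#'   as quadrants.
#' @param truth Tibble with one row per region: columns `region`, `pdff`,
#'   `t1`, `sfa`, `mufa`, `pufa`, `r2star`, `psi`. Default =
#'   `default_phantom_truth()`.
#' @param schedule An [acquisition_schedule()].
#' @param snr Signal-to-noise ratio (mean in-mask magnitude / per-channel
#'   noise SD); `NULL` (default) for noiseless data.
#' @param beta True inversion efficiency.
#' @param phi0 True global phase (rad).
#' @param cl Chain length used in the forward model.
#' @param seed Random seed; required when `snr` is finite.
#' @return A list of class `fw_phantom`: `data` (complex array
#'   `n_ti x n_te x size x size`), `schedule`, `region_map` (integer
#'   matrix), `mask`, `truth` (tibble, augmented with the implied `ndb`,
#'   `nmidb`, `W`, `F`), `snr`, `seed`.
#' @export
make_fatwater_phantom <- function(size = 32, truth = default_phantom_truth(),
                                  schedule = acquisition_schedule(),
                                  snr = NULL, beta = 0.95, phi0 = 0.3,
                                  cl = 17.3, seed = NULL) {
  stopifnot(size >= 2, nrow(truth) >= 1)
  if (!is.null(snr) && is.null(seed))
    stop("a seed is required for noisy phantoms", call. = FALSE)
  bonds <- bonds_from_fac(truth$sfa, truth$mufa, truth$pufa)
  truth <- dplyr::mutate(truth, ndb = bonds$ndb, nmidb = bonds$nmidb,
                         W = 1 - pdff, F = pdff, beta = beta, phi0 = phi0)
  region_map <- quadrant_map(size, nrow(truth))
  n_ti <- length(schedule$ti_list); n_te <- length(schedule$te_list)
  data <- array(0 + 0i, c(n_ti, n_te, size, size))
  for (r in seq_len(nrow(truth))) {
    tr <- truth[r, ]
    params <- tg_params(cl = cl, ndb = tr$ndb, nmidb = tr$nmidb)
    sig <- model_signal(schedule, W = tr$W, F = tr$F, t1 = tr$t1,
                        r2star = tr$r2star, psi = tr$psi, beta = beta,
                        phi0 = phi0, params = params)
    for (v in which(region_map == r)) {
      i <- (v - 1L) %% size + 1L; j <- (v - 1L) %/% size + 1L
      data[, , i, j] <- sig
    }
  }
  mask <- region_map > 0
  if (!is.null(snr)) {
    set.seed(seed)
    mag <- matrix(Mod(data), n_ti * n_te)
    sigma <- mean(mag[, as.vector(mask)]) / snr
    noise <- array(stats::rnorm(length(data), sd = sigma) +
                     1i * stats::rnorm(length(data), sd = sigma), dim(data))
    data <- data + noise
  }
  structure(list(data = data, schedule = schedule, region_map = region_map,
                 mask = mask, truth = truth, snr = snr, seed = seed),
            class = "fw_phantom")
}

#' @rdname make_fatwater_phantom
#' @export
default_phantom_truth <- function() {
  tibble::tibble(
    region = c("water", "myocardium_like", "eat_like", "fat"),
    pdff = c(0, 0.3, 0.8, 1.0),
    t1 = c(1.3, 0.8, 0.7, 0.7),
    sfa = c(0.40, 0.30, 0.60, 0.45),
    mufa = c(0.40, 0.50, 0.30, 0.35),
    pufa = c(0.20, 0.20, 0.10, 0.20),
    r2star = c(30, 40, 25, 25),
    psi = c(-40, 60, -60, 30)
  )
}

# split a square image into nearly equal vertical-then-horizontal blocks
quadrant_map <- function(size, n_regions) {
  region_map <- matrix(0L, size, size)
  n_col_blocks <- ceiling(sqrt(n_regions))
  n_row_blocks <- ceiling(n_regions / n_col_blocks)
  rb <- round(seq(0, size, length.out = n_row_blocks + 1))
  cb <- round(seq(0, size, length.out = n_col_blocks + 1))
  r <- 0L
  for (bi in seq_len(n_row_blocks)) for (bj in seq_len(n_col_blocks)) {
    r <- r + 1L
    if (r > n_regions) break
    region_map[(rb[bi] + 1):rb[bi + 1], (cb[bj] + 1):cb[bj + 1]] <- r
  }
  region_map
}

#' Synthetic ASL T1 pair from a prescribed flow map
#'
#' Inverts the FAIR flow relation so that [mbf_from_t1()] applied to the
#' returned selective/global T1 pair recovers the prescribed flow exactly:
#' `t1_sel = t1_glob / (1 + mbf * t1_blood / (60 * lambda))`.
#'
#' @param mbf_map Prescribed flow (mL/g/min); scalar, vector or matrix.
#' @param cfg An [asl_config()].
#' @param t1_glob Global-inversion T1 (s); default 1.8.
#' @param t1_noise_frac Relative Gaussian noise SD applied to both T1s
#'   (e.g. 0.02 for 2%); 0 for noiseless.
#' @param seed Seed, required when `t1_noise_frac > 0`.
#' @return A list: `t1_selective`, `t1_global` (same shape as `mbf_map`),
#'   `mbf_true`, `cfg`.
#' @export
make_asl_phantom <- function(mbf_map, cfg = asl_config(), t1_glob = 1.8,
                             t1_noise_frac = 0, seed = NULL) {
  stopifnot(all(mbf_map >= 0), t1_glob > 0, t1_noise_frac >= 0)
  t1_sel <- t1_glob / (1 + mbf_map * cfg$t1_blood / (60 * cfg$lambda_bp))
  t1_g <- mbf_map * 0 + t1_glob
  if (t1_noise_frac > 0) {
    if (is.null(seed)) stop("a seed is required for noisy phantoms", call. = FALSE)
    set.seed(seed)
    t1_sel <- t1_sel * (1 + stats::rnorm(length(t1_sel), sd = t1_noise_frac))
    t1_g <- t1_g * (1 + stats::rnorm(length(t1_g), sd = t1_noise_frac))
  }
  list(t1_selective = t1_sel, t1_global = t1_g, mbf_true = mbf_map, cfg = cfg)
}

#' Synthetic DENSE series with a prescribed strain-time curve
#'
#' Builds displacement-encoded phase images of an annular wall deforming by
#' uniform dilation about its centre with stretch
#' `lambda(t) = sqrt(1 + 2*ell(t))`, so the wall-tangent Lagrangian strain
#' equals the prescribed global curve `ell(t)` exactly at every pixel.
#' Default curve: `ell(t) = es_strain * sin(pi*t/period)^2`. Phases are
#' `2*pi*ke*u`, wrapped to (-pi, pi]; wrapping occurs whenever
#' `max|u| * ke > 0.5`.
#'
#' @param es_strain Prescribed end-systolic strain (negative = shortening).
#' @param period Cardiac period (s).
#' @param n_frames Number of frames; frame 1 at t = 0 is the reference.
#' @param frame_interval Frame spacing (s); default 7 ms (the DENSE TR).
#' @param ke Encoding frequency (cycles/mm).
#' @param size Image side (pixels).
#' @param spacing Pixel spacing (mm).
#' @param r_inner,r_outer Annulus radii (mm).
#' @param phase_noise_sd Gaussian phase noise SD (rad) added before
#'   wrapping; 0 for noiseless. The reciprocal of the phase SNR.
#' @param seed Seed, required when `phase_noise_sd > 0`.
#' @return A list of class `dense_series` suitable for [analyse_dense()]:
#'   `phase_x`, `phase_y`, `ke`, `frame_interval`, `mask`, `spacing`, plus
#'   ground truth `true_curve` (tibble `time`, `ell`), `true_gls`,
#'   `true_pdsr` (the continuous-time peak recovery rate
#'   `|es_strain| * pi / period`).
#' @export
make_dense_phantom <- function(es_strain = -0.15, period = 0.12,
                               n_frames = 18, frame_interval = 7e-3,
                               ke = 1.0, size = 64, spacing = 0.25,
                               r_inner = 3, r_outer = 5,
                               phase_noise_sd = 0, seed = NULL) {
  stopifnot(es_strain > -0.5, ke > 0, n_frames >= 3)
  if (phase_noise_sd > 0 && is.null(seed))
    stop("a seed is required for noisy phantoms", call. = FALSE)
  ctr <- (size + 1) / 2
  xs <- (seq_len(size) - ctr) * spacing
  X <- matrix(xs, size, size)           # x varies along rows
  Y <- matrix(xs, size, size, byrow = TRUE)
  R <- sqrt(X^2 + Y^2)
  mask <- R >= r_inner & R <= r_outer
  tt <- (seq_len(n_frames) - 1) * frame_interval
  ell <- es_strain * sin(pi * tt / period)^2
  lam <- sqrt(1 + 2 * ell)
  if (phase_noise_sd > 0) set.seed(seed)
  wrap <- function(p) ((p + pi) %% (2 * pi)) - pi
  phase_x <- phase_y <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    ux <- (lam[f] - 1) * X
    uy <- (lam[f] - 1) * Y
    px <- 2 * pi * ke * ux
    py <- 2 * pi * ke * uy
    if (phase_noise_sd > 0) {
      px <- px + stats::rnorm(length(px), sd = phase_noise_sd)
      py <- py + stats::rnorm(length(py), sd = phase_noise_sd)
    }
    phase_x[[f]] <- wrap(px)
    phase_y[[f]] <- wrap(py)
  }
  structure(list(phase_x = phase_x, phase_y = phase_y, ke = ke,
                 frame_interval = frame_interval, mask = mask,
                 spacing = spacing, magnitude = NULL,
                 true_curve = tibble::tibble(time = tt, ell = ell),
                 true_gls = es_strain,
                 true_pdsr = abs(es_strain) * pi / period),
            class = "dense_series")
}

#' Synthetic cine mask stack from a half-ellipsoid left ventricle
#'
#' Digitises a truncated half-ellipsoid LV (endocardial semi-axes
#' `a, a, c`) into per-slice circular endocardial and epicardial masks at
#' end-diastole, shrinks the endocardial radii by `sqrt(esv_ratio)` for
#' end-systole (so the continuous cavity-volume ratio is `esv_ratio`
#' exactly), and returns the closed-form ground-truth metrics.
#'
#' @param a Endocardial equatorial radius (mm).
#' @param c_ax Endocardial long-axis length (mm).
#' @param wall Wall thickness (mm) added radially for the epicardium.
#' @param esv_ratio ESV/EDV of the continuous solids; default 0.35
#'   (EF 65%).
#' @param n_slices Number of short-axis slices spanning the long axis.
#' @param size Mask side (pixels).
#' @param pixel_spacing In-plane spacing (mm).
#' @param body_weight Body weight (g) carried for indexing.
#' @param density Myocardial density (mg/uL) used for the true mass.
#' @return A list of class `lv_mask_stack` for [lv_metrics()] plus `truth`:
#'   closed-form `edv_ul`, `esv_ul`, `ef_pct`, `lv_mass_mg`, `edwt_mm`,
#'   `eswt_mm`.
#' @export
make_cine_phantom <- function(a = 1.5, c_ax = 4, wall = 0.9,
                              esv_ratio = 0.35, n_slices = 8, size = 64,
                              pixel_spacing = 0.2, body_weight = 40,
                              density = 1.05) {
  stopifnot(a > 0, c_ax > 0, wall > 0, esv_ratio > 0, esv_ratio < 1)
  thickness <- c_ax / n_slices
  z <- (seq_len(n_slices) - 0.5) * thickness
  r_endo <- a * sqrt(pmax(1 - (z / c_ax)^2, 0))
  shrink <- sqrt(esv_ratio)
  disk <- function(r) {
    ctr <- (size + 1) / 2
    xs <- (seq_len(size) - ctr) * pixel_spacing
    outer(xs, xs, function(x, y) sqrt(x^2 + y^2) <= r)
  }
  endo_ed <- lapply(r_endo, disk)
  epi_ed <- lapply(r_endo + wall, disk)
  endo_es <- lapply(r_endo * shrink, disk)
  epi_es <- epi_ed
  edv <- (2 / 3) * pi * a^2 * c_ax
  esv <- esv_ratio * edv
  v_epi <- sum(pi * (r_endo + wall)^2) * thickness
  v_endo_slices <- sum(pi * r_endo^2) * thickness
  mid <- ceiling(n_slices / 2)
  truth <- tibble::tibble(
    edv_ul = edv, esv_ul = esv,
    ef_pct = 100 * (1 - esv_ratio),
    lv_mass_mg = (v_epi - v_endo_slices) * density,
    edwt_mm = wall,
    eswt_mm = wall + (1 - shrink) * r_endo[mid]
  )
  structure(list(endo_ed = endo_ed, epi_ed = epi_ed, endo_es = endo_es,
                 epi_es = epi_es, pixel_spacing = pixel_spacing,
                 slice_thickness = thickness, body_weight = body_weight,
                 truth = truth),
            class = "lv_mask_stack")
}

#' Synthetic two-group cohort
#'
#' Draws per-animal values for each variable from normal effect models
#' (control mean, treatment shift, common SD) and per-animal glucose
#' tolerance curves from group templates plus Gaussian noise. The default
#' effect model is the study's powering assumption: a perfusion-reserve
#' (MPR) shift of 0.4 with SD 0.35.
#'
#' @param n_per_group Integer vector of length 2 (control, treated);
#'   default `c(15, 15)`.
#' @param effects Tibble with columns `variable`, `control_mean`, `shift`,
#'   `sd`. Default: MPR with control mean 1.4, shift 0.4, SD 0.35.
#' @param gtt_times GTT sampling grid (min).
#' @param gtt_templates Named list of glucose templates (mg/dL), one per
#'   group, matching `gtt_times`; `NULL` disables GTT curves.
#' @param gtt_noise_sd Per-sample glucose noise SD (mg/dL).
#' @param seed Random seed (required).
#' @return A list: `cohort` (long tibble `animal_id`, `group`, `variable`,
#'   `value`), `gtt` (tibble `animal_id`, `group`, `time`, `glucose`, or
#'   `NULL`), `effects` (the true effect table).
#' @export
make_cohort <- function(n_per_group = c(15, 15),
                        effects = tibble::tibble(variable = "mpr",
                                                 control_mean = 1.4,
                                                 shift = 0.4, sd = 0.35),
                        gtt_times = c(0, 10, 30, 60, 90, 120),
                        gtt_templates = list(
                          control = c(150, 420, 480, 430, 360, 300),
                          treated = c(130, 380, 400, 330, 260, 210)),
                        gtt_noise_sd = 25, seed) {
  stopifnot(length(n_per_group) == 2, all(n_per_group >= 2),
            all(effects$sd > 0))
  set.seed(seed)
  groups <- c("control", "treated")
  ids <- list(
    control = sprintf("C%02d", seq_len(n_per_group[1])),
    treated = sprintf("T%02d", seq_len(n_per_group[2]))
  )
  cohort <- purrr::map_dfr(seq_along(groups), function(gi) {
    g <- groups[gi]
    purrr::map_dfr(seq_len(nrow(effects)), function(vi) {
      e <- effects[vi, ]
      mu <- e$control_mean + if (gi == 2) e$shift else 0
      tibble::tibble(animal_id = ids[[g]], group = g,
                     variable = e$variable,
                     value = stats::rnorm(n_per_group[gi], mu, e$sd))
    })
  })
  gtt <- NULL
  if (!is.null(gtt_templates)) {
    stopifnot(all(groups %in% names(gtt_templates) | length(gtt_templates) == 2))
    tmpl <- stats::setNames(gtt_templates[1:2], groups)
    gtt <- purrr::map_dfr(groups, function(g) {
      purrr::map_dfr(ids[[g]], function(id) {
        gl <- pmax(tmpl[[g]] +
                     stats::rnorm(length(gtt_times), sd = gtt_noise_sd), 0)
        tibble::tibble(animal_id = id, group = g, time = gtt_times,
                       glucose = gl)
      })
    })
  }
  list(cohort = cohort, gtt = gtt, effects = effects)
}
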