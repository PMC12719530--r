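#' Cavity volume by slice summation
#'
#' Simpson-style slice summation of a binary mask stack: per-slice
#' cross-sectional area (pixel count times pixel spacing squared) multiplied
#' by the slice thickness, summed over contiguous slices. 1 mm^3 = 1 uL.
#'
#' @param masks List of logical/0-1 matrices (one per slice) or a single
#'   matrix.
#' @param pixel_spacing In-plane spacing (mm).
#' @param slice_thickness Slice thickness (mm).
#' @return Volume in microliters.
#' @examples
#' cavity_volume(matrix(1, 10, 10), 0.2, 1.0)  # 4 uL
#' @export
cavity_volume <- function(masks, pixel_spacing, slice_thickness) {
  stopifnot(pixel_spacing > 0, slice_thickness > 0)
  if (is.matrix(masks)) masks <- list(masks)
  areas <- vapply(masks, function(m) sum(m != 0) * pixel_spacing^2,
                  numeric(1))
  sum(areas) * slice_thickness
}

#' Left-ventricular mass from endocardial and epicardial masks
#'
#' Myocardial shell volume (epicardial minus endocardial cavity volume)
#' times myocardial density.
#'
#' @param endo_masks,epi_masks Mask stacks as in [cavity_volume()];
#'   endocardium must be contained in the epicardium.
#' @param pixel_spacing,slice_thickness Geometry (mm).
#' @param density Myocardial density (mg/uL); default 1.05.
#' @return Mass in mg.
#' @export
lv_mass <- function(endo_masks, epi_masks, pixel_spacing, slice_thickness,
                    density = 1.05) {
  v_epi <- cavity_volume(epi_masks, pixel_spacing, slice_thickness)
  v_endo <- cavity_volume(endo_masks, pixel_spacing, slice_thickness)
  if (v_endo > v_epi)
    stop("endocardial volume exceeds epicardial volume", call. = FALSE)
  (v_epi - v_endo) * density
}

#' Ejection fraction
#'
#' `100 * (EDV - ESV) / EDV` in percent.
#'
#' @param edv,esv End-diastolic and end-systolic volumes (uL), `edv > 0`.
#' @return Percentage.
#' @examples
#' ejection_fraction(60, 21)  # 65
#' @export
ejection_fraction <- function(edv, esv) {
  stopifnot(edv > 0)
  100 * (edv - esv) / edv
}

#' Mean wall thickness by radial rays
#'
#' Casts `n_rays` equally spaced radial rays from the epicardial centroid of
#' a single (mid-ventricular) slice and averages the difference between the
#' outermost epicardial and outermost endocardial in-mask radius along each
#' ray.
#'
#' @param endo_mask,epi_mask Binary masks of one slice.
#' @param pixel_spacing In-plane spacing (mm).
#' @param n_rays Number of rays; default 24.
#' @return Mean thickness in mm.
#' @export
wall_thickness <- function(endo_mask, epi_mask, pixel_spacing, n_rays = 24) {
  epi <- epi_mask != 0
  endo <- endo_mask != 0
  if (!any(epi)) return(0)
  idx <- which(epi, arr.ind = TRUE)
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  r_max <- max(sqrt((idx[, 1] - cx)^2 + (idx[, 2] - cy)^2)) + 1
  rs <- seq(0, r_max, by = 0.25)            # quarter-pixel sampling
  angles <- (seq_len(n_rays) - 1) * 2 * pi / n_rays
  in_mask <- function(m, x, y) {
    i <- round(x); j <- round(y)
    ok <- i >= 1 & i <= nrow(m) & j >= 1 & j <= ncol(m)
    out <- rep(FALSE, length(x))
    out[ok] <- m[cbind(i[ok], j[ok])]
    out
  }
  thick <- vapply(angles, function(a) {
    xs <- cx + rs * cos(a); ys <- cy + rs * sin(a)
    hit_epi <- in_mask(epi, xs, ys)
    hit_endo <- in_mask(endo, xs, ys)
    r_epi <- if (any(hit_epi)) max(rs[hit_epi]) else 0
    r_endo <- if (any(hit_endo)) max(rs[hit_endo]) else 0
    max(r_epi - r_endo, 0)
  }, numeric(1))
  mean(thick) * pixel_spacing
}

#' Left-ventricular metrics from an ED/ES mask stack
#'
#' Computes EDV, ESV, EF, LV mass and end-diastolic/end-systolic wall
#' thickness from per-slice endocardial and epicardial masks at
#' end-diastole and end-systole. Mass is reported at end-diastole; wall
#' thickness on the mid-ventricular slice.
#'
#' @param stack A list with `endo_ed`, `epi_ed`, `endo_es`, `epi_es` (lists
#'   of per-slice masks), `pixel_spacing`, `slice_thickness` (mm) and
#'   optionally `body_weight` (g), e.g. from [make_cine_phantom()].
#' @param density Myocardial density (mg/uL).
#' @param n_rays Rays for wall thickness.
#' @return A one-row tibble: `edv_ul`, `esv_ul`, `ef_pct`, `lv_mass_mg`,
#'   `edwt_mm`, `eswt_mm`.
#' @export
lv_metrics <- function(stack, density = 1.05, n_rays = 24) {
  sp <- stack$pixel_spacing; th <- stack$slice_thickness
  edv <- cavity_volume(stack$endo_ed, sp, th)
  esv <- cavity_volume(stack$endo_es, sp, th)
  mid <- ceiling(length(stack$endo_ed) / 2)
  tibble::tibble(
    edv_ul = edv,
    esv_ul = esv,
    ef_pct = ejection_fraction(edv, esv),
    lv_mass_mg = lv_mass(stack$endo_ed, stack$epi_ed, sp, th, density),
    edwt_mm = wall_thickness(stack$endo_ed[[mid]], stack$epi_ed[[mid]], sp,
                             n_rays),
    eswt_mm = wall_thickness(stack$endo_es[[mid]], stack$epi_es[[mid]], sp,
                             n_rays)
  )
}
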