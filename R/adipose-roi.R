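#' Threshold an adipose depot ROI by PDFF
#'
#' Applies the fat-dominance rule to a manually segmented depot: voxels with
#' PDFF below the threshold are excluded (so voxels at exactly the threshold
#' are kept), and the depot is flagged as excluded from analysis when fewer
#' than `min_voxels` survive. `NaN` map voxels (failed fits) are dropped.
#'
#' @param mask Logical/0-1 matrix marking the depot voxels.
#' @param pdff_map Numeric matrix of PDFF values, same geometry as `mask`.
#' @param threshold PDFF keep threshold; default 0.50.
#' @param min_voxels Minimum surviving voxels before the depot is excluded;
#'   default 30. Use `0` for depots (myocardium) not subject to the rule.
#' @return A list with `kept` (logical matrix of surviving voxels),
#'   `n_initial`, `n_kept`, and `excluded`.
#' @examples
#' m <- matrix(TRUE, 2, 3)
#' p <- matrix(c(0.2, 0.4, 0.5, 0.6, 0.9, NaN), 2, 3)
#' threshold_depot(m, p)$n_kept  # 3
#' @export
threshold_depot <- function(mask, pdff_map, threshold = 0.50,
                            min_voxels = 30) {
  mask <- as.logical(mask)
  if (length(mask) != length(pdff_map))
    stop("mask and pdff_map geometry mismatch", call. = FALSE)
  dim(mask) <- dim(pdff_map)
  kept <- mask & !is.na(pdff_map) & !is.nan(pdff_map) & pdff_map >= threshold
  n_kept <- sum(kept)
  list(kept = kept, n_initial = sum(mask), n_kept = n_kept,
       excluded = n_kept < min_voxels)
}

#' Summarise a depot over its thresholded ROI
#'
#' Arithmetic means of the parametric maps over the surviving voxels of a
#' depot, with the voxel counts and exclusion flag from [threshold_depot()].
#'
#' @param depot Depot label string (e.g. `"EAT"`, `"SAT"`, `"myocardium"`).
#' @param thresholded Result of [threshold_depot()].
#' @param fit A `fatwater_fit` object (or any list of map matrices with
#'   elements `pdff`, `t1`, `sfa`, `mufa`, `pufa`).
#' @return A one-row tibble: `depot`, `n_voxels_initial`, `n_voxels_kept`,
#'   `excluded`, `mean_pdff`, `mean_t1`, `mean_sfa`, `mean_mufa`,
#'   `mean_pufa`. Means are `NA` when no voxel survives.
#' @export
depot_summary <- function(depot, thresholded, fit) {
  kept <- thresholded$kept
  mean_of <- function(map) {
    v <- map[kept]
    v <- v[is.finite(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  tibble::tibble(
    depot = depot,
    n_voxels_initial = thresholded$n_initial,
    n_voxels_kept = thresholded$n_kept,
    excluded = thresholded$excluded,
    mean_pdff = mean_of(fit$pdff),
    mean_t1 = mean_of(fit$t1),
    mean_sfa = mean_of(fit$sfa),
    mean_mufa = mean_of(fit$mufa),
    mean_pufa = mean_of(fit$pufa)
  )
}

#' Summarise all depots of a labelled segmentation
#'
#' Convenience wrapper running [threshold_depot()] + [depot_summary()] for
#' each label of an integer segmentation (0 background, 1 EAT, 2 SAT,
#' 3 myocardium by default). The PDFF threshold and 30-voxel rule apply to
#' the adipose depots only; the myocardial summary is an unthresholded mean.
#'
#' @param labels Integer label matrix.
#' @param fit A `fatwater_fit` object (or compatible list of maps).
#' @param label_map Named integer vector mapping depot names to label values.
#' @param adipose Names of labels subject to the PDFF threshold and voxel
#'   minimum.
#' @inheritParams threshold_depot
#' @return A tibble with one row per depot (see [depot_summary()]).
#' @export
summarise_depots <- function(labels, fit,
                             label_map = c(EAT = 1L, SAT = 2L,
                                           myocardium = 3L),
                             adipose = c("EAT", "SAT"),
                             threshold = 0.50, min_voxels = 30) {
  purrr::map_dfr(names(label_map), function(nm) {
    mask <- labels == label_map[[nm]]
    if (nm %in% adipose) {
      th <- threshold_depot(mask, fit$pdff, threshold, min_voxels)
    } else {
      th <- threshold_depot(mask, fit$pdff, threshold = 0, min_voxels = 0)
    }
    depot_summary(nm, th, fit)
  })
}

#' EAT SFA index
#'
#' The epicardial depot's saturated fraction referenced to the subcutaneous
#' depot's, `eat_sfa / sat_sfa`. SAT serves as the metabolically healthier
#' reference depot; the index is missing when the SAT value is unavailable,
#' non-positive, or the SAT depot was excluded.
#'
#' @param eat_sfa,sat_sfa Mean SFA fractions of the two depots.
#' @param sat_excluded Was the SAT depot excluded by the voxel-count rule?
#' @return The ratio, or `NA` when undefined.
#' @examples
#' sfa_index(0.48, 0.40)  # 1.2
#' @export
sfa_index <- function(eat_sfa, sat_sfa, sat_excluded = FALSE) {
  if (isTRUE(sat_excluded) || is.na(sat_sfa) || sat_sfa <= 0 ||
      is.na(eat_sfa))
    return(NA_real_)
  eat_sfa / sat_sfa
}

#' EAT volume index from end-diastolic masks
#'
#' Sums the epicardial adipose pixels over all end-diastolic cine slices,
#' converts to volume via the per-pixel volume (in-plane spacing squared
#' times slice thickness; 0.2 x 0.2 x 1.0 mm gives 0.038 mm^3/pixel at the
#' default cine geometry), and indexes the volume in microliters to body
#' weight in grams.
#'
#' @param eat_masks List of logical/0-1 matrices, one per slice, or a single
#'   matrix.
#' @param pixel_spacing In-plane pixel spacing (mm).
#' @param slice_thickness Slice thickness (mm).
#' @param body_weight Body weight (g).
#' @return A one-row tibble: `n_pixels`, `pixel_volume_mm3`, `volume_ul`,
#'   `body_weight_g`, `volume_index_ul_per_g`.
#' @examples
#' eat_volume_index(matrix(1, 10, 10), 0.2, 1.0, body_weight = 40)
#' @export
eat_volume_index <- function(eat_masks, pixel_spacing, slice_thickness,
                             body_weight) {
  stopifnot(pixel_spacing > 0, slice_thickness > 0, body_weight > 0)
  if (is.matrix(eat_masks)) eat_masks <- list(eat_masks)
  n_pixels <- sum(vapply(eat_masks, function(m) sum(m != 0), numeric(1)))
  pixel_volume <- pixel_spacing^2 * slice_thickness
  volume <- n_pixels * pixel_volume                    # 1 mm^3 = 1 uL
  tibble::tibble(
    n_pixels = n_pixels,
    pixel_volume_mm3 = pixel_volume,
    volume_ul = volume,
    body_weight_g = body_weight,
    volume_index_ul_per_g = volume / body_weight
  )
}
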