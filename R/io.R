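#' Read and write parametric maps as NIfTI
#'
#' Maps are stored as single-volume NIfTI files with the in-plane pixel
#' spacing and slice thickness in `pixdim`; complex stacks are stored as
#' paired real/imaginary files. Writing then reading reproduces the array
#' bitwise.
#'
#' @param map Numeric matrix (or array).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param pixel_spacing In-plane spacing (mm).
#' @param slice_thickness Slice thickness (mm).
#' @return `write_nifti_map()` returns `path` invisibly; `read_nifti_map()`
#'   returns the array with attributes `pixel_spacing` and
#'   `slice_thickness`.
#' @export
write_nifti_map <- function(map, path, pixel_spacing = 0.2,
                            slice_thickness = 1.0) {
  img <- RNifti::asNifti(map)
  nd <- length(dim(map))
  pd <- c(pixel_spacing, pixel_spacing, slice_thickness, rep(1, nd))[1:max(nd, 3)]
  RNifti::pixdim(img) <- pd[seq_len(nd)]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_map
#' @export
read_nifti_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  out <- as.array(img)
  pd <- RNifti::pixdim(img)
  attr(out, "pixel_spacing") <- pd[1]
  attr(out, "slice_thickness") <- if (length(pd) >= 3) pd[3] else NA_real_
  out
}

#' Read and write an acquisition schedule JSON sidecar
#'
#' The sidecar stores the TE/TI construction (`n_te`, `te1_s`, `dte_s`,
#' `n_ti`, `ti1_s`, `rr_s`), the flip angle and the spectrometer frequency.
#' Missing required fields raise an explicit parse error naming the field.
#'
#' @param path JSON file path.
#' @return `read_schedule_json()` returns an [acquisition_schedule()];
#'   `write_schedule_json()` returns `path` invisibly.
#' @export
read_schedule_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("n_te", "te1_s", "dte_s", "n_ti", "ti1_s", "rr_s", "flip_deg",
            "f0_hz")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("schedule sidecar ", path, " is missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  acquisition_schedule(n_te = x$n_te, te1 = x$te1_s, dte = x$dte_s,
                       n_ti = x$n_ti, ti1 = x$ti1_s, rr = x$rr_s,
                       flip_deg = x$flip_deg, f0 = x$f0_hz)
}

#' @rdname read_schedule_json
#' @param schedule An [acquisition_schedule()] built parametrically (its
#'   TE/TI grids must be arithmetic).
#' @export
write_schedule_json <- function(schedule, path) {
  te <- schedule$te_list; ti <- schedule$ti_list
  jsonlite::write_json(list(
    n_te = length(te), te1_s = te[1],
    dte_s = if (length(te) > 1) te[2] - te[1] else 0,
    n_ti = length(ti), ti1_s = ti[1], rr_s = schedule$rr,
    flip_deg = schedule$flip_deg, f0_hz = schedule$f0
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write long-format cohort tables
#'
#' Cohort tables are CSV in long format with columns `animal_id`, `group`,
#' `variable`, `value`. The write-read roundtrip reproduces the table.
#'
#' @param cohort Tibble in long format.
#' @param path CSV path.
#' @return `read_cohort_csv()` returns a tibble; `write_cohort_csv()`
#'   returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  need <- c("animal_id", "group", "variable", "value")
  if (!all(need %in% names(cohort)))
    stop("cohort table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  readr::write_csv(cohort[, need], path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    animal_id = readr::col_character(), group = readr::col_character(),
    variable = readr::col_character(), value = readr::col_double()))
}

#' Run the full synthetic-study pipeline
#'
#' Generates the five synthetic input modalities from one seed, runs every
#' analysis stage (fat-water-T1 fitting + depot summaries, ASL perfusion,
#' DENSE strain, cine LV metrics, cohort statistics), writes the per-stage
#' CSV/JSON outputs under `out_dir`, and records a manifest (seed, config
#' hash, package version, per-stage status). A stage failure is recorded in
#' the manifest and its dependents are skipped; rerunning with the same
#' seed and config reproduces identical outputs.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed driving all randomness.
#' @param config Named list of stage parameters; defaults via
#'   [pipeline_config()].
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(out_dir, seed, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, config = config,
                   package_version = as.character(utils::packageVersion("cmrquant")),
                   stages = list())
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))
  results <- list()

  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       message = conditionMessage(res))
      NULL
    } else {
      manifest$stages[[name]] <<- list(status = "ok")
      results[[name]] <<- res
      res
    }
  }

  fw <- run_stage("fatwater", function() {
    sched <- acquisition_schedule(n_ti = config$fw_n_ti, rr = config$fw_rr)
    ph <- make_fatwater_phantom(size = config$fw_size, schedule = sched,
                                snr = config$fw_snr, seed = seed)
    fit <- fit_stack(ph, ph$mask)
    labels <- matrix(0L, config$fw_size, config$fw_size)
    labels[ph$region_map == 3] <- 1L   # EAT-like
    labels[ph$region_map == 4] <- 2L   # pure-fat region standing in for SAT
    labels[ph$region_map == 2] <- 3L   # myocardium-like
    depots <- summarise_depots(labels, fit,
                               threshold = config$pdff_threshold,
                               min_voxels = config$min_voxels)
    readr::write_csv(depots, file.path(out_dir, "depot_summaries.csv"))
    write_nifti_map(fit$pdff, file.path(out_dir, "pdff.nii.gz"))
    write_nifti_map(fit$t1, file.path(out_dir, "t1.nii.gz"))
    list(phantom = ph, fit = fit, depots = depots)
  })

  run_stage("asl", function() {
    rest <- make_asl_phantom(matrix(config$asl_rest_mbf, 10, 10))
    stress <- make_asl_phantom(matrix(config$asl_stress_mbf, 10, 10))
    study <- perfusion_study(rest$t1_selective, rest$t1_global,
                             stress$t1_selective, stress$t1_global)
    readr::write_csv(study, file.path(out_dir, "perfusion.csv"))
    study
  })

  run_stage("dense", function() {
    ph <- make_dense_phantom(es_strain = config$dense_es_strain,
                             period = config$dense_period)
    crv <- analyse_dense(ph)
    readr::write_csv(tidy(crv), file.path(out_dir, "strain_curve.csv"))
    readr::write_csv(glance(crv), file.path(out_dir, "strain_summary.csv"))
    crv
  })

  run_stage("cine", function() {
    ph <- make_cine_phantom()
    lv <- lv_metrics(ph)
    vol <- eat_volume_index(ph$epi_ed[[1]] & !ph$endo_ed[[1]],
                            ph$pixel_spacing, ph$slice_thickness,
                            ph$body_weight)
    readr::write_csv(lv, file.path(out_dir, "lv_metrics.csv"))
    readr::write_csv(vol, file.path(out_dir, "eat_volume.csv"))
    list(lv = lv, eat_volume = vol)
  })

  run_stage("cohort", function() {
    ch <- make_cohort(seed = seed)
    write_cohort_csv(ch$cohort, file.path(out_dir, "cohort.csv"))
    cmp <- compare_groups(dplyr::filter(ch$cohort, variable == "mpr"),
                          value, group)
    auc <- ch$gtt |>
      dplyr::group_by(animal_id, group) |>
      dplyr::summarise(auc = gtt_auc(times = time, glucose = glucose),
                       .groups = "drop")
    readr::write_csv(auc, file.path(out_dir, "gtt_auc.csv"))
    jsonlite::write_json(as.list(cmp), file.path(out_dir, "group_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
    list(comparison = cmp, gtt_auc = auc)
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(c(results, list(manifest = manifest)))
}

#' @rdname run_pipeline
#' @param ... Overrides of the default stage parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fw_size = 8, fw_n_ti = 12, fw_rr = 0.25, fw_snr = NULL,
    pdff_threshold = 0.5, min_voxels = 5,
    asl_rest_mbf = 5, asl_stress_mbf = 10,
    dense_es_strain = -0.15, dense_period = 0.12
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  utils::modifyList(cfg, dots)
}
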