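#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted fat-water stack into a per-voxel tibble
#'
#' @param x A `fatwater_fit` from [fit_stack()].
#' @param ... Unused.
#' @return A tibble with one row per in-mask voxel: `row`, `col`, the
#'   fitted parameters and derived maps, and the `ok` quality flag.
#' @method tidy fatwater_fit
#' @export
tidy.fatwater_fit <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE)
  maps <- c("pdff", "t1", "sfa", "mufa", "pufa", "psi", "r2star", "beta",
            "W", "F", "ndb", "nmidb", "resnorm")
  out <- tibble::tibble(row = idx[, 1], col = idx[, 2])
  for (m in maps) out[[m]] <- x[[m]][idx]
  out$ok <- x$ok[idx]
  out
}

#' Summarise a fitted fat-water stack
#'
#' @param x A `fatwater_fit`.
#' @param ... Unused.
#' @return A one-row tibble: voxel counts, flagged-voxel count, and
#'   in-mask means of PDFF, T1 and SFA.
#' @method glance fatwater_fit
#' @export
glance.fatwater_fit <- function(x, ...) {
  v <- tidy(x)
  tibble::tibble(
    n_voxels = nrow(v),
    n_flagged = sum(!v$ok),
    mean_pdff = mean(v$pdff, na.rm = TRUE),
    mean_t1 = mean(v$t1, na.rm = TRUE),
    mean_sfa = mean(v$sfa, na.rm = TRUE),
    total_resnorm = sum(v$resnorm, na.rm = TRUE)
  )
}

#' @method tidy strain_curve
#' @export
tidy.strain_curve <- function(x, ...) {
  tibble::tibble(time = x$time, ell = x$ell)
}

#' Summarise a strain curve
#'
#' @param x A `strain_curve` from [gls_and_pdsr()] or [analyse_dense()].
#' @param ... Unused.
#' @return A one-row tibble: `gls` (end-systolic global longitudinal
#'   strain), `es_strain`, `es_frame`, `pdsr` (1/s).
#' @method glance strain_curve
#' @export
glance.strain_curve <- function(x, ...) {
  tibble::tibble(gls = attr(x, "gls"),
                 es_strain = attr(x, "es_strain"),
                 es_frame = attr(x, "es_frame"),
                 pdsr = attr(x, "pdsr"))
}

#' Plot a parametric map from a fitted fat-water stack
#'
#' @param object A `fatwater_fit`.
#' @param map Which map to draw (e.g. `"pdff"`, `"t1"`, `"sfa"`).
#' @param ... Unused.
#' @return A ggplot raster of the requested map.
#' @method autoplot fatwater_fit
#' @export
autoplot.fatwater_fit <- function(object, map = "pdff", ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data[[map]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = map) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a strain-time curve
#'
#' Marks the end-systolic frame and annotates the peak diastolic strain
#' rate.
#'
#' @param object A `strain_curve`.
#' @param ... Unused.
#' @return A ggplot line plot of global longitudinal strain over time.
#' @method autoplot strain_curve
#' @export
autoplot.strain_curve <- function(object, ...) {
  g <- glance(object)
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$ell)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = df$time[g$es_frame],
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = "time (s)", y = "global longitudinal strain",
      subtitle = sprintf("GLS = %.3f, PDSR = %s s⁻¹", g$gls,
                         ifelse(is.na(g$pdsr), "NA",
                                sprintf("%.2f", g$pdsr)))) +
    ggplot2::theme_minimal()
}

#' Plot per-animal GTT curves by group
#'
#' @param gtt Tibble with columns `animal_id`, `group`, `time`, `glucose`
#'   (e.g. from [make_cohort()]).
#' @return A ggplot of glucose-versus-time curves, one line per animal,
#'   coloured by group.
#' @export
plot_gtt <- function(gtt) {
  ggplot2::ggplot(gtt, ggplot2::aes(x = .data$time, y = .data$glucose,
                                    group = .data$animal_id,
                                    colour = .data$group)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "time (min)", y = "glucose (mg/dL)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
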