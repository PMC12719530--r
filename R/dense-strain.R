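#' Quality-guided 2-D phase unwrapping
#'
#' Region-growing unwrap within a mask: starting from the highest-quality
#' seed (ties broken toward the lowest linear index), pixels adjacent to the
#' solved region are absorbed in decreasing quality order, each adjusted by
#' the integer multiple of 2*pi that brings it within pi of the mean of its
#' already-unwrapped 4-neighbours. Disconnected masks are unwrapped per
#' connected component with a warning; the result is then only defined up to
#' an independent 2*pi multiple per component.
#'
#' @param phase Numeric matrix of wrapped phases in (-pi, pi].
#' @param mask Logical/0-1 matrix; only in-mask pixels are unwrapped
#'   (default: all).
#' @param quality Numeric matrix guiding the growth order (e.g. signal
#'   magnitude). Constant by default, which reduces to deterministic
#'   breadth-first growth.
#' @return Matrix of unwrapped phases; out-of-mask pixels are `NA`.
#' @export
unwrap_phase <- function(phase, mask = NULL, quality = NULL) {
  nr <- nrow(phase); nc <- ncol(phase)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  mask <- matrix(as.logical(mask), nr, nc)
  if (is.null(quality)) quality <- matrix(1, nr, nc)
  stopifnot(all(dim(quality) == dim(phase)))
  out <- matrix(NA_real_, nr, nc)
  comp <- connected_components(mask)
  n_comp <- max(comp, 0)
  if (n_comp > 1)
    warning("mask is disconnected; unwrapping each component independently")
  for (cc in seq_len(n_comp)) {
    sel <- comp == cc
    out[sel] <- unwrap_component(phase, sel, quality)[sel]
  }
  out
}

# 4-connected component labelling by flood fill, deterministic order
connected_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- matrix(0L, nr, nc)
  lab <- 0L
  for (start in which(mask)) {
    if (comp[start] != 0L) next
    lab <- lab + 1L
    stack <- start
    comp[start] <- lab
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- (p - 1L) %% nr + 1L; j <- (p - 1L) %/% nr + 1L
      for (q in neighbours4(i, j, nr, nc)) {
        if (mask[q] && comp[q] == 0L) {
          comp[q] <- lab
          stack <- c(stack, q)
        }
      }
    }
  }
  comp
}

neighbours4 <- function(i, j, nr, nc) {
  q <- integer(0)
  if (i > 1L)  q <- c(q, (j - 1L) * nr + i - 1L)
  if (i < nr)  q <- c(q, (j - 1L) * nr + i + 1L)
  if (j > 1L)  q <- c(q, (j - 2L) * nr + i)
  if (j < nc)  q <- c(q, j * nr + i)
  q
}

unwrap_component <- function(phase, mask, quality) {
  nr <- nrow(phase); nc <- ncol(phase)
  out <- matrix(NA_real_, nr, nc)
  idx_mask <- which(mask)
  # seed: highest quality, ties -> lowest linear index
  seed <- idx_mask[order(-quality[idx_mask], idx_mask)][1]
  out[seed] <- phase[seed]
  solved <- matrix(FALSE, nr, nc); solved[seed] <- TRUE
  frontier <- rep(FALSE, nr * nc)
  add_frontier <- function(p) {
    i <- (p - 1L) %% nr + 1L; j <- (p - 1L) %/% nr + 1L
    for (q in neighbours4(i, j, nr, nc))
      if (mask[q] && !solved[q]) frontier[q] <<- TRUE
  }
  add_frontier(seed)
  while (any(frontier)) {
    cand <- which(frontier)
    p <- cand[order(-quality[cand], cand)][1]
    frontier[p] <- FALSE
    i <- (p - 1L) %% nr + 1L; j <- (p - 1L) %/% nr + 1L
    nb <- neighbours4(i, j, nr, nc)
    ref <- mean(out[nb[solved[nb]]])
    k <- round((ref - phase[p]) / (2 * pi))
    out[p] <- phase[p] + 2 * pi * k
    solved[p] <- TRUE
    add_frontier(p)
  }
  out
}

#' Displacement from displacement-encoded phase
#'
#' The defining relation of displacement encoding: tissue displacement along
#' the encoded direction is the (unwrapped) phase divided by `2*pi*ke`, with
#' `ke` the encoding frequency in cycles/mm.
#'
#' @param phase Unwrapped phase (rad): matrix or vector.
#' @param ke Displacement-encoding frequency (cycles/mm), > 0.
#' @return Displacement in mm, same shape as `phase`.
#' @examples
#' displacement_from_phase(pi, ke = 1)  # 0.5 mm
#' @export
displacement_from_phase <- function(phase, ke) {
  stopifnot(ke > 0)
  phase / (2 * pi * ke)
}

#' Lagrangian strain tensor from a reference-frame displacement field
#'
#' Computes the deformation gradient `F = I + grad(u)` by mask-aware finite
#' differences on the reference grid (central where both neighbours are in
#' the mask, one-sided at mask edges) and the Green-Lagrange strain
#' `E = (F'F - I)/2`.
#'
#' @param ux,uy Displacement components (mm) on the reference grid
#'   (matrices; rows = x index, cols = y index).
#' @param mask Logical matrix of myocardial pixels.
#' @param spacing Grid spacing (mm/pixel).
#' @return A list of matrices `exx`, `exy`, `eyy` (strain components) and
#'   `flagged` (logical: pixels where a gradient direction had no in-mask
#'   neighbour and the local strain is undefined).
#' @export
strain_from_displacement <- function(ux, uy, mask = NULL, spacing = 1) {
  nr <- nrow(ux); nc <- ncol(ux)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  mask <- matrix(as.logical(mask), nr, nc)
  g <- function(u) masked_gradient(u, mask, spacing)
  gx <- g(ux)  # dux/dx, dux/dy
  gy <- g(uy)
  f11 <- 1 + gx$dx; f12 <- gx$dy
  f21 <- gy$dx;     f22 <- 1 + gy$dy
  exx <- (f11^2 + f21^2 - 1) / 2
  eyy <- (f12^2 + f22^2 - 1) / 2
  exy <- (f11 * f12 + f21 * f22) / 2
  flagged <- mask & (gx$flag | gy$flag)
  exx[!mask] <- NA; eyy[!mask] <- NA; exy[!mask] <- NA
  list(exx = exx, exy = exy, eyy = eyy, flagged = flagged)
}

# per-direction finite differences restricted to the mask
masked_gradient <- function(u, mask, spacing) {
  nr <- nrow(u); nc <- ncol(u)
  dx <- matrix(NA_real_, nr, nc); dy <- matrix(NA_real_, nr, nc)
  flag <- matrix(FALSE, nr, nc)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j]) next
    up <- i > 1 && mask[i - 1, j]
    dn <- i < nr && mask[i + 1, j]
    dx[i, j] <- if (up && dn) (u[i + 1, j] - u[i - 1, j]) / (2 * spacing)
      else if (dn) (u[i + 1, j] - u[i, j]) / spacing
      else if (up) (u[i, j] - u[i - 1, j]) / spacing
      else { flag[i, j] <- TRUE; 0 }
    lt <- j > 1 && mask[i, j - 1]
    rt <- j < nc && mask[i, j + 1]
    dy[i, j] <- if (lt && rt) (u[i, j + 1] - u[i, j - 1]) / (2 * spacing)
      else if (rt) (u[i, j + 1] - u[i, j]) / spacing
      else if (lt) (u[i, j] - u[i, j - 1]) / spacing
      else { flag[i, j] <- TRUE; 0 }
  }
  list(dx = dx, dy = dy, flag = flag)
}

#' Wall-tangent (longitudinal) strain component
#'
#' Projects the Lagrangian strain tensor onto the local wall-tangent
#' direction, taken perpendicular to the radial direction from the wall
#' centroid — the arc-length tangent of the mid-wall contour for an
#' annular wall.
#'
#' @param strain Result of [strain_from_displacement()].
#' @param mask Logical myocardial mask.
#' @param centroid Optional `c(x, y)` pixel coordinates of the wall centre;
#'   default is the mask centroid.
#' @return Matrix of tangential strain values (`NA` outside the mask), with
#'   attribute `theta` giving each pixel's angular position.
#' @export
tangential_strain <- function(strain, mask, centroid = NULL) {
  mask <- matrix(as.logical(mask), nrow(strain$exx), ncol(strain$exx))
  idx <- which(mask, arr.ind = TRUE)
  if (is.null(centroid)) centroid <- c(mean(idx[, 1]), mean(idx[, 2]))
  th <- atan2(idx[, 2] - centroid[2], idx[, 1] - centroid[1])
  tx <- -sin(th); ty <- cos(th)
  ell <- matrix(NA_real_, nrow(mask), ncol(mask))
  ell[idx] <- tx^2 * strain$exx[idx] + 2 * tx * ty * strain$exy[idx] +
    ty^2 * strain$eyy[idx]
  theta <- matrix(NA_real_, nrow(mask), ncol(mask))
  theta[idx] <- th
  attr(ell, "theta") <- theta
  ell
}

#' Global longitudinal strain curve and peak diastolic strain rate
#'
#' Builds the global strain-time curve as the mean over wall segments of the
#' longitudinal strain, identifies the end-systolic strain as the signed
#' extremum, and computes the peak diastolic strain rate (PDSR) as the
#' maximum time derivative after the end-systolic frame — positive during
#' recovery of negative (shortening) strain. Derivatives are central
#' differences (one-sided at the curve ends); no temporal smoothing is
#' applied unless requested.
#'
#' @param curves Numeric matrix (frames x segments) of per-segment
#'   longitudinal strain, or a vector (single global curve). The reference
#'   frame (strain 0) is frame 1.
#' @param frame_interval Time between frames (s).
#' @param smooth Apply a 3-point moving average before differentiating?
#'   Default `FALSE`.
#' @return An object of class `strain_curve`: a tibble with columns `time`,
#'   `ell`, plus attributes accessed via [glance.strain_curve()]:
#'   `es_strain`, `es_frame`, `pdsr` (1/s; `NA` when the curve has no
#'   recovery phase), `gls` (the end-systolic global strain, the
#'   conventional GLS report).
#' @examples
#' tt <- seq(0, 0.12, by = 0.004)
#' crv <- gls_and_pdsr(-0.15 * sin(pi * tt / 0.12)^2, frame_interval = 0.004)
#' glance(crv)
#' @export
gls_and_pdsr <- function(curves, frame_interval, smooth = FALSE) {
  if (is.matrix(curves)) ell <- rowMeans(curves) else ell <- as.numeric(curves)
  n <- length(ell)
  if (n < 3) stop("need at least 3 frames", call. = FALSE)
  if (smooth && n >= 3)
    ell <- stats::filter(ell, rep(1 / 3, 3), sides = 2) |>
      (\(x) { x[1] <- ell[1]; x[n] <- ell[n]; as.numeric(x) })()
  time <- (seq_len(n) - 1) * frame_interval
  es_frame <- which.max(abs(ell))
  es_strain <- ell[es_frame]
  d <- strain_rate(ell, frame_interval)
  pdsr <- NA_real_
  if (es_frame < n) {
    cand <- d[(es_frame + 1):n]
    if (any(cand > 0)) pdsr <- max(cand)
  }
  out <- tibble::tibble(time = time, ell = ell)
  attr(out, "es_strain") <- es_strain
  attr(out, "es_frame") <- es_frame
  attr(out, "pdsr") <- pdsr
  attr(out, "gls") <- es_strain
  class(out) <- c("strain_curve", class(out))
  out
}

strain_rate <- function(ell, dt) {
  n <- length(ell)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (ell[3:n] - ell[1:(n - 2)]) / (2 * dt)
  d[1] <- (ell[2] - ell[1]) / dt
  d[n] <- (ell[n] - ell[n - 1]) / dt
  d
}

#' Full DENSE analysis of a phase-image series
#'
#' Runs the complete strain chain on a displacement-encoded series:
#' per-frame, per-direction phase unwrapping, phase-to-displacement
#' conversion, Lagrangian strain, wall-tangent projection, segmental
#' averaging, and the GLS/PDSR summary.
#'
#' @param series A list with `phase_x`, `phase_y` (lists of wrapped phase
#'   matrices, one per frame), `ke` (cycles/mm), `frame_interval` (s),
#'   `mask` (reference-frame myocardial mask), `spacing` (mm/pixel), and
#'   optionally `magnitude` (quality maps for unwrapping), e.g. from
#'   [make_dense_phantom()].
#' @param n_segments Number of angular wall segments averaged into the
#'   global curve. Default 6.
#' @return A `strain_curve` (see [gls_and_pdsr()]).
#' @export
analyse_dense <- function(series, n_segments = 6) {
  mask <- series$mask
  n_frames <- length(series$phase_x)
  seg_curves <- matrix(0, n_frames, n_segments)
  idx <- which(mask, arr.ind = TRUE)
  centroid <- c(mean(idx[, 1]), mean(idx[, 2]))
  th <- atan2(idx[, 2] - centroid[2], idx[, 1] - centroid[1])
  seg_of <- pmin(floor((th + pi) / (2 * pi) * n_segments) + 1, n_segments)
  for (f in seq_len(n_frames)) {
    q <- if (!is.null(series$magnitude)) series$magnitude[[f]] else NULL
    px <- unwrap_phase(series$phase_x[[f]], mask, q)
    py <- unwrap_phase(series$phase_y[[f]], mask, q)
    ux <- displacement_from_phase(px, series$ke)
    uy <- displacement_from_phase(py, series$ke)
    ux[!mask] <- 0; uy[!mask] <- 0
    st <- strain_from_displacement(ux, uy, mask, series$spacing)
    ell <- tangential_strain(st, mask, centroid)
    vals <- ell[idx]
    seg_curves[f, ] <- vapply(seq_len(n_segments), function(s) {
      v <- vals[seg_of == s]
      if (length(v)) mean(v, na.rm = TRUE) else NA_real_
    }, numeric(1))
  }
  gls_and_pdsr(seg_curves, series$frame_interval)
}
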