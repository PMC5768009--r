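#' Gamma-evaluation criteria
#'
#' Global-normalization gamma criteria: dose tolerance as a percentage of
#' the normalization dose, distance-to-agreement in mm, and a low-dose
#' threshold (percentage of the normalization dose) below which points are
#' excluded from the pass rate.
#'
#' @param dose_tolerance Dose difference tolerance (% of normalization).
#' @param dta Distance-to-agreement (mm).
#' @param low_dose_threshold Threshold (% of normalization) masking
#'   low-dose points, in `(0, 100)`.
#' @param normalization `"max"` (the reference maximum, i.e. the Bragg-peak
#'   dose for mono-energy fields), `"isocenter"`, or an explicit positive
#'   value.
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_tolerance = 2, dta = 2,
                           low_dose_threshold = 20,
                           normalization = "max") {
  stopifnot(dose_tolerance > 0, dta > 0,
            low_dose_threshold > 0, low_dose_threshold < 100)
  if (is.numeric(normalization)) {
    stopifnot(normalization > 0)
  } else {
    normalization <- match.arg(normalization, c("max", "isocenter"))
  }
  structure(list(dose_tolerance = dose_tolerance, dta = dta,
                 low_dose_threshold = low_dose_threshold,
                 normalization = normalization),
            class = "gamma_criteria")
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf("Gamma criteria: %g%% / %g mm, low-dose threshold %g%%, normalization: %s\n",
              x$dose_tolerance, x$dta, x$low_dose_threshold,
              if (is.numeric(x$normalization))
                sprintf("%g", x$normalization) else x$normalization))
  invisible(x)
}

#' 1-D profile sample extracted from a dose grid
#' @keywords internal
profile_sample <- function(axis, coordinates, values) {
  stopifnot(axis %in% c("depth", "lateral-x", "lateral-y"),
            length(coordinates) == length(values),
            !is.unsorted(coordinates, strictly = TRUE))
  structure(list(axis = axis, coordinates = coordinates, values = values),
            class = "profile_sample")
}

#' @export
print.profile_sample <- function(x, ...) {
  cat(sprintf("%s profile: %d samples on [%g, %g], max %g\n", x$axis,
              length(x$coordinates), min(x$coordinates), max(x$coordinates),
              max(x$values)))
  invisible(x)
}

#' @export
plot.profile_sample <- function(x, ...) {
  graphics::plot(x$coordinates, x$values, type = "l",
                 xlab = if (x$axis == "depth") "depth (mm)" else
                   "lateral position (mm)",
                 ylab = "dose (per particle)", ...)
  invisible(x)
}

# nearest voxel index along one axis for a lab coordinate
.vox_index <- function(grid, axis, coord) {
  i <- floor((coord - grid$origin[axis]) / grid$spacing[axis]) + 1
  if (i < 1 || i > grid$n[axis]) stop("position outside grid")
  as.integer(i)
}

#' Extract an absolute depth-dose (ADD) profile
#'
#' The 1-D depth profile through the voxel column at the given lateral
#' position (by default the field centre). Values are dose per incident
#' particle as scored by the run.
#'
#' @param dose A `dose_grid` from [run_simulation()].
#' @param lateral_position `(x, y)` position (mm) of the sampled column.
#' @return A `profile_sample` (axis `"depth"`, coordinates in mm).
#' @export
extract_add <- function(dose, lateral_position = c(0, 0)) {
  g <- dose$grid
  i <- .vox_index(g, 1, lateral_position[1])
  j <- .vox_index(g, 2, lateral_position[2])
  zc <- g$origin[3] + (seq_len(g$n[3]) - 0.5) * g$spacing[3]
  profile_sample("depth", zc, dose$dose[i, j, ])
}

#' Extract an off-center-ratio (OCR) lateral profile
#'
#' The 1-D lateral profile (along x, through the field centre in y) at the
#' given depth, e.g. the middle of the range.
#'
#' @param dose A `dose_grid` from [run_simulation()].
#' @param depth Depth z (mm) of the sampled plane.
#' @param y Lateral y position (mm) of the sampled row.
#' @return A `profile_sample` (axis `"lateral-x"`, coordinates in mm).
#' @export
extract_ocr <- function(dose, depth, y = 0) {
  g <- dose$grid
  k <- .vox_index(g, 3, depth)
  j <- .vox_index(g, 2, y)
  xc <- g$origin[1] + (seq_len(g$n[1]) - 0.5) * g$spacing[1]
  profile_sample("lateral-x", xc, dose$dose[, j, k])
}

#' Extract the central z-x plane of a dose grid
#'
#' @param dose A `dose_grid`.
#' @param y Lateral y position (mm) of the plane.
#' @return A list with `x` (mm), `z` (mm) and the dose `values` matrix
#'   (`length(x)` rows by `length(z)` columns).
#' @export
extract_zx_plane <- function(dose, y = 0) {
  g <- dose$grid
  j <- .vox_index(g, 2, y)
  list(x = g$origin[1] + (seq_len(g$n[1]) - 0.5) * g$spacing[1],
       z = g$origin[3] + (seq_len(g$n[3]) - 0.5) * g$spacing[3],
       values = dose$dose[, j, ])
}

# bilinear resampling of a slice onto new coordinates
.resample_slice <- function(values, x, z, x_new, z_new) {
  tmp <- apply(values, 2, function(col)
    stats::approx(x, col, xout = x_new, rule = 2)$y)
  t(apply(tmp, 1, function(row)
    stats::approx(z, row, xout = z_new, rule = 2)$y))
}

#' 2-D gamma-index map
#'
#' Standard global-normalization gamma: for each evaluated point,
#' `gamma = min over reference points of sqrt((distance/DTA)^2 +
#' (dose difference / tolerance)^2)`, the dose difference being normalized
#' by the criteria's normalization dose. The reference distribution is
#' upsampled by linear interpolation (`interp_factor` points per original
#' spacing) and the minimization is restricted to a search radius of
#' `search_factor * DTA`.
#'
#' Both slices must be supplied with their coordinate vectors; if the grids
#' differ, both are resampled by linear interpolation onto the finer grid
#' over the overlapping region.
#'
#' @param eval_dose,ref_dose 2-D dose matrices (evaluated and reference).
#' @param eval_x,eval_z,ref_x,ref_z Strictly increasing coordinate vectors
#'   (mm) for the matrix rows (x) and columns (z).
#' @param crit A [gamma_criteria()].
#' @param interp_factor Reference upsampling factor (1 disables
#'   interpolation).
#' @param search_factor Search radius in units of DTA (`Inf` searches the
#'   whole reference slice).
#' @return An object of class `gamma_map`: the gamma matrix (`NA` where the
#'   evaluated dose is below the low-dose threshold), the evaluated dose,
#'   coordinates, criteria and normalization value.
#' @export
gamma_index_2d <- function(eval_dose, ref_dose, eval_x, eval_z,
                           ref_x = eval_x, ref_z = eval_z,
                           crit = gamma_criteria(), interp_factor = 10,
                           search_factor = 3) {
  stopifnot(is.matrix(eval_dose), is.matrix(ref_dose),
            nrow(eval_dose) == length(eval_x),
            ncol(eval_dose) == length(eval_z),
            nrow(ref_dose) == length(ref_x),
            ncol(ref_dose) == length(ref_z))
  # resample onto the finer common grid if the grids differ
  if (!isTRUE(all.equal(eval_x, ref_x)) ||
      !isTRUE(all.equal(eval_z, ref_z))) {
    lo_x <- max(min(eval_x), min(ref_x)); hi_x <- min(max(eval_x), max(ref_x))
    lo_z <- max(min(eval_z), min(ref_z)); hi_z <- min(max(eval_z), max(ref_z))
    if (lo_x >= hi_x || lo_z >= hi_z) stop("slices do not overlap")
    dx <- min(min(diff(eval_x)), min(diff(ref_x)))
    dz <- min(min(diff(eval_z)), min(diff(ref_z)))
    gx <- seq(lo_x, hi_x, by = dx)
    gz <- seq(lo_z, hi_z, by = dz)
    eval_dose <- .resample_slice(eval_dose, eval_x, eval_z, gx, gz)
    ref_dose <- .resample_slice(ref_dose, ref_x, ref_z, gx, gz)
    eval_x <- ref_x <- gx
    eval_z <- ref_z <- gz
  }
  norm <- if (is.numeric(crit$normalization)) crit$normalization
  else if (crit$normalization == "max") max(ref_dose)
  else ref_dose[which.min(abs(ref_x - 0)),
                which.min(abs(ref_z - mean(range(ref_z))))]
  if (norm <= 0) stop("normalization dose must be positive")
  radius <- if (is.finite(search_factor)) search_factor * crit$dta else -1
  gam <- gamma_search_cpp(eval_dose, eval_x, eval_z,
                          ref_dose, ref_x, ref_z,
                          crit$dose_tolerance / 100 * norm, crit$dta,
                          as.integer(interp_factor), radius)
  thr <- crit$low_dose_threshold / 100 * norm
  gam[eval_dose < thr] <- NA_real_
  structure(list(gamma = gam, eval_dose = eval_dose,
                 x = eval_x, z = eval_z, crit = crit, norm = norm),
            class = "gamma_map")
}

#' @export
print.gamma_map <- function(x, ...) {
  ev <- x$gamma[!is.na(x$gamma)]
  cat(sprintf("Gamma map: %d x %d points, %d evaluable\n", nrow(x$gamma),
              ncol(x$gamma), length(ev)))
  print(x$crit)
  if (length(ev)) {
    cat(sprintf("  pass rate %.1f%%, mean gamma %.3f, max gamma %.3f\n",
                pass_rate(x), mean(ev), max(ev)))
  }
  invisible(x)
}

#' @export
plot.gamma_map <- function(x, ...) {
  graphics::image(x$z, x$x, t(x$gamma), xlab = "depth z (mm)",
                  ylab = "x (mm)", main = "gamma index",
                  col = grDevices::hcl.colors(64, "Blue-Red"), ...)
  invisible(x)
}

#' Gamma pass rate
#'
#' `100 * (#points with gamma <= 1) / (#points above the low-dose
#' threshold)`.
#'
#' @param gamma_map A `gamma_map` from [gamma_index_2d()].
#' @param crit Optional [gamma_criteria()] overriding the threshold stored
#'   in the map (the gamma values themselves are reused as computed).
#' @return Pass rate in percent.
#' @export
pass_rate <- function(gamma_map, crit = NULL) {
  stopifnot(inherits(gamma_map, "gamma_map"))
  gam <- gamma_map$gamma
  if (!is.null(crit)) {
    thr <- crit$low_dose_threshold / 100 * gamma_map$norm
    gam <- gamma_map$gamma
    gam[gamma_map$eval_dose < thr] <- NA_real_
  }
  ev <- gam[!is.na(gam)]
  if (!length(ev)) stop("no evaluable points above the low-dose threshold")
  100 * sum(ev <= 1) / length(ev)
}
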