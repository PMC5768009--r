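#' Voxel grid geometry
#'
#' Axis-aligned voxel grid in the lab frame (beam axis = +z). Voxel
#' `(i, j, k)` (0-based) spans the half-open box
#' `[origin + i*dx, origin + (i+1)*dx) x ...`.
#'
#' @param n Integer triple of voxel counts `(nx, ny, nz)`, all `>= 1`.
#' @param spacing Numeric triple of voxel widths `(dx, dy, dz)` in mm, `> 0`.
#' @param origin Position (mm) of the corner of voxel `(0, 0, 0)`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(n, spacing, origin = c(0, 0, 0)) {
  n <- as.integer(n)
  stopifnot(length(n) == 3, all(n >= 1),
            length(spacing) == 3, all(spacing > 0),
            length(origin) == 3, all(is.finite(origin)))
  structure(list(n = n, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("Voxel grid: %d x %d x %d voxels, spacing %g x %g x %g mm\n",
              x$n[1], x$n[2], x$n[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) mm, extent (%g, %g, %g) mm\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$n[1] * x$spacing[1], x$n[2] * x$spacing[2],
              x$n[3] * x$spacing[3]))
  invisible(x)
}

#' Water-equivalent-ratio map
#'
#' A voxel grid together with a per-voxel water-equivalent ratio (WER), the
#' factor converting geometric path length in the voxel's medium to the
#' equivalent path length in water.
#'
#' @param grid A [voxel_grid()].
#' @param wer 3-D numeric array (`nx x ny x nz`) of WER values, finite and
#'   `> 0`.
#' @return An object of class `wer_map`.
#' @export
wer_map <- function(grid, wer) {
  stopifnot(inherits(grid, "voxel_grid"),
            is.array(wer), all(dim(wer) == grid$n))
  if (any(!is.finite(wer)) || any(wer <= 0)) {
    stop("WER values must be finite and > 0")
  }
  structure(list(grid = grid, wer = wer), class = "wer_map")
}

#' @export
print.wer_map <- function(x, ...) {
  print(x$grid)
  cat(sprintf("  WER range [%g, %g]\n", min(x$wer), max(x$wer)))
  invisible(x)
}

#' @export
summary.wer_map <- function(object, ...) {
  u <- sort(unique(as.vector(object$wer)))
  cat("WER map summary\n")
  print(object$grid)
  if (length(u) <= 8) {
    cat("  distinct WER values:", paste(signif(u, 4), collapse = ", "), "\n")
  } else {
    cat(sprintf("  %d distinct WER values in [%g, %g]\n",
                length(u), min(u), max(u)))
  }
  invisible(object)
}

#' Build a homogeneous water phantom
#'
#' @param extents Phantom extents `(x, y, z)` in mm, `> 0`.
#' @param voxel_size Isotropic voxel width in mm, or a triple, `> 0`. Grid
#'   dimensions are `ceiling(extent / voxel_size)`.
#' @param origin Grid origin (mm); by default the phantom is centred
#'   laterally on the beam axis with its entrance face at z = 0, positioned
#'   so that the axis passes through a voxel centre (an axis lying exactly
#'   on a voxel face would split an axial pencil beam over four columns).
#' @return A [wer_map()] with WER = 1 everywhere.
#' @export
build_water_phantom <- function(extents, voxel_size = 1, origin = NULL) {
  if (any(extents <= 0) || any(voxel_size <= 0)) {
    stop("extents and voxel_size must be positive")
  }
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  n <- as.integer(ceiling(extents / voxel_size))
  if (is.null(origin)) {
    origin <- c(-(floor(n[1] / 2) + 0.5) * voxel_size[1],
                -(floor(n[2] / 2) + 0.5) * voxel_size[2], 0)
  }
  grid <- voxel_grid(n, voxel_size, origin)
  wer_map(grid, array(1.0, dim = n))
}

#' Phantom specification with slab heterogeneities
#'
#' A water background with axis-aligned box inserts, each carrying its own
#' water-equivalent ratio (e.g. bone WER = 2, air WER = 0.001). Voxels are
#' assigned by voxel-centre membership; when inserts overlap, the
#' last-listed insert wins (a warning is issued).
#'
#' @param extents Phantom extents (mm).
#' @param inserts List of inserts, each a list with elements `lo` and `hi`
#'   (mm corner triples) and `wer` (`> 0`).
#' @param kind One of `"water"`, `"slab_hetero"`, `"custom"`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(extents, inserts = list(), kind = "slab_hetero") {
  stopifnot(all(extents > 0), kind %in% c("water", "slab_hetero", "custom"))
  for (ins in inserts) {
    stopifnot(length(ins$lo) == 3, length(ins$hi) == 3, ins$wer > 0,
              all(ins$hi > ins$lo))
  }
  structure(list(extents = as.numeric(extents), inserts = inserts,
                 kind = kind),
            class = "phantom_spec")
}

#' Default heterogeneous slab phantom specification
#'
#' Two bone slabs (WER 2) and one air slab (WER 0.001) embedded in water,
#' with an edge parallel to the beam axis so that edge scattering is
#' exercised. The dimensions are an editable configuration default, not
#' ground truth; coordinates are in the phantom frame whose entrance face is
#' z = 0 and whose lateral origin is the beam axis.
#'
#' @param extents Phantom extents (mm).
#' @return A [phantom_spec()].
#' @export
default_slab_spec <- function(extents = c(200, 200, 350)) {
  inserts <- list(
    list(lo = c(-100, -100,  20), hi = c(0, 100,  50), wer = 2.0),    # bone
    list(lo = c(0,    -100,  60), hi = c(100, 100, 90), wer = 0.001), # air
    list(lo = c(-100, -100, 100), hi = c(100, 100, 120), wer = 2.0)   # bone
  )
  phantom_spec(extents, inserts, kind = "slab_hetero")
}

#' Build a slab-heterogeneity phantom from a specification
#'
#' @param spec A [phantom_spec()] (kind `"slab_hetero"` or `"custom"`); an
#'   empty insert list reproduces a water phantom.
#' @param voxel_size Voxel width (mm), scalar or triple.
#' @return A [wer_map()].
#' @export
build_slab_phantom <- function(spec = default_slab_spec(), voxel_size = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  wm <- build_water_phantom(spec$extents, voxel_size)
  g <- wm$grid
  cx <- g$origin[1] + (seq_len(g$n[1]) - 0.5) * g$spacing[1]
  cy <- g$origin[2] + (seq_len(g$n[2]) - 0.5) * g$spacing[2]
  cz <- g$origin[3] + (seq_len(g$n[3]) - 0.5) * g$spacing[3]
  assigned <- array(FALSE, dim = g$n)
  overlap <- FALSE
  for (ins in spec$inserts) {
    ix <- which(cx >= ins$lo[1] & cx < ins$hi[1])
    iy <- which(cy >= ins$lo[2] & cy < ins$hi[2])
    iz <- which(cz >= ins$lo[3] & cz < ins$hi[3])
    if (length(ix) && length(iy) && length(iz)) {
      if (any(assigned[ix, iy, iz])) overlap <- TRUE
      wm$wer[ix, iy, iz] <- ins$wer
      assigned[ix, iy, iz] <- TRUE
    }
  }
  if (overlap) warning("overlapping inserts: last-listed insert wins")
  wm
}

#' Convert CT numbers to water-equivalent ratios
#'
#' Element-wise piecewise-linear interpolation of a user-supplied monotone
#' calibration table; values outside the table clamp to the end values.
#'
#' @param hu_values Numeric vector/array of CT numbers (HU).
#' @param calibration_table data.frame with columns `hu` (ascending) and
#'   `wer` (`> 0`).
#' @return WER values with the same shape as `hu_values`.
#' @export
hu_to_wer <- function(hu_values, calibration_table) {
  if (is.null(calibration_table) || nrow(calibration_table) == 0) {
    stop("calibration table must be non-empty")
  }
  stopifnot(all(c("hu", "wer") %in% names(calibration_table)))
  tb <- calibration_table
  if (is.unsorted(tb$hu, strictly = TRUE)) stop("calibration table HU must be ascending")
  out <- stats::approx(tb$hu, tb$wer, xout = as.vector(hu_values),
                       rule = 2)$y
  if (is.array(hu_values)) out <- array(out, dim = dim(hu_values))
  out
}

#' Exact voxel-by-voxel ray traversal (Siddon)
#'
#' Traces a ray through the grid and returns, in order, each traversed voxel
#' together with the geometric chord length inside it. The segment lengths
#' partition the chord: their sum equals the in-grid chord length up to
#' `max_length`.
#'
#' @param map A [wer_map()] (or a bare [voxel_grid()]).
#' @param start Ray start (mm); inside or on the grid boundary (a start
#'   outside the grid with the ray pointing away yields an empty result).
#' @param direction Unit direction vector.
#' @param max_length Maximum traced length (mm); `Inf` for the full chord.
#' @return A data.frame with 0-based voxel indices `i`, `j`, `k` and segment
#'   lengths `dL` (mm, all `> 0`).
#' @export
traverse_ray <- function(map, start, direction, max_length = Inf) {
  g <- if (inherits(map, "wer_map")) map$grid else map
  stopifnot(inherits(g, "voxel_grid"), length(start) == 3,
            length(direction) == 3)
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-6) stop("direction must be a unit vector")
  res <- traverse_ray_cpp(as.integer(g$n), g$spacing, g$origin,
                          as.numeric(start), as.numeric(direction) / nrm,
                          as.numeric(max_length))
  data.frame(i = res$i, j = res$j, k = res$k, dL = res$dL)
}
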