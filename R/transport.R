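#' Transport physics configuration
#'
#' Bundles every physics ingredient the tracking loop needs: the
#' range-energy model, the multiple-Coulomb-scattering model, the elastic
#' cross-section table with its correction factors, the large-angle angular
#' model, the residual-range cutoff and the depth-projection convention.
#'
#' @param range_model A [range_energy_model()].
#' @param mcs A [mcs_model()].
#' @param xs A [cross_section_table()].
#' @param factors A [correction_factors()] object.
#' @param angular A [las_angular_model()].
#' @param const Physics constants, see [physics_constants()].
#' @param cutoff Residual-range cutoff (g/cm^2) terminating a track.
#' @param projection Depth-projection convention for the in-progress step:
#'   `"half"` scores the current step at `L'w + dLw*cos(theta)/2`
#'   (default); `"cos2"` scores it at `L'w + dLw*cos(theta)^2`.
#' @param mcs_scale Multiplier on the MCS deflection sigma (0 disables MCS;
#'   diagnostic use).
#' @param las_p_override If non-negative, forces the per-step large-angle
#'   interaction probability to this value (diagnostic use; `NA` disables).
#' @return An object of class `transport_physics`.
#' @export
transport_physics <- function(range_model = range_energy_model(),
                              mcs = mcs_model(),
                              xs = default_cross_sections(),
                              factors = correction_factors(),
                              angular = las_angular_model(),
                              const = physics_constants(),
                              cutoff = 0.1,
                              projection = c("half", "cos2"),
                              mcs_scale = 1,
                              las_p_override = NA_real_) {
  projection <- match.arg(projection)
  stopifnot(cutoff >= 0, mcs_scale >= 0)
  structure(list(range_model = range_model, mcs = mcs, xs = xs,
                 factors = factors, angular = angular, const = const,
                 cutoff = cutoff, projection = projection,
                 mcs_scale = mcs_scale, las_p_override = las_p_override),
            class = "transport_physics")
}

# dense energy<->range lookup passed to the compiled engine
.range_lookup <- function(model, E_max = 350, dE = 0.25) {
  E <- seq(0, E_max, by = dE)
  list(E = E, R = range_from_energy(E, model))
}

# adjusted partial cross-sections on the table's energy grid:
# hydrogen 2*F_pH*sigma_pH, oxygen F_pO*sigma_pO
.adjusted_partials <- function(xs, fac) {
  f <- interp_correction_factors(fac, xs$energies)
  list(E = xs$energies,
       H = 2 * f$F_pH * xs$sigma_pH,
       O = f$F_pO * xs$sigma_pO)
}

.physics_cpp_list <- function(physics, las_on) {
  lk <- .range_lookup(physics$range_model)
  ap <- .adjusted_partials(physics$xs, physics$factors)
  cst <- physics$const
  list(re_E = lk$E, re_R = lk$R,
       X0 = physics$mcs$X0, mcs_k = physics$mcs$k,
       mcs_clog = physics$mcs$c_log,
       m_proton = cst$m_proton, m_oxygen = cst$m_oxygen,
       n_factor = cst$N_avogadro * cst$rho_water / cst$M_water *
         cst$barn_cm2 / cst$rho_water,
       xs_E = ap$E, xs_H = ap$H, xs_O = ap$O,
       theta_min = physics$angular$theta_min,
       theta_max = physics$angular$theta_max,
       theta_s0 = physics$angular$theta_s0,
       e_ref = physics$angular$E_ref,
       cutoff = physics$cutoff,
       halfstep = physics$projection == "half",
       mcs_scale = physics$mcs_scale,
       las_on = las_on,
       p_override = if (is.na(physics$las_p_override)) -1
                    else physics$las_p_override)
}

#' Projected water-equivalent depth along a particle track
#'
#' Maintains the table-lookup depth variable: after `n` steps with
#' water-equivalent lengths `dLw` at angles `theta` to the beam axis, the
#' completed-track depth is `sum(dLw * cos(theta))`, while the in-progress
#' step `n` contributes only `dLw[n] * cos(theta[n]) / 2` (half-weight
#' midpoint convention) or `dLw[n] * cos(theta[n])^2` under the alternative
#' convention.
#'
#' @param dLw Water-equivalent step lengths (g/cm^2), in track order.
#' @param cos_theta Cosines of the step angles to the beam axis.
#' @param convention `"half"` (default) or `"cos2"`.
#' @return A list with `score` (the projected depth at which each step is
#'   scored) and `final` (the completed projected depth after all steps).
#' @export
project_depth <- function(dLw, cos_theta, convention = c("half", "cos2")) {
  convention <- match.arg(convention)
  stopifnot(length(dLw) == length(cos_theta), all(abs(cos_theta) <= 1))
  full <- dLw * cos_theta
  before <- c(0, cumsum(full))[seq_along(dLw)]
  inprog <- if (convention == "half") full / 2 else dLw * cos_theta^2
  list(score = before + inprog, final = sum(full))
}

# deterministic largest-remainder allocation of n particles to weights
.allocate_particles <- function(weights, n) {
  if (sum(weights) <= 0) stop("plan has zero total weight")
  exact <- n * weights / sum(weights)
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    order_frac <- order(exact - base, decreasing = TRUE)
    base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# table matched to an energy; conventional mode uses the unmodified IDD
.match_table <- function(tables, energy, mode) {
  for (tb in tables) {
    e <- if (inherits(tb, "midd_table")) tb$base$energy else tb$energy
    if (isTRUE(all.equal(e, energy))) {
      if (mode == "conventional" && inherits(tb, "midd_table")) {
        return(tb$base)
      }
      return(tb)
    }
  }
  stop("no depth-dose table supplied for energy ", energy, " MeV")
}

.table_arrays <- function(tb) {
  if (inherits(tb, "midd_table")) {
    list(z0 = tb$base$z[1], dz = tb$base$dz, v = tb$values)
  } else {
    list(z0 = tb$z[1], dz = tb$dz, v = tb$values)
  }
}

#' Run the simplified Monte Carlo dose calculation
#'
#' Tracks particles voxel-to-voxel through the water-equivalent-ratio map.
#' At each voxel crossing the step's water-equivalent length is scored
#' against the energy-matched depth-dose table at the particle's projected
#' water-equivalent depth, the residual range is decremented, a Gaussian
#' multiple-Coulomb-scattering deflection is applied, and (in `"modified"`
#' mode) a large-angle elastic scattering may occur with the per-step
#' probability given by the adjusted cross-section; a large-angle event
#' deflects the particle and reduces its residual range according to
#' two-body elastic kinematics. Tracks end when the residual range falls
#' below the cutoff or the particle leaves the grid.
#'
#' `"conventional"` mode disables the large-angle channel and scores from
#' the unmodified IDD; `"modified"` mode enables it and should be paired
#' with m-IDD tables (the per-step random stream is identical in both modes,
#' so with a vanishing large-angle cross-section the two modes produce
#' bitwise-identical dose grids for the same seed). Runs are reproducible
#' for a fixed seed: every particle owns a counter-based RNG substream keyed
#' by (seed, particle index).
#'
#' @param plan A [spot_plan()].
#' @param map A [wer_map()].
#' @param physics A [transport_physics()] configuration.
#' @param tables List of [idd_table()] / [midd_table()] objects covering all
#'   plan energies (checked before any tracking).
#' @param n_particles Total number of primary histories, allocated across
#'   spots proportionally to spot weights (largest-remainder rounding).
#' @param seed Integer seed.
#' @param mode `"modified"` (large-angle channel on) or `"conventional"`.
#' @param score_dose Score the per-voxel dose grid (default `TRUE`).
#' @param depth_hist Also accumulate the laterally integrated table-weighted
#'   histogram `sum(dLw * table(L'w))` per projected-depth bin, with
#'   per-particle variance bookkeeping (used for survival estimation and the
#'   lateral-integration consistency check).
#' @param hist_dz Histogram bin width (g/cm^2).
#' @param hist_zmax Histogram upper edge (g/cm^2).
#' @return An object of class `dose_grid`: per-voxel dose per incident
#'   particle (value x voxel volume = `table(L'w) * sum(dLw) / N0`), plus
#'   run metadata and, if requested, the depth histogram with standard
#'   errors.
#' @export
run_simulation <- function(plan, map, physics = transport_physics(),
                           tables, n_particles, seed = 1,
                           mode = c("modified", "conventional"),
                           score_dose = TRUE, depth_hist = FALSE,
                           hist_dz = 0.1, hist_zmax = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(plan, "spot_plan"), inherits(map, "wer_map"),
            n_particles >= 0)
  # configuration check before any tracking
  spot_tables <- lapply(unique(plan$spots$energy), function(e)
    .match_table(tables, e, mode))
  names(spot_tables) <- as.character(unique(plan$spots$energy))

  g <- map$grid
  nvox <- prod(g$n)
  tally <- numeric(nvox)
  if (is.null(hist_zmax)) {
    hist_zmax <- max(range_from_energy(unique(plan$spots$energy),
                                       physics$range_model)) + 2
  }
  hist_n <- as.integer(ceiling(hist_zmax / hist_dz))
  hist_sum <- numeric(hist_n)
  hist_sumsq <- numeric(hist_n)

  n_spot <- .allocate_particles(plan$spots$weight, as.integer(n_particles))
  phys_cpp <- .physics_cpp_list(physics, las_on = (mode == "modified"))

  set.seed(seed)
  gid0 <- 0L
  if (n_particles > 0) {
    for (is in seq_len(nrow(plan$spots))) {
      if (n_spot[is] == 0) next
      spot <- plan$spots[is, ]
      ps <- .plan_ps(plan, spot$energy)
      parts <- sample_particles(spot, ps, n_spot[is], sad = plan$sad,
                                model = physics$range_model,
                                z_entry = plan$z_entry)
      ta <- .table_arrays(spot_tables[[as.character(spot$energy)]])
      res <- run_engine_cpp(as.numeric(map$wer), g$n, g$spacing, g$origin,
                            parts, ta$z0, ta$dz, ta$v, phys_cpp,
                            as.integer(seed), gid0,
                            score_dose, depth_hist, hist_dz, hist_n)
      if (score_dose) tally <- tally + res$tally
      if (depth_hist) {
        hist_sum <- hist_sum + res$hist_sum
        hist_sumsq <- hist_sumsq + res$hist_sumsq
      }
      gid0 <- gid0 + n_spot[is]
    }
  }

  vol_cm3 <- prod(g$spacing) / 1000
  dose <- array(if (n_particles > 0) tally / (vol_cm3 * n_particles)
                else tally, dim = g$n)
  out <- structure(list(grid = g, dose = dose,
                        n_particles = as.integer(n_particles),
                        mode = mode, seed = as.integer(seed),
                        cutoff = physics$cutoff),
                   class = "dose_grid")
  if (depth_hist) {
    out$depth_hist <- data.frame(z = (seq_len(hist_n) - 0.5) * hist_dz,
                                 sum = hist_sum, sumsq = hist_sumsq)
    out$hist_dz <- hist_dz
  }
  out
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("Dose grid (%s SMC): %d x %d x %d voxels, %s histories, seed %d\n",
              x$mode, x$grid$n[1], x$grid$n[2], x$grid$n[3],
              format(x$n_particles, big.mark = ","), x$seed))
  cat(sprintf("  dose per particle: max %.4g, total %.4g (arb. unit / cm3)\n",
              max(x$dose), sum(x$dose)))
  invisible(x)
}

#' @export
summary.dose_grid <- function(object, ...) {
  print(object)
  pk <- which(object$dose == max(object$dose), arr.ind = TRUE)[1, ]
  g <- object$grid
  cat(sprintf("  peak voxel (0-based): (%d, %d, %d) at z = %g mm\n",
              pk[1] - 1, pk[2] - 1, pk[3] - 1,
              g$origin[3] + (pk[3] - 0.5) * g$spacing[3]))
  invisible(object)
}

#' @export
plot.dose_grid <- function(x, j = NULL, ...) {
  g <- x$grid
  if (is.null(j)) j <- ceiling(g$n[2] / 2)
  sl <- x$dose[, j, ]
  zs <- g$origin[3] + (seq_len(g$n[3]) - 0.5) * g$spacing[3]
  xs <- g$origin[1] + (seq_len(g$n[1]) - 0.5) * g$spacing[1]
  graphics::image(zs, xs, t(sl), xlab = "depth z (mm)", ylab = "x (mm)",
                  main = sprintf("%s SMC dose, z-x plane", x$mode),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
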