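#' Integrated depth-dose (IDD) table
#'
#' Dose integrated over an infinite lateral plane per incident proton, as a
#' function of water-equivalent depth. Depth grid must be uniform; values
#' are non-negative with a single Bragg peak for pristine beams.
#'
#' @param energy Nominal beam kinetic energy (MeV).
#' @param z Depths (g/cm^2), ascending, uniformly spaced.
#' @param values Table values (dose-area per incident proton, consistent
#'   arbitrary unit), `>= 0`.
#' @return An object of class `idd_table`.
#' @export
idd_table <- function(energy, z, values) {
  stopifnot(energy > 0, length(z) == length(values), length(z) >= 2,
            all(values >= 0), !is.unsorted(z, strictly = TRUE))
  dz <- diff(z)
  if (max(abs(dz - dz[1])) > 1e-9 * dz[1]) {
    stop("IDD depth grid must be uniformly spaced")
  }
  structure(list(energy = energy, z = as.numeric(z),
                 values = as.numeric(values), dz = dz[1]),
            class = "idd_table")
}

#' @export
print.idd_table <- function(x, ...) {
  cat(sprintf("IDD table: E = %g MeV, %d depths on [%g, %g] g/cm2 (dz = %g)\n",
              x$energy, length(x$z), min(x$z), max(x$z), x$dz))
  cat(sprintf("  peak %g at z = %g g/cm2\n",
              max(x$values), x$z[which.max(x$values)]))
  invisible(x)
}

#' @export
plot.idd_table <- function(x, ...) {
  graphics::plot(x$z, x$values, type = "l", xlab = "depth (g/cm2)",
                 ylab = "IDD (arb. unit)",
                 main = sprintf("IDD, E = %g MeV", x$energy), ...)
  invisible(x)
}

#' Generate a synthetic pristine Bragg-curve IDD table
#'
#' Analytic stand-in for a measured or full-Monte-Carlo integrated depth
#' dose. The underlying curve is the Bragg-Kleeman stopping power
#' `S(z) ~ (R0 - z)^(1/p - 1)` times a mild linear fluence-reduction factor
#' (entrance-to-peak ratio control), convolved with a Gaussian range
#' straggle of width `sigma_R = straggling_fraction * R0`. The depth axis is
#' shifted after convolution so that the table's maximum sits exactly at the
#' model range `R0 = range_from_energy(E)`.
#'
#' @param E Beam kinetic energy (MeV), `> 0`.
#' @param model A [range_energy_model()].
#' @param dz Depth grid spacing (g/cm^2).
#' @param straggling_fraction Gaussian range-straggle sigma as a fraction of
#'   the range (typical ~1%).
#' @param fluence_slope Linear fluence reduction over the full range
#'   (dimensionless; 0.2 means 20% fewer primaries at the peak than at the
#'   surface), controls the entrance-to-peak ratio.
#' @param tail_cut Table is extended past the peak until the value falls
#'   below this fraction of the peak (default 0.1%).
#' @return An [idd_table()].
#' @export
generate_synthetic_idd <- function(E, model = range_energy_model(),
                                   dz = 0.1, straggling_fraction = 0.011,
                                   fluence_slope = 0.25, tail_cut = 1e-3) {
  if (E <= 0) stop("energy must be > 0")
  R0 <- range_from_energy(E, model)
  sigma <- straggling_fraction * R0
  # fine grid for the convolution, extended past the range
  fine <- dz / 4
  zf <- seq(0, R0 + 8 * sigma + 2, by = fine)
  expo <- 1 / model$p - 1                      # ~ -0.44, integrable singularity
  s <- ifelse(zf < R0, pmax(R0 - zf, fine / 2)^expo, 0)
  s <- s * pmax(0, 1 - fluence_slope * zf / R0)
  kern_half <- ceiling(5 * sigma / fine)
  kern <- stats::dnorm(seq(-kern_half, kern_half) * fine, sd = sigma) * fine
  pad <- rep(0, kern_half)
  sv <- stats::filter(c(s[1] + numeric(kern_half), s, pad), kern, sides = 2)
  sv <- as.numeric(sv)[kern_half + seq_along(zf)]
  sv[is.na(sv)] <- 0
  # re-anchor the peak at the nominal range
  shift <- R0 - zf[which.max(sv)]
  z_out <- seq(0, R0 + 6 * sigma + 1, by = dz)
  v <- stats::approx(zf + shift, sv, xout = z_out, rule = 2)$y
  v[v < 0] <- 0
  # trim distal tail below tail_cut of peak (keep at least one such node)
  pk <- which.max(v)
  below <- which(v < tail_cut * max(v) & seq_along(v) > pk)
  if (length(below)) v[below] <- 0
  # normalize entrance to 1 (arbitrary consistent unit)
  v <- v / v[1]
  idd_table(E, z_out, v)
}

#' Evaluate a depth-dose table at arbitrary depths
#'
#' Linear interpolation on the depth grid; depths past the table end return
#' 0, depths before the first node return the first value.
#'
#' @param table An [idd_table()] or [midd_table()].
#' @param z Depths (g/cm^2), `>= 0`, vectorized.
#' @return Interpolated table values.
#' @export
lookup <- function(table, z) {
  if (any(z < 0)) stop("depth must be >= 0")
  tb <- if (inherits(table, "midd_table")) table$base else table
  vals <- if (inherits(table, "midd_table")) table$values else tb$values
  out <- stats::approx(tb$z, vals, xout = z, yleft = vals[1], yright = 0)$y
  out[z > max(tb$z)] <- 0
  out
}

#' Particle survival curve versus projected water-equivalent depth
#'
#' The Monte-Carlo estimate of the surviving primary fluence fraction
#' `s(z) = N(z)/N0` (the inverse of the m-IDD conversion factor), binned on
#' the same projected water-equivalent depth variable that indexes the dose
#' tables. Constructed by [estimate_survival()]. Because the underlying
#' path-length bracket weights oblique tracks by their full path, estimates
#' may marginally exceed 1 (sub-percent) where the halo's path obliquity
#' outweighs fluence loss; a hard upper sanity bound of 1.05 is enforced.
#'
#' @param z Bin-centre depths (g/cm^2).
#' @param s Survival fraction estimates (`>= 0`, at most marginally above 1).
#' @param stderr Per-bin Monte-Carlo standard errors.
#' @param n_histories Number of histories used for the estimate.
#' @return An object of class `survival_curve`.
#' @export
survival_curve <- function(z, s, stderr = rep(0, length(z)),
                           n_histories = NA_integer_) {
  stopifnot(length(z) == length(s), length(s) == length(stderr),
            all(s >= 0), all(s <= 1.05), !is.unsorted(z))
  structure(list(z = as.numeric(z), s = as.numeric(s),
                 stderr = as.numeric(stderr), n_histories = n_histories),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Survival curve: %d bins on [%g, %g] g/cm2", length(x$z),
              min(x$z), max(x$z)))
  if (!is.na(x$n_histories)) cat(sprintf(", %d histories", x$n_histories))
  cat(sprintf("\n  s range [%g, %g]\n", min(x$s), max(x$s)))
  invisible(x)
}

#' @export
plot.survival_curve <- function(x, ...) {
  graphics::plot(x$z, x$s, type = "s", ylim = c(0, 1),
                 xlab = "projected water-equivalent depth (g/cm2)",
                 ylab = "surviving fraction", ...)
  invisible(x)
}

#' Estimate the particle survival fraction by matched unit-table engine runs
#'
#' Runs the transport engine twice on a water phantom with every preset
#' table value replaced by one, accumulating the path-length bracket
#' `sum(dLw) / (N0 * dz)` per projected water-equivalent depth bin: once in
#' modified mode (large-angle channel on) and once in conventional mode
#' (channel off), with the *same* seed so the two runs share every random
#' stream. The survival estimate is the per-bin ratio
#' `bracket_modified / bracket_conventional`. The conventional bracket is
#' the algorithm's own fluence-invariance baseline (it differs from 1 only
#' through multiple-Coulomb path obliquity, a sub-percent effect), so the
#' ratio isolates the fluence loss caused by large-angle scattering; in the
#' degenerate limit of a vanishing large-angle cross-section the two runs
#' are identical and the estimate is exactly 1 in every bin.
#'
#' Because the range-out cliff at the end of the track appears identically
#' in the numerator and the denominator, the ratio remains meaningful
#' through the distal falloff; the support ends where the conventional
#' bracket drops below `support_floor` (too few primaries left to
#' normalize). Downstream, [convert_idd_to_midd()] holds the conversion
#' factor at its last supported value.
#'
#' By default the beam carries the Gaussian energy spread whose range image
#' matches the depth-dose tables' range straggle
#' ([energy_spread_for_straggle()]): the conversion run should present the
#' same distal fluence falloff as the table it converts, and with it the
#' conversion factor keeps rising through the Bragg peak, which is what
#' makes the m-IDD peak sharper than the IDD peak.
#'
#' @param E Beam kinetic energy (MeV).
#' @param n_histories Number of primary histories (`> 0`).
#' @param dz Depth bin width (g/cm^2); defaults to the IDD grid spacing
#'   convention (0.1 g/cm^2 = 1 mm of water).
#' @param physics A [transport_physics()] configuration.
#' @param lateral_mm Lateral half-extent of the scoring water phantom (mm).
#' @param voxel_mm Voxel width (mm) of the scoring phantom.
#' @param seed Integer seed for the per-particle RNG substreams.
#' @param energy_spread Gaussian kinetic-energy sigma (MeV) of the
#'   conversion beam; `NULL` (default) matches the synthetic tables'
#'   straggling fraction, 0 gives a strictly mono-energetic beam.
#' @param straggling_fraction Range-straggle fraction used when
#'   `energy_spread` is `NULL` (must match the table generator's value).
#' @param support_floor Minimum conventional-mode bracket value for a bin
#'   to stay in the curve's support.
#' @param monotone Apply non-increasing isotonic smoothing to the ratio
#'   (off by default: the bracket ratio is genuinely non-monotone at the
#'   sub-percent level where halo obliquity precedes fluence loss, and
#'   forcing monotonicity would bias the table conversion).
#' @return A [survival_curve()].
#' @export
estimate_survival <- function(E, n_histories = 1e5, dz = 0.1,
                              physics = transport_physics(),
                              lateral_mm = 100, voxel_mm = 2, seed = 1,
                              energy_spread = NULL,
                              straggling_fraction = 0.011,
                              support_floor = 0.05, monotone = FALSE) {
  if (n_histories <= 0) stop("n_histories must be > 0")
  if (is.null(energy_spread)) {
    energy_spread <- energy_spread_for_straggle(E, physics$range_model,
                                                straggling_fraction)
  }
  R0 <- range_from_energy(E, physics$range_model)
  depth_mm <- 10 * (R0 + 2)
  phantom <- build_water_phantom(c(2 * lateral_mm, 2 * lateral_mm, depth_mm),
                                 voxel_mm)
  # unit preset table spanning the full depth range
  zt <- seq(0, R0 + 2, by = dz)
  unit_tab <- idd_table(E, zt, rep(1, length(zt)))
  ps <- phase_space(energy = E, sigma_x = 0, sigma_theta = 0,
                    energy_spread = energy_spread)
  plan <- spot_plan(spots = data.frame(x = 0, y = 0, energy = E, weight = 1),
                    phase_space = list(ps))
  one_run <- function(mode) {
    run_simulation(plan, phantom, physics = physics,
                   tables = list(unit_tab), n_particles = n_histories,
                   seed = seed, mode = mode, score_dose = FALSE,
                   depth_hist = TRUE, hist_dz = dz,
                   hist_zmax = R0 + 2)$depth_hist
  }
  hm <- one_run("modified")
  hc <- one_run("conventional")
  # support: enough surviving primaries in the normalization run
  keep_until <- max(which(hc$sum / (n_histories * dz) >= support_floor))
  keep <- seq_len(keep_until)
  hm <- hm[keep, ]; hc <- hc[keep, ]
  s <- hm$sum / hc$sum
  per_se <- function(h) sqrt(pmax(0, h$sumsq / n_histories -
                                    (h$sum / n_histories)^2) / n_histories)
  # conservative (uncorrelated) propagation of the two brackets
  se <- s * sqrt((per_se(hm) / pmax(hm$sum / n_histories, 1e-300))^2 +
                   (per_se(hc) / (hc$sum / n_histories))^2)
  if (monotone) {
    iso <- stats::isoreg(hm$z, -s)
    s <- -iso$yf
  }
  s <- pmin(1.05, pmax(0, s))
  survival_curve(hm$z, s, se, n_histories)
}

#' Modified IDD (m-IDD) table
#'
#' An IDD table rescaled depth-by-depth by the conversion factor
#' `C(z) = 1/s(z)`, the inverse surviving fluence fraction, so that
#' table-lookup dose scoring remains exact when the large-angle channel
#' removes primaries: `m_IDD(z) = C(z) * IDD(z)`. `C` rises well above 1
#' toward the range end; it may dip marginally (sub-percent) below 1 in the
#' proximal region where halo path obliquity precedes fluence loss.
#'
#' @param base The source [idd_table()].
#' @param C Conversion factors per depth node, `> 0`.
#' @param survival The [survival_curve()] used for the conversion (kept for
#'   provenance; may be `NULL`).
#' @return An object of class `midd_table`.
#' @export
midd_table <- function(base, C, survival = NULL) {
  stopifnot(inherits(base, "idd_table"), length(C) == length(base$z),
            all(C > 0))
  structure(list(base = base, C = C,
                 values = C * base$values, survival = survival,
                 energy = base$energy),
            class = "midd_table")
}

#' @export
print.midd_table <- function(x, ...) {
  cat(sprintf("m-IDD table: E = %g MeV, %d depths, C(z) in [%g, %g]\n",
              x$base$energy, length(x$base$z), min(x$C), max(x$C)))
  invisible(x)
}

#' @export
plot.midd_table <- function(x, ...) {
  graphics::plot(x$base$z, x$values, type = "l", col = "red",
                 xlab = "depth (g/cm2)", ylab = "value (arb. unit)",
                 main = sprintf("IDD vs m-IDD, E = %g MeV", x$base$energy), ...)
  graphics::lines(x$base$z, x$base$values, col = "black")
  graphics::legend("topleft", legend = c("m-IDD", "IDD"),
                   col = c("red", "black"), lty = 1, bty = "n")
  invisible(x)
}

#' Convert an IDD table to m-IDD form using a survival curve
#'
#' Resamples the survival curve onto the IDD depth grid by linear
#' interpolation (holding the end values beyond the curve's support), forms
#' `C(z) = 1/s(z)` (clamped where `s` falls below `s_floor`, with a
#' warning), and returns `m_IDD = C * IDD`. With `s == 1` everywhere the
#' conversion is the exact identity.
#'
#' @param idd An [idd_table()].
#' @param s A [survival_curve()].
#' @param s_floor Survival floor below which `C` is clamped (default 1e-3).
#' @return A [midd_table()].
#' @export
convert_idd_to_midd <- function(idd, s, s_floor = 1e-3) {
  stopifnot(inherits(idd, "idd_table"), inherits(s, "survival_curve"))
  sz <- stats::approx(s$z, s$s, xout = idd$z, rule = 2)$y
  if (any(sz < s_floor & idd$values > 0)) {
    warning("survival below floor at some depths with non-zero IDD; C clamped")
  }
  C <- 1 / pmax(sz, s_floor)
  midd_table(idd, C, survival = s)
}

#' Full width of a depth-dose peak at a fractional level
#'
#' Width of the interval where the (linearly interpolated) curve exceeds
#' `level * max`, used to compare IDD and m-IDD peak sharpness.
#'
#' @param table An [idd_table()] or [midd_table()].
#' @param level Fraction of the maximum (default 0.8).
#' @return Width in g/cm^2.
#' @export
peak_width <- function(table, level = 0.8) {
  z <- if (inherits(table, "midd_table")) table$base$z else table$z
  v <- if (inherits(table, "midd_table")) table$values else table$values
  thr <- level * max(v)
  above <- which(v >= thr)
  lo <- min(above); hi <- max(above)
  z_lo <- if (lo > 1) {
    z[lo - 1] + (thr - v[lo - 1]) / (v[lo] - v[lo - 1]) * (z[lo] - z[lo - 1])
  } else z[1]
  z_hi <- if (hi < length(z)) {
    z[hi] + (v[hi] - thr) / (v[hi] - v[hi + 1]) * (z[hi + 1] - z[hi])
  } else z[length(z)]
  z_hi - z_lo
}

#' Read / write depth-dose tables and survival curves as CSV
#'
#' Tables: columns `z`, `value` (and `C` for m-IDD). Survival curves:
#' columns `z`, `s`, `stderr`.
#'
#' @param path File path.
#' @param energy Beam energy (MeV) recorded in the table.
#' @param table,curve Object to write.
#' @return The read object, or (for writers) the path, invisibly.
#' @export
read_idd_csv <- function(path, energy) {
  df <- utils::read.csv(path)
  idd_table(energy, df$z, df$value)
}

#' @rdname read_idd_csv
#' @export
write_idd_csv <- function(table, path) {
  if (inherits(table, "midd_table")) {
    utils::write.csv(data.frame(z = table$base$z, value = table$values,
                                C = table$C), path, row.names = FALSE)
  } else {
    utils::write.csv(data.frame(z = table$z, value = table$values), path,
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname read_idd_csv
#' @export
read_survival_csv <- function(path) {
  df <- utils::read.csv(path)
  survival_curve(df$z, df$s, if ("stderr" %in% names(df)) df$stderr else
    rep(0, nrow(df)))
}

#' @rdname read_idd_csv
#' @export
write_survival_csv <- function(curve, path) {
  utils::write.csv(data.frame(z = curve$z, s = curve$s, stderr = curve$stderr),
                   path, row.names = FALSE)
  invisible(path)
}
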