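#' Physical constants used by the transport engine
#'
#' Fixed, documented values (CODATA / PDG): molar mass of water, Avogadro
#' number, density of water, proton and oxygen-16 nuclear rest masses, and
#' the radiation length of water used by the multiple-Coulomb-scattering
#' formula.
#'
#' @return A named list of constants:
#' \describe{
#'   \item{M_water}{molar mass of water, 18.015 g/mol}
#'   \item{N_avogadro}{Avogadro number, 6.02214076e23 1/mol}
#'   \item{rho_water}{density of water, 1 g/cm^3}
#'   \item{m_proton}{proton rest mass, 938.27208816 MeV/c^2}
#'   \item{m_oxygen}{oxygen-16 nuclear rest mass, 14895.08 MeV/c^2}
#'   \item{X0_water}{radiation length of water, 36.08 g/cm^2}
#'   \item{barn_cm2}{1 barn in cm^2, 1e-24}
#' }
#' @export
physics_constants <- function() {
  list(
    M_water     = 18.015,
    N_avogadro  = 6.02214076e23,
    rho_water   = 1.0,
    m_proton    = 938.27208816,
    m_oxygen    = 14895.08,
    X0_water    = 36.08,
    barn_cm2    = 1e-24
  )
}

# Bragg-Kleeman defaults fitted through the study's end anchors
# (118 MeV, 10 g/cm2) and (218.9 MeV, 30 g/cm2); reproduces the
# intermediate beam (178.2 MeV -> 20.81 vs 21 g/cm2) to 0.9%.
.bk_p_default     <- log(3) / log(218.9 / 118)          # 1.77789
.bk_alpha_default <- 10 / 118^.bk_p_default             # 2.07215e-3 g/cm2/MeV^p

#' Range-energy model for protons in water
#'
#' Bragg-Kleeman power law `R = alpha * E^p` (range in g/cm^2, kinetic energy
#' in MeV), optionally overridden by a monotone tabulated CSDA-range curve.
#'
#' @param alpha Bragg-Kleeman coefficient (g/cm^2 per MeV^p).
#' @param p Bragg-Kleeman exponent (dimensionless).
#' @param table Optional data.frame with columns `energy` (MeV, ascending)
#'   and `range` (g/cm^2, strictly increasing) overriding the power law.
#' @return An object of class `range_energy_model`.
#' @export
range_energy_model <- function(alpha = .bk_alpha_default, p = .bk_p_default,
                               table = NULL) {
  stopifnot(alpha > 0, p > 0)
  if (!is.null(table)) {
    stopifnot(is.data.frame(table), all(c("energy", "range") %in% names(table)))
    if (is.unsorted(table$energy, strictly = TRUE) ||
        is.unsorted(table$range, strictly = TRUE)) {
      stop("tabulated range-energy override must be strictly increasing")
    }
  }
  structure(list(alpha = alpha, p = p, table = table),
            class = "range_energy_model")
}

#' @export
print.range_energy_model <- function(x, ...) {
  if (is.null(x$table)) {
    cat(sprintf("Range-energy model: Bragg-Kleeman R = %.4e * E^%.4f (g/cm2, MeV)\n",
                x$alpha, x$p))
  } else {
    cat(sprintf("Range-energy model: tabulated, %d nodes on [%g, %g] MeV\n",
                nrow(x$table), min(x$table$energy), max(x$table$energy)))
  }
  invisible(x)
}

#' Proton range in water from kinetic energy
#'
#' @param E Kinetic energy (MeV), vectorized, `>= 0`.
#' @param model A [range_energy_model()].
#' @return Residual range in water (g/cm^2).
#' @export
range_from_energy <- function(E, model = range_energy_model()) {
  if (any(!is.finite(E)) || any(E < 0)) stop("energy must be finite and >= 0")
  if (is.null(model$table)) {
    model$alpha * E^model$p
  } else {
    tb <- model$table
    # linear continuation below the first node keeps range(0) = 0
    out <- stats::approx(c(0, tb$energy), c(0, tb$range), xout = E,
                         rule = 2)$y
    out
  }
}

#' Proton kinetic energy from residual range in water
#'
#' Exact analytic inverse for the Bragg-Kleeman form; monotone interpolation
#' of the inverted table otherwise.
#'
#' @param R Residual range (g/cm^2), vectorized, `>= 0`.
#' @param model A [range_energy_model()].
#' @return Kinetic energy (MeV).
#' @export
energy_from_range <- function(R, model = range_energy_model()) {
  if (any(!is.finite(R)) || any(R < 0)) stop("range must be finite and >= 0")
  if (is.null(model$table)) {
    (R / model$alpha)^(1 / model$p)
  } else {
    tb <- model$table
    stats::approx(c(0, tb$range), c(0, tb$energy), xout = R, rule = 2)$y
  }
}

#' Energy spread matched to a range-straggling width
#'
#' The Gaussian kinetic-energy spread whose range image under the
#' range-energy model equals a given range-straggling sigma
#' (`sigma_R = straggling_fraction * range`): `sigma_E = sigma_R /
#' (dR/dE)`. Used so that the beam model of a table-conversion run carries
#' the same distal falloff width as the depth-dose table it converts.
#'
#' @param E Kinetic energy (MeV).
#' @param model A [range_energy_model()].
#' @param straggling_fraction Straggle sigma as a fraction of range.
#' @return Energy spread sigma (MeV).
#' @export
energy_spread_for_straggle <- function(E, model = range_energy_model(),
                                       straggling_fraction = 0.011) {
  stopifnot(E > 0, straggling_fraction >= 0)
  h <- 1e-3 * E
  dRdE <- (range_from_energy(E + h, model) -
             range_from_energy(max(0, E - h), model)) / (2 * h)
  straggling_fraction * range_from_energy(E, model) / dRdE
}

#' Relativistic kinematics helpers
#'
#' Momentum (MeV/c) and velocity ratio beta for a proton of kinetic energy E.
#' @param E Kinetic energy (MeV).
#' @return `proton_momentum`: momentum in MeV/c; `proton_beta`: v/c.
#' @keywords internal
proton_momentum <- function(E) {
  m <- physics_constants()$m_proton
  sqrt((E + m)^2 - m^2)
}

#' @rdname proton_momentum
#' @keywords internal
proton_beta <- function(E) {
  m <- physics_constants()$m_proton
  proton_momentum(E) / (E + m)
}

#' Multiple-Coulomb-scattering model (Lynch-Dahl / Highland form)
#'
#' @param X0_water Radiation length of water (g/cm^2).
#' @param highland_constant The 13.6 MeV constant.
#' @param log_correction_coefficient Coefficient of the log10 correction
#'   term (0.088 in the Lynch-Dahl fit written with log10).
#' @return An object of class `mcs_model`.
#' @export
mcs_model <- function(X0_water = physics_constants()$X0_water,
                      highland_constant = 13.6,
                      log_correction_coefficient = 0.088) {
  structure(list(X0 = X0_water, k = highland_constant,
                 c_log = log_correction_coefficient),
            class = "mcs_model")
}

#' Standard deviation of the MCS deflection angle over one step
#'
#' Lynch-Dahl empirical formula for a singly charged particle:
#' `sigma = (13.6 MeV / (beta c p)) * sqrt(t) * (1 + 0.088 log10(t))` with
#' `t = dLw / X0`. The bracket is clamped at zero for extremely thin steps
#' where the log correction would drive it negative.
#'
#' @param E Kinetic energy (MeV), `> 0`.
#' @param dLw Water-equivalent step length (g/cm^2), `>= 0`.
#' @param model An [mcs_model()].
#' @return Projected-angle standard deviation (rad).
#' @export
mcs_sigma <- function(E, dLw, model = mcs_model()) {
  if (any(E <= 0)) stop("energy must be > 0")
  if (any(dLw < 0)) stop("step length must be >= 0")
  t <- dLw / model$X0
  sig <- ifelse(t > 0,
                model$k / (proton_beta(E) * proton_momentum(E)) * sqrt(t) *
                  pmax(0, 1 + model$c_log * log10(t)),
                0)
  sig
}

#' Elastic cross-section table for protons on hydrogen and oxygen
#'
#' Total elastic cross-sections (barn) versus proton kinetic energy. Lookups
#' outside the tabulated energies clamp to the end values.
#'
#' @param energies Ascending energies (MeV).
#' @param sigma_pH,sigma_pO Cross-sections (barn), `>= 0`, same length.
#' @return An object of class `cross_section_table`.
#' @export
cross_section_table <- function(energies, sigma_pH, sigma_pO) {
  stopifnot(length(energies) == length(sigma_pH),
            length(energies) == length(sigma_pO),
            !is.unsorted(energies, strictly = TRUE),
            all(sigma_pH >= 0), all(sigma_pO >= 0))
  structure(list(energies = as.numeric(energies),
                 sigma_pH = as.numeric(sigma_pH),
                 sigma_pO = as.numeric(sigma_pO)),
            class = "cross_section_table")
}

#' Default proton elastic cross-section parameterization
#'
#' A smooth declared-approximate parameterization of total proton-hydrogen
#' and proton-oxygen elastic cross-sections, of the published order of
#' magnitude (0.1-1 barn over 10-250 MeV) and monotonically decreasing with
#' energy. These defaults are calibration-dependent stand-ins: the halo
#' magnitude they produce is tuned-model territory, and every shipped check
#' of the large-angle channel is structural (support, distribution shape,
#' ratios), not absolute.
#'
#' @param energies Energies at which to tabulate (MeV).
#' @return A [cross_section_table()].
#' @export
default_cross_sections <- function(energies = seq(1, 300, by = 1)) {
  sig_pH <- 0.035 * (100 / energies)^0.8 + 0.010
  sig_pO <- 0.300 * (100 / energies)^0.45 + 0.050
  cross_section_table(energies, sig_pH, sig_pO)
}

#' Read / write a cross-section table as CSV
#'
#' Three-column CSV: `energy` (MeV, ascending), `sigma_pH`, `sigma_pO` (barn).
#' @param path File path.
#' @param xs A [cross_section_table()].
#' @return `read_cross_sections`: a [cross_section_table()].
#' @export
read_cross_sections <- function(path) {
  df <- utils::read.csv(path)
  cross_section_table(df$energy, df$sigma_pH, df$sigma_pO)
}

#' @rdname read_cross_sections
#' @export
write_cross_sections <- function(xs, path) {
  utils::write.csv(data.frame(energy = xs$energies, sigma_pH = xs$sigma_pH,
                              sigma_pO = xs$sigma_pO),
                   path, row.names = FALSE)
  invisible(path)
}

#' Energy-dependent cross-section correction factors
#'
#' Multiplicative factors applied to the elastic cross-sections before
#' summation so that the single large-angle channel also stands in for
#' inelastic interactions and secondary particles. Anchored at 10, 100 and
#' 250 MeV; linear interpolation in energy between anchors, clamped outside.
#'
#' @param anchors Anchor energies (MeV).
#' @param F_pH Factors for proton-hydrogen at the anchors.
#' @param F_pO Factors for proton-oxygen at the anchors.
#' @return An object of class `correction_factors`.
#' @export
correction_factors <- function(anchors = c(10, 100, 250),
                               F_pH = c(3.0, 8.0, 17),
                               F_pO = c(1.0, 1.0, 1.0)) {
  stopifnot(length(anchors) == length(F_pH),
            length(anchors) == length(F_pO),
            !is.unsorted(anchors, strictly = TRUE),
            all(F_pH >= 1), all(F_pO >= 1))
  structure(list(anchors = anchors, F_pH = F_pH, F_pO = F_pO),
            class = "correction_factors")
}

#' Interpolate correction factors at given energies
#'
#' @param fac A [correction_factors()] object.
#' @param E Energies (MeV), vectorized.
#' @return A list with components `F_pH` and `F_pO` at each energy.
#' @export
interp_correction_factors <- function(fac, E) {
  list(F_pH = stats::approx(fac$anchors, fac$F_pH, xout = E, rule = 2)$y,
       F_pO = stats::approx(fac$anchors, fac$F_pO, xout = E, rule = 2)$y)
}

#' Read / write correction factors as YAML
#'
#' @param path File path.
#' @param fac A [correction_factors()] object.
#' @export
read_correction_factors <- function(path) {
  y <- yaml::read_yaml(path)
  correction_factors(anchors = as.numeric(y$anchors),
                     F_pH = as.numeric(y$F_pH), F_pO = as.numeric(y$F_pO))
}

#' @rdname read_correction_factors
#' @export
write_correction_factors <- function(fac, path) {
  yaml::write_yaml(list(anchors = fac$anchors, F_pH = fac$F_pH,
                        F_pO = fac$F_pO), path)
  invisible(path)
}

#' Adjusted total cross-section of the large-angle-scattering channel
#'
#' `sigma_LAS = 2 * F_pH(E) * sigma_pH(E) + F_pO(E) * sigma_pO(E)`; the
#' factor 2 counts the two hydrogen atoms per water molecule. Energies
#' outside the table's coverage clamp to the end values (with a warning).
#'
#' @param E Proton kinetic energy (MeV), vectorized.
#' @param xs A [cross_section_table()].
#' @param fac A [correction_factors()] object.
#' @return Total adjusted cross-section (barn).
#' @export
las_total_cross_section <- function(E, xs = default_cross_sections(),
                                    fac = correction_factors()) {
  if (any(E < min(xs$energies)) || any(E > max(xs$energies))) {
    warning("energy outside cross-section table coverage; clamping")
  }
  sH <- stats::approx(xs$energies, xs$sigma_pH, xout = E, rule = 2)$y
  sO <- stats::approx(xs$energies, xs$sigma_pO, xout = E, rule = 2)$y
  f <- interp_correction_factors(fac, E)
  2 * f$F_pH * sH + f$F_pO * sO
}

#' Per-step probability of a large-angle-scattering interaction
#'
#' `P = (Na * rho_w / M) * dLw * sigma_LAS`, i.e. molecular number density of
#' water times water-equivalent step length times the adjusted cross-section
#' (barn converted to cm^2). The result is clamped to `[0, 1]`.
#'
#' @param dLw Water-equivalent step length (g/cm^2 == cm at unit density),
#'   `>= 0`.
#' @param sigma_LAS Adjusted total cross-section (barn), `>= 0`.
#' @param const Physics constants, see [physics_constants()].
#' @return Interaction probability (dimensionless, in `[0, 1]`).
#' @export
las_probability <- function(dLw, sigma_LAS, const = physics_constants()) {
  stopifnot(all(dLw >= 0), all(sigma_LAS >= 0))
  n_density <- const$N_avogadro * const$rho_water / const$M_water  # 1/cm^3
  # dLw in g/cm^2 over rho_w in g/cm^3 is a length in cm
  pmin(1, n_density * (dLw / const$rho_water) * sigma_LAS * const$barn_cm2)
}

#' Angular model for the large-angle-scattering channel
#'
#' Deflection angles are drawn from a truncated exponential density
#' `f(theta) ~ exp(-theta / theta_s(E))` on `[theta_min, theta_max]` with an
#' energy-scaled slope `theta_s(E) = theta_s0 * (E_ref / E)`; the azimuth is
#' uniform on `[0, 2*pi)`. The exponential falloff is a pluggable stand-in
#' reproducing the qualitative monotone decrease of hadron-elastic angular
#' distributions; `theta_min` marks the hand-over to the Gaussian MCS
#' regime. The default slope (0.35 rad at 178.2 MeV) is broad: the channel
#' mostly stands in for proton-hydrogen elastic scattering, whose
#' near-isotropic centre-of-mass distribution maps to wide laboratory
#' angles, so scattered particles lose substantial range and terminate a
#' short distance downstream.
#'
#' @param theta_min Minimum deflection angle (rad).
#' @param theta_max Maximum deflection angle (rad).
#' @param theta_s0 Slope parameter at the reference energy (rad).
#' @param E_ref Reference energy (MeV).
#' @return An object of class `las_angular_model`.
#' @export
las_angular_model <- function(theta_min = 0.05, theta_max = pi / 2,
                              theta_s0 = 0.35, E_ref = 178.2) {
  stopifnot(theta_min >= 0, theta_max > theta_min, theta_s0 > 0, E_ref > 0)
  structure(list(theta_min = theta_min, theta_max = theta_max,
                 theta_s0 = theta_s0, E_ref = E_ref),
            class = "las_angular_model")
}

#' Slope of the large-angle angular density at energy E
#' @keywords internal
las_theta_s <- function(model, E) {
  pmax(1e-3, model$theta_s0 * model$E_ref / E)
}

#' Analytic CDF of the large-angle deflection distribution
#'
#' @param theta Deflection angles (rad).
#' @param E Proton kinetic energy (MeV).
#' @param model A [las_angular_model()].
#' @return CDF values in `[0, 1]`.
#' @export
las_angle_cdf <- function(theta, E, model = las_angular_model()) {
  s <- las_theta_s(model, E)
  th <- pmin(pmax(theta, model$theta_min), model$theta_max)
  num <- 1 - exp(-(th - model$theta_min) / s)
  den <- 1 - exp(-(model$theta_max - model$theta_min) / s)
  num / den
}

#' Sample large-angle-scattering deflections
#'
#' Inverse-CDF sampling of the truncated exponential polar angle and a
#' uniform azimuth. Uses R's RNG stream (set a seed for reproducibility).
#'
#' @param E Proton kinetic energy (MeV), scalar.
#' @param n Number of draws.
#' @param model A [las_angular_model()].
#' @return A data.frame with columns `theta` and `phi` (rad).
#' @export
sample_las_angle <- function(E, n = 1, model = las_angular_model()) {
  s <- las_theta_s(model, E)
  u <- stats::runif(n)
  den <- 1 - exp(-(model$theta_max - model$theta_min) / s)
  theta <- model$theta_min - s * log(1 - u * den)
  phi <- stats::runif(n, 0, 2 * pi)
  data.frame(theta = theta, phi = phi)
}

#' Proton energy after an elastic collision
#'
#' Classical two-body elastic kinematics. Hydrogen target (equal masses):
#' `E' = E * cos^2(theta_lab)`, defined for `theta_lab < pi/2`. Oxygen
#' target: the centre-of-mass angle follows from
#' `theta_cm = theta_lab + asin(r * sin(theta_lab))` with `r = m_p/m_O`, and
#' `E' = E * (1 - K * sin^2(theta_cm / 2))` with
#' `K = 4 m_p m_O / (m_p + m_O)^2`.
#'
#' @param E Kinetic energy before the collision (MeV).
#' @param theta_lab Laboratory deflection angle (rad), `>= 0`.
#' @param target `"hydrogen"` or `"oxygen"`.
#' @param const Physics constants.
#' @return Kinetic energy after the collision (MeV), `<= E`.
#' @export
post_scatter_energy <- function(E, theta_lab, target = c("hydrogen", "oxygen"),
                                const = physics_constants()) {
  target <- match.arg(target)
  if (any(theta_lab < 0)) stop("scattering angle must be >= 0")
  if (target == "hydrogen") {
    if (any(theta_lab >= pi / 2)) {
      stop("hydrogen target: lab angle >= pi/2 is kinematically forbidden")
    }
    E * cos(theta_lab)^2
  } else {
    r <- const$m_proton / const$m_oxygen
    theta_cm <- theta_lab + asin(r * sin(theta_lab))
    K <- 4 * const$m_proton * const$m_oxygen /
      (const$m_proton + const$m_oxygen)^2
    E * (1 - K * sin(theta_cm / 2)^2)
  }
}
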