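test_that("range-energy model is a consistent closed form with exact inverse", {
  m <- range_energy_model()
  expect_equal(range_from_energy(0, m), 0)
  expect_equal(energy_from_range(0, m), 0)
  # direct evaluation of the power law with explicit parameters
  m2 <- range_energy_model(alpha = 0.0022, p = 1.77)
  expect_equal(range_from_energy(100, m2), 0.0022 * 100^1.77)
  # round trips
  for (E in c(1, 70, 150, 230)) {
    expect_equal(energy_from_range(range_from_energy(E, m), m), E,
                 tolerance = 1e-9)
  }
  expect_error(range_from_energy(-1, m), "0")
  expect_error(energy_from_range(-1, m), "0")
})

test_that("tabulated range-energy override interpolates and inverts", {
  m <- range_energy_model()
  E <- seq(1, 300, by = 1)
  tb <- data.frame(energy = E, range = range_from_energy(E, m))
  mt <- range_energy_model(table = tb)
  expect_equal(range_from_energy(150, mt), range_from_energy(150, m),
               tolerance = 1e-4)
  expect_equal(energy_from_range(21, mt), energy_from_range(21, m),
               tolerance = 1e-3)
  expect_equal(energy_from_range(range_from_energy(77.3, mt), mt), 77.3,
               tolerance = 1e-6)
})

test_that("MCS sigma matches an independent re-evaluation of the formula", {
  # oracle: kinematics computed separately from the implementation
  E <- 178.2; dLw <- 1; X0 <- 36.08
  m_p <- 938.27208816
  gamma <- (E + m_p) / m_p
  beta <- sqrt(1 - 1 / gamma^2)
  p_mom <- gamma * m_p * beta
  t <- dLw / X0
  oracle <- 13.6 / (beta * p_mom) * sqrt(t) * (1 + 0.088 * log10(t))
  expect_equal(mcs_sigma(E, dLw), oracle, tolerance = 1e-12)

  expect_equal(mcs_sigma(E, 0), 0)
  # monotone in step length across a decade
  sig <- mcs_sigma(E, c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6))
  expect_false(is.unsorted(sig))
  # bracket clamps at zero for absurdly thin steps
  expect_gte(mcs_sigma(E, 1e-14), 0)
  expect_error(mcs_sigma(-5, 1), "> 0")
})

test_that("correction factors reproduce the anchor table and interpolate", {
  fac <- correction_factors()
  at <- interp_correction_factors(fac, c(10, 100, 250))
  expect_identical(at$F_pH, c(3.0, 8.0, 17))
  expect_identical(at$F_pO, c(1.0, 1.0, 1.0))
  # hand linear interpolation between (100, 8) and (250, 17)
  expect_equal(interp_correction_factors(fac, 175)$F_pH, 12.5)
  # clamped outside the anchors
  expect_equal(interp_correction_factors(fac, 5)$F_pH, 3.0)
  expect_equal(interp_correction_factors(fac, 400)$F_pH, 17)
  # continuity at an anchor
  eps <- 1e-9
  expect_equal(interp_correction_factors(fac, 100 - eps)$F_pH,
               interp_correction_factors(fac, 100 + eps)$F_pH,
               tolerance = 1e-6)
})

test_that("adjusted LAS cross-section combines channels per water stoichiometry", {
  xs <- cross_section_table(c(50, 100, 200), c(0.05, 0.04, 0.03),
                            c(0.40, 0.35, 0.25))
  fac <- correction_factors()
  # at 100 MeV: 2 * 8 * 0.04 + 1 * 0.35
  expect_equal(las_total_cross_section(100, xs, fac), 2 * 8 * 0.04 + 0.35)
  # zero cross-sections give a zero channel
  expect_equal(las_total_cross_section(100, zero_xs(), fac), 0)
  # clamped lookup warns outside coverage
  expect_warning(las_total_cross_section(10, xs, fac), "clamp")
})

test_that("LAS probability is the number-density formula, linear, clamped", {
  # hand evaluation: 3.343e22 cm^-3 molecules x 1 cm x 1e-24 cm^2
  expect_equal(las_probability(1, 1), 6.02214076e23 / 18.015 * 1e-24,
               tolerance = 1e-12)
  expect_equal(las_probability(0, 5), 0)
  expect_equal(las_probability(0.4, 2), 2 * las_probability(0.2, 2))
  expect_equal(las_probability(0.2, 4), 2 * las_probability(0.2, 2))
  expect_equal(las_probability(1e6, 1), 1)  # clamped
})

test_that("sampled LAS angles live on the support and match the analytic CDF", {
  model <- las_angular_model()
  set.seed(7)
  n <- 1e5
  draws <- sample_las_angle(178.2, n, model)
  expect_true(all(draws$theta >= model$theta_min))
  expect_true(all(draws$theta <= model$theta_max))
  expect_true(all(draws$phi >= 0 & draws$phi < 2 * pi))

  # Kolmogorov-Smirnov distance against the analytic truncated-exponential CDF
  th <- sort(draws$theta)
  emp <- seq_len(n) / n
  ks <- max(abs(emp - las_angle_cdf(th, 178.2, model)))
  expect_lt(ks, 0.01)

  # azimuth uniformity: chi-square over 36 bins not rejected at alpha = 0.01
  counts <- table(cut(draws$phi, breaks = seq(0, 2 * pi, length.out = 37)))
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.01)
})

test_that("post-scatter energy follows two-body elastic kinematics", {
  expect_equal(post_scatter_energy(178.2, 0, "hydrogen"), 178.2)
  expect_equal(post_scatter_energy(178.2, 0, "oxygen"), 178.2)
  expect_equal(post_scatter_energy(200, pi / 4, "hydrogen"), 100)
  expect_error(post_scatter_energy(200, pi / 2, "hydrogen"), "forbidden")

  # oracle: classical conservation-law solver for the oxygen target
  cst <- physics_constants()
  two_body <- function(E, theta_lab) {
    v0 <- sqrt(2 * E / cst$m_proton)          # classical speed units
    f <- function(v1) {
      # recoil momentum from vector conservation, then energy balance
      px <- cst$m_proton * (v0 - v1 * cos(theta_lab))
      py <- -cst$m_proton * v1 * sin(theta_lab)
      T_recoil <- (px^2 + py^2) / (2 * cst$m_oxygen)
      E - 0.5 * cst$m_proton * v1^2 - T_recoil
    }
    v1 <- stats::uniroot(f, c(1e-9, v0), tol = 1e-14)$root
    0.5 * cst$m_proton * v1^2
  }
  for (th in c(0.05, 10 * pi / 180, 0.5, 1.2)) {
    expect_equal(post_scatter_energy(178.2, th, "oxygen"),
                 two_body(178.2, th), tolerance = 1e-6)
  }

  # energy never increases, any channel, any angle
  set.seed(3)
  th_h <- stats::runif(200, 0, pi / 2 - 1e-6)
  th_o <- stats::runif(200, 0, pi)
  expect_true(all(post_scatter_energy(150, th_h, "hydrogen") <= 150))
  expect_true(all(post_scatter_energy(150, th_o, "oxygen") <= 150))
})

test_that("matched energy spread maps back onto the range straggle", {
  m <- range_energy_model()
  E <- 178.2
  sE <- energy_spread_for_straggle(E, m, 0.011)
  dR <- range_from_energy(E + sE, m) - range_from_energy(E, m)
  expect_equal(dR, 0.011 * range_from_energy(E, m), tolerance = 1e-2)
})

test_that("cross-section table round-trips through CSV", {
  xs <- default_cross_sections(seq(10, 250, by = 20))
  path <- tempfile(fileext = ".csv")
  write_cross_sections(xs, path)
  back <- read_cross_sections(path)
  expect_equal(back$energies, xs$energies)
  expect_equal(back$sigma_pH, xs$sigma_pH)
  expect_equal(back$sigma_pO, xs$sigma_pO)
})

test_that("correction factors round-trip through YAML", {
  fac <- correction_factors()
  path <- tempfile(fileext = ".yaml")
  write_correction_factors(fac, path)
  back <- read_correction_factors(path)
  expect_equal(back$anchors, fac$anchors)
  expect_equal(back$F_pH, fac$F_pH)
  expect_equal(back$F_pO, fac$F_pO)
})
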