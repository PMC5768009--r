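#' Pencil-beam phase space (double-Gaussian beam optics)
#'
#' Per-spot beam optics as a mixture of up to two Gaussian components. Each
#' component carries, per transverse plane, a 2x2 sigma matrix
#' `[sigma_x^2, cov; cov, sigma_theta^2]` (position spread mm, angular
#' spread rad, position-angle covariance mm*rad). The same optics are used
#' for the x and y planes.
#'
#' @param energy Nominal kinetic energy (MeV).
#' @param sigma_x Position spread (mm) of component 1.
#' @param sigma_theta Angular spread (rad) of component 1.
#' @param cov_x_theta Position-angle covariance (mm*rad) of component 1.
#' @param weight2 Weight of the second Gaussian component in `[0, 1)`
#'   (component weights sum to 1).
#' @param sigma_x2,sigma_theta2,cov_x_theta2 Second-component parameters.
#' @param energy_spread Gaussian sigma of the kinetic energy (MeV); 0 for a
#'   mono-energetic beam.
#' @return An object of class `phase_space`.
#' @export
phase_space <- function(energy, sigma_x = 4, sigma_theta = 0.003,
                        cov_x_theta = 0, weight2 = 0, sigma_x2 = 0,
                        sigma_theta2 = 0, cov_x_theta2 = 0,
                        energy_spread = 0) {
  stopifnot(energy > 0, sigma_x >= 0, sigma_theta >= 0,
            weight2 >= 0, weight2 < 1, sigma_x2 >= 0, sigma_theta2 >= 0,
            energy_spread >= 0)
  comp <- function(sx, st, cxt) {
    S <- matrix(c(sx^2, cxt, cxt, st^2), 2, 2)
    if (det(S) < -1e-12 * max(1e-300, sx^2 * st^2)) {
      stop("sigma matrix must be positive semi-definite")
    }
    S
  }
  structure(list(energy = energy,
                 weights = c(1 - weight2, weight2),
                 sigma = list(comp(sigma_x, sigma_theta, cov_x_theta),
                              comp(sigma_x2, sigma_theta2, cov_x_theta2)),
                 energy_spread = energy_spread),
            class = "phase_space")
}

#' @export
print.phase_space <- function(x, ...) {
  cat(sprintf("Phase space: E = %g MeV (sigma_E = %g)\n", x$energy,
              x$energy_spread))
  for (g in 1:2) {
    if (x$weights[g] > 0) {
      S <- x$sigma[[g]]
      cat(sprintf("  component %d: w = %.3f, sigma_x = %.3g mm, sigma_theta = %.3g rad, cov = %.3g\n",
                  g, x$weights[g], sqrt(S[1, 1]), sqrt(S[2, 2]), S[1, 2]))
    }
  }
  invisible(x)
}

#' Scanning spot plan
#'
#' A list of pencil-beam spots (lateral position at the isocenter plane,
#' energy, relative weight) plus the source-axis distance and per-energy
#' phase spaces. The isocenter plane is taken at the phantom entrance face
#' (z = 0) unless stated otherwise.
#'
#' @param spots data.frame with columns `x`, `y` (mm), `energy` (MeV),
#'   `weight` (`>= 0`).
#' @param phase_space List of [phase_space()] objects covering every energy
#'   appearing in `spots` (matched by energy).
#' @param sad Source-axis distance (mm); the virtual source sits this far
#'   upstream of the isocenter plane.
#' @param z_entry Phantom entry plane z (mm).
#' @return An object of class `spot_plan`.
#' @export
spot_plan <- function(spots, phase_space, sad = 2500, z_entry = 0) {
  stopifnot(is.data.frame(spots),
            all(c("x", "y", "energy", "weight") %in% names(spots)),
            all(spots$weight >= 0), sad > 0)
  ps_energies <- vapply(phase_space, function(p) p$energy, numeric(1))
  missing_e <- setdiff(unique(spots$energy), ps_energies)
  if (length(missing_e)) {
    stop("no phase space supplied for energies: ",
         paste(missing_e, collapse = ", "))
  }
  structure(list(spots = spots, phase_space = phase_space, sad = sad,
                 z_entry = z_entry),
            class = "spot_plan")
}

#' @export
print.spot_plan <- function(x, ...) {
  cat(sprintf("Spot plan: %d spots, %d energy layer(s), SAD = %g mm\n",
              nrow(x$spots), length(unique(x$spots$energy)), x$sad))
  for (e in sort(unique(x$spots$energy))) {
    sel <- x$spots$energy == e
    cat(sprintf("  E = %g MeV: %d spots, total weight %g\n", e, sum(sel),
                sum(x$spots$weight[sel])))
  }
  invisible(x)
}

# phase space matched to a spot energy
.plan_ps <- function(plan, energy) {
  for (p in plan$phase_space) if (p$energy == energy) return(p)
  stop("no phase space for energy ", energy)
}

#' Sample initial particle states for one spot
#'
#' Each particle picks a Gaussian component by weight, draws a transverse
#' position/angle pair per plane from that component's sigma matrix, and is
#' tilted so its mean ray passes through the virtual source at distance SAD
#' upstream (divergence `x/SAD`, `y/SAD`). Initial residual range is
#' `range_from_energy(E)`; projected water-equivalent depth starts at 0.
#' Uses R's RNG stream.
#'
#' @param spot One-row data.frame (or list) with `x`, `y`, `energy`.
#' @param ps A [phase_space()].
#' @param n Number of particles, `>= 1`.
#' @param sad Source-axis distance (mm).
#' @param model A [range_energy_model()] for the initial residual range.
#' @param z_entry Entry plane z (mm).
#' @return Matrix with columns `x, y, z, ux, uy, uz, R0` (mm, unit vector,
#'   g/cm^2).
#' @export
sample_particles <- function(spot, ps, n, sad = 2500,
                             model = range_energy_model(), z_entry = 0) {
  if (n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  comp <- sample.int(2, n, replace = TRUE, prob = ps$weights)
  xpos <- numeric(n); ypos <- numeric(n)
  thx <- numeric(n); thy <- numeric(n)
  for (g in 1:2) {
    idx <- which(comp == g)
    if (!length(idx)) next
    S <- ps$sigma[[g]]
    L <- if (all(S == 0)) matrix(0, 2, 2) else {
      ev <- eigen(S, symmetric = TRUE)
      ev$vectors %*% diag(sqrt(pmax(0, ev$values)), 2) %*% t(ev$vectors)
    }
    zx <- matrix(stats::rnorm(2 * length(idx)), 2)
    zy <- matrix(stats::rnorm(2 * length(idx)), 2)
    px <- L %*% zx; py <- L %*% zy
    xpos[idx] <- px[1, ]; thx[idx] <- px[2, ]
    ypos[idx] <- py[1, ]; thy[idx] <- py[2, ]
  }
  x0 <- spot$x + xpos
  y0 <- spot$y + ypos
  # mean direction through the virtual source: divergence x/SAD, y/SAD
  tx <- spot$x / sad + thx
  ty <- spot$y / sad + thy
  nrm <- sqrt(tx^2 + ty^2 + 1)
  E <- rep(spot$energy, n)
  if (ps$energy_spread > 0) {
    E <- pmax(1e-3, E + stats::rnorm(n, 0, ps$energy_spread))
  }
  cbind(x = x0, y = y0, z = rep(z_entry, n),
        ux = tx / nrm, uy = ty / nrm, uz = 1 / nrm,
        R0 = range_from_energy(E, model))
}

#' Build a single-energy scanned-field plan
#'
#' Rectangular grid of equally weighted spots centred on the beam axis,
#' spot positions inclusive of both field edges (a 50 mm field at 5 mm
#' spacing gives 11 spot positions per axis).
#'
#' @param field_size Field side length (mm); 0 gives a single central spot.
#' @param spot_spacing Spot spacing (mm), `> 0`.
#' @param energy Beam energy (MeV).
#' @param phase_space A [phase_space()] for that energy (default optics if
#'   omitted).
#' @param sad Source-axis distance (mm).
#' @return A [spot_plan()].
#' @export
build_scanned_field <- function(field_size, spot_spacing = 5, energy,
                                phase_space = NULL, sad = 2500) {
  stopifnot(field_size >= 0, spot_spacing > 0, energy > 0)
  half <- field_size / 2
  pos <- if (field_size == 0) 0 else {
    k <- floor(half / spot_spacing + 1e-9)
    seq(-k, k) * spot_spacing
  }
  spots <- expand.grid(x = pos, y = pos)
  spots$energy <- energy
  spots$weight <- 1
  if (is.null(phase_space)) phase_space <- smcdose::phase_space(energy = energy)
  spot_plan(spots, list(phase_space), sad = sad)
}

#' Build a spread-out-Bragg-peak (SOBP) plan
#'
#' Energy layers are spaced so that their Bragg peaks span
#' `[range_max - sobp_width, range_max]`; per-layer weights are solved by
#' non-negative least squares so that the laterally integrated depth dose
#' (IDD superposition, the central-axis dose of a broad field) is flat over
#' the SOBP plateau. If the achieved flatness exceeds `flatness_target` a
#' warning reports the achieved value.
#'
#' @param range_max Distal range (g/cm^2).
#' @param sobp_width SOBP width (g/cm^2), `< range_max`; 0 gives a
#'   single-layer plan.
#' @param field_size Field side length (mm).
#' @param spot_spacing Spot spacing (mm).
#' @param n_layers Number of energy layers (`>= 2` unless `sobp_width` is 0).
#' @param model A [range_energy_model()].
#' @param make_idd Function `(E) -> idd_table` supplying per-layer depth
#'   doses for the weight solve (default [generate_synthetic_idd()]).
#' @param phase_space_fn Function `(E) -> phase_space` (default optics).
#' @param sad Source-axis distance (mm).
#' @param flatness_target Relative plateau flatness objective (default 2%).
#' @return A [spot_plan()] with attributes `layers` (data.frame of energy,
#'   range, weight) and `flatness` (achieved relative plateau deviation).
#' @export
build_sobp_plan <- function(range_max, sobp_width, field_size = 100,
                            spot_spacing = 5, n_layers = 15,
                            model = range_energy_model(),
                            make_idd = NULL, phase_space_fn = NULL,
                            sad = 2500, flatness_target = 0.02) {
  stopifnot(range_max > 0, sobp_width >= 0, sobp_width < range_max)
  if (is.null(make_idd)) make_idd <- function(E) generate_synthetic_idd(E, model)
  if (is.null(phase_space_fn)) {
    phase_space_fn <- function(E) phase_space(energy = E)
  }
  if (sobp_width == 0) {
    ranges <- range_max
  } else {
    if (n_layers < 2) stop("need >= 2 energy layers for a non-zero SOBP width")
    ranges <- seq(range_max - sobp_width, range_max, length.out = n_layers)
  }
  energies <- energy_from_range(ranges, model)
  idds <- lapply(energies, make_idd)
  # flatness solve on the plateau (margins of half a layer spacing)
  if (length(ranges) > 1) {
    margin <- (ranges[2] - ranges[1]) / 2
    zp <- seq(range_max - sobp_width + margin, range_max - margin,
              by = 0.05)
    A <- vapply(idds, function(tb) lookup(tb, zp), numeric(length(zp)))
    fit <- pracma::lsqnonneg(A, rep(1, length(zp)))
    w <- fit$x
    d <- as.numeric(A %*% w)
    flat <- (max(d) - min(d)) / (2 * mean(d))
    if (flat > flatness_target) {
      warning(sprintf("SOBP plateau flatness %.2f%% exceeds the %.2f%% target",
                      100 * flat, 100 * flatness_target))
    }
  } else {
    w <- 1
    flat <- 0
  }
  half <- field_size / 2
  pos <- if (field_size == 0) 0 else {
    k <- floor(half / spot_spacing + 1e-9)
    seq(-k, k) * spot_spacing
  }
  spots_list <- lapply(seq_along(energies), function(i) {
    g <- expand.grid(x = pos, y = pos)
    g$energy <- energies[i]
    g$weight <- w[i]
    g
  })
  spots <- do.call(rbind, spots_list)
  spots <- spots[spots$weight > 0, , drop = FALSE]
  keep <- unique(spots$energy)
  plan <- spot_plan(spots,
                    lapply(keep, phase_space_fn),
                    sad = sad)
  attr(plan, "layers") <- data.frame(energy = energies, range = ranges,
                                     weight = w)
  attr(plan, "flatness") <- flat
  plan
}

#' Read / write spot lists as CSV and plans as YAML
#'
#' Spot CSV columns: `x`, `y` (mm), `energy` (MeV), `weight`.
#'
#' @param path File path.
#' @param plan A [spot_plan()].
#' @export
read_spots_csv <- function(path) utils::read.csv(path)

#' @rdname read_spots_csv
#' @export
write_spots_csv <- function(plan, path) {
  utils::write.csv(plan$spots, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_spots_csv
#' @export
write_plan_yaml <- function(plan, path) {
  ps <- lapply(plan$phase_space, function(p) {
    list(energy = p$energy, weights = p$weights,
         sigma1 = as.vector(p$sigma[[1]]), sigma2 = as.vector(p$sigma[[2]]),
         energy_spread = p$energy_spread)
  })
  yaml::write_yaml(list(sad = plan$sad, z_entry = plan$z_entry,
                        spots = lapply(seq_len(nrow(plan$spots)), function(i)
                          as.list(plan$spots[i, ])),
                        phase_space = ps), path)
  invisible(path)
}

#' @rdname read_spots_csv
#' @export
read_plan_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  spots <- do.call(rbind, lapply(y$spots, as.data.frame))
  ps <- lapply(y$phase_space, function(p) {
    s1 <- matrix(as.numeric(p$sigma1), 2, 2)
    s2 <- matrix(as.numeric(p$sigma2), 2, 2)
    phase_space(energy = p$energy,
                sigma_x = sqrt(s1[1, 1]), sigma_theta = sqrt(s1[2, 2]),
                cov_x_theta = s1[1, 2], weight2 = p$weights[2],
                sigma_x2 = sqrt(s2[1, 1]), sigma_theta2 = sqrt(s2[2, 2]),
                cov_x_theta2 = s2[1, 2],
                energy_spread = p$energy_spread)
  })
  spot_plan(spots, ps, sad = y$sad, z_entry = y$z_entry)
}
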