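# shared fixtures: built in code, kept small so the default suite stays fast

# a zero-emittance single-spot plan on the beam axis
pencil_plan <- function(E, energy_spread = 0) {
  spot_plan(data.frame(x = 0, y = 0, energy = E, weight = 1),
            list(phase_space(E, sigma_x = 0, sigma_theta = 0,
                             energy_spread = energy_spread)))
}

# cross-section table that switches the large-angle channel off entirely
zero_xs <- function() cross_section_table(c(1, 300), c(0, 0), c(0, 0))

# physics with every stochastic deflection disabled: straight-line transport
straightline_physics <- function() {
  transport_physics(xs = zero_xs(), mcs_scale = 0)
}

# small water phantom for transport tests (mm)
small_water <- function(extent = c(60, 60, 240), voxel = 2) {
  build_water_phantom(extent, voxel)
}

# brute-force gamma oracle: exhaustive search over all reference points,
# no interpolation -- the independent check for the compiled search
gamma_brute_force <- function(eval_dose, ref_dose, ex, ez, rx, rz,
                              tol_abs, dta) {
  out <- matrix(NA_real_, nrow(eval_dose), ncol(eval_dose))
  for (i in seq_along(ex)) {
    for (k in seq_along(ez)) {
      d2 <- outer((rx - ex[i])^2, (rz - ez[k])^2, "+") / dta^2
      dd2 <- ((ref_dose - eval_dose[i, k]) / tol_abs)^2
      out[i, k] <- sqrt(min(d2 + dd2))
    }
  }
  out
}
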