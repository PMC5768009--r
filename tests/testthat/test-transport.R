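test_that("projected depth bookkeeping follows the half-step convention", {
  # straight axial track: scoring depth is the step midpoint
  pd <- project_depth(c(0.2, 0.2, 0.2), c(1, 1, 1))
  expect_equal(pd$score, c(0.1, 0.3, 0.5))
  expect_equal(pd$final, 0.6)

  # constant 60 degrees: each full step contributes dLw/2
  pd2 <- project_depth(c(0.2, 0.2), c(0.5, 0.5))
  expect_equal(pd2$final, 0.2)

  # hand-summed zig-zag
  pd3 <- project_depth(c(0.3, 0.2), c(1, 0.5))
  expect_equal(pd3$score, c(0.15, 0.3 + 0.05))
  expect_equal(pd3$final, 0.4)

  # alternative cos^2 reading of the in-progress term
  pd4 <- project_depth(c(0.3, 0.2), c(1, 0.5), convention = "cos2")
  expect_equal(pd4$score, c(0.3, 0.3 + 0.2 * 0.25))
  expect_equal(pd4$final, 0.4)
})

test_that("deterministic straight-line limit scores dose per the table ratio", {
  phys <- straightline_physics()
  E <- 118
  idd <- generate_synthetic_idd(E)
  ph <- small_water(c(20, 20, 140), 2)
  d <- run_simulation(pencil_plan(E), ph, phys, list(idd), n_particles = 1,
                      seed = 1, mode = "conventional")
  add <- extract_add(d, c(0, 0))
  # every step has dLw = 0.2 g/cm2; dose ratio between depths equals the
  # table ratio at the half-step projected depths
  k1 <- 10; k2 <- 40
  lw <- function(k) (k - 0.5) * 0.2
  expect_equal(add$values[k1] / add$values[k2],
               lookup(idd, lw(k1)) / lookup(idd, lw(k2)), tolerance = 1e-9)
  # off-axis voxels get nothing
  expect_equal(sum(d$dose) * prod(ph$grid$spacing) / 1000,
               sum(add$values) * prod(ph$grid$spacing) / 1000)
  # track ends at the range: no dose beyond range + cutoff margin
  R0 <- range_from_energy(E)
  expect_equal(max(which(add$values > 0)), ceiling(10 * R0 / 2), tolerance = 1)
})

test_that("water-equivalent ratio scales the range geometrically", {
  phys <- straightline_physics()
  E <- 118
  R0 <- range_from_energy(E)
  zt <- seq(0, R0 + 2, by = 0.1)
  unit <- idd_table(E, zt, rep(1, length(zt)))

  # water: track length ~ R0 (cm) -> 10 R0 mm of depth
  ph_w <- small_water(c(20, 20, 160), 2)
  dw <- run_simulation(pencil_plan(E), ph_w, phys, list(unit), 1, seed = 1)
  zw <- max(which(extract_add(dw)$values > 0)) * 2

  # insert a 30 mm air-like slab: geometric range extends by ~30 mm
  spec <- phantom_spec(c(20, 20, 160), list(
    list(lo = c(-10, -10, 20), hi = c(10, 10, 50), wer = 0.001)))
  ph_a <- build_slab_phantom(spec, 2)
  da <- run_simulation(pencil_plan(E), ph_a, phys, list(unit), 1, seed = 1)
  za <- max(which(extract_add(da)$values > 0)) * 2
  expect_equal(za - zw, 30, tolerance = 2.1)

  # a bone slab (WER 2) of 30 mm shortens it by ~30 mm
  spec_b <- phantom_spec(c(20, 20, 160), list(
    list(lo = c(-10, -10, 20), hi = c(10, 10, 50), wer = 2)))
  ph_b <- build_slab_phantom(spec_b, 2)
  db <- run_simulation(pencil_plan(E), ph_b, phys, list(unit), 1, seed = 1)
  zb <- max(which(extract_add(db)$values > 0)) * 2
  expect_equal(zw - zb, 30, tolerance = 2.1)
})

test_that("runs are bitwise reproducible for a fixed seed", {
  idd <- generate_synthetic_idd(118)
  ph <- small_water()
  plan <- build_scanned_field(20, 10, 118)
  d1 <- run_simulation(plan, ph, tables = list(idd), n_particles = 2000,
                       seed = 42, mode = "modified")
  d2 <- run_simulation(plan, ph, tables = list(idd), n_particles = 2000,
                       seed = 42, mode = "modified")
  expect_identical(d1$dose, d2$dose)
  d3 <- run_simulation(plan, ph, tables = list(idd), n_particles = 2000,
                       seed = 43, mode = "modified")
  expect_false(identical(d1$dose, d3$dose))
})

test_that("zero histories give a zero dose grid", {
  idd <- generate_synthetic_idd(118)
  ph <- small_water()
  d <- run_simulation(pencil_plan(118), ph, tables = list(idd),
                      n_particles = 0, seed = 1)
  expect_true(all(d$dose == 0))
})

test_that("a missing table is a configuration error before any tracking", {
  ph <- small_water()
  idd <- generate_synthetic_idd(118)
  expect_error(run_simulation(pencil_plan(178.2), ph, tables = list(idd),
                              n_particles = 10, seed = 1),
               "no depth-dose table")
})

test_that("conventional-mode lateral profile is a single Gaussian", {
  E <- 178.2
  idd <- generate_synthetic_idd(E)
  ph <- build_water_phantom(c(120, 120, 240), 2)
  plan <- build_scanned_field(0, 5, E)  # default 4 mm sigma optics
  d <- run_simulation(plan, ph, tables = list(idd), n_particles = 5e4,
                      seed = 17, mode = "conventional")
  ocr <- extract_ocr(d, depth = 104)
  w <- ocr$values > 0
  df <- data.frame(x = ocr$coordinates[w], y = ocr$values[w])
  fit <- stats::nls(y ~ A * exp(-(x - mu)^2 / (2 * sg^2)), data = df,
                    start = list(A = max(df$y), mu = 0, sg = 6))
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((df$y - mean(df$y))^2)
  expect_gt(r2, 0.99)
})

test_that("the halo channel adds lateral dose the conventional mode lacks", {
  E <- 178.2
  idd <- generate_synthetic_idd(E)
  s <- estimate_survival(E, n_histories = 2e4, seed = 23)
  midd <- convert_idd_to_midd(idd, s)
  ph <- build_water_phantom(c(120, 120, 240), 2)
  plan <- build_scanned_field(0, 5, E)
  don <- run_simulation(plan, ph, tables = list(midd), n_particles = 3e4,
                        seed = 29, mode = "modified")
  doff <- run_simulation(plan, ph, tables = list(idd), n_particles = 3e4,
                         seed = 29, mode = "conventional")
  g <- ph$grid
  xc <- g$origin[1] + (seq_len(g$n[1]) - 0.5) * g$spacing[1]
  yc <- g$origin[2] + (seq_len(g$n[2]) - 0.5) * g$spacing[2]
  rr <- sqrt(outer(xc^2, yc^2, "+"))
  ann <- rr >= 30 & rr <= 45
  k <- 52  # ~ mid range
  expect_gt(mean(don$dose[, , k][ann]), mean(doff$dose[, , k][ann]))
  # dose is non-negative and finite everywhere
  expect_true(all(don$dose >= 0))
  expect_true(all(is.finite(don$dose)))
})
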