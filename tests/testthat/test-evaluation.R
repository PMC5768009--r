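test_that("profiles are extracted from the stated column and plane", {
  g <- voxel_grid(c(11, 11, 20), c(2, 2, 2), c(-11, -11, 0))
  dose <- array(0, dim = g$n)
  dose[6, 6, ] <- seq_len(20)
  dg <- structure(list(grid = g, dose = dose, n_particles = 1L,
                       mode = "conventional", seed = 1L, cutoff = 0.1),
                  class = "dose_grid")
  add <- extract_add(dg, c(0, 0))
  expect_equal(add$values, seq_len(20))
  expect_equal(add$coordinates, seq(1, 39, by = 2))
  ocr <- extract_ocr(dg, depth = 9)
  expect_equal(which(ocr$values > 0), 6)
  expect_equal(ocr$values[6], 5)
  expect_error(extract_add(dg, c(100, 0)), "outside")
  # zero grid gives an all-zero profile
  dg$dose[] <- 0
  expect_true(all(extract_add(dg)$values == 0))
})

test_that("scanned-field profiles are symmetric with a flat centre", {
  E <- 118
  idd <- generate_synthetic_idd(E)
  ph <- build_water_phantom(c(140, 140, 130), 2)
  plan <- build_scanned_field(50, 5, E)
  d <- run_simulation(plan, ph, tables = list(idd), n_particles = 1e5,
                      seed = 37, mode = "conventional")
  # ADD symmetry between mirrored columns, within MC error
  a1 <- extract_add(d, c(10, 0))
  a2 <- extract_add(d, c(-10, 0))
  sel <- a1$values > 0.2 * max(a1$values)
  expect_lt(median(abs(a1$values[sel] - a2$values[sel]) /
                     a1$values[sel]), 0.15)
  # OCR flat over the central half of the field (coefficient of variation),
  # mirror-symmetric in the mean
  ocr <- extract_ocr(d, depth = 50)
  ctr <- abs(ocr$coordinates) <= 12.5
  # smooth over one spot spacing (5 voxels) before judging flatness, so the
  # check sees the field structure rather than per-voxel counting noise
  sm <- stats::filter(ocr$values, rep(1 / 5, 5), sides = 2)
  expect_lt(stats::sd(sm[ctr]) / mean(sm[ctr]), 0.06)
  v <- ocr$values
  expect_lt(abs(mean(v[ctr]) - mean(rev(v)[ctr])) / mean(v[ctr]), 0.03)
  # broad-beam ADD peaks at the table's peak depth within one voxel:
  # the default 4 mm optics keep the column fluence near-constant so the
  # axial profile follows the table
  dp <- run_simulation(build_scanned_field(0, 5, E), ph, tables = list(idd),
                       n_particles = 5e4, seed = 41, mode = "conventional")
  addp <- extract_add(dp, c(0, 0))
  zpk <- addp$coordinates[which.max(addp$values)]
  expect_lt(abs(zpk - 10 * range_from_energy(E)), 4.1)
})

test_that("gamma of identical distributions is zero with full pass rate", {
  set.seed(51)
  A <- matrix(stats::runif(900, 0.5, 1), 30, 30)
  x <- seq(0, 29); z <- seq(0, 29)
  g <- gamma_index_2d(A, A, x, z, crit = gamma_criteria())
  expect_true(all(g$gamma[!is.na(g$gamma)] == 0))
  expect_equal(pass_rate(g), 100)
})

test_that("a uniform one-percent offset passes 2%/2mm with gamma <= 0.5", {
  x <- seq(0, 49); z <- seq(0, 49)
  ref <- matrix(1, 50, 50)
  ev <- ref * 1.01
  g <- gamma_index_2d(ev, ref, x, z, crit = gamma_criteria())
  expect_true(all(g$gamma[!is.na(g$gamma)] <= 0.5 + 1e-12))
  expect_equal(pass_rate(g), 100)
})

test_that("compiled gamma equals the exhaustive brute-force oracle", {
  # steep-gradient slab shifted by 3 mm: failures concentrate on the edge
  x <- seq(0, 49); z <- seq(0, 49)
  slab <- function(shift) {
    outer(rep(1, 50), 1 / (1 + exp(-(z - 25 - shift) / 1.5)))
  }
  ref <- slab(0); ev <- slab(3)
  crit <- gamma_criteria(2, 2, 20, normalization = "max")
  g <- gamma_index_2d(ev, ref, x, z, crit = crit, interp_factor = 1,
                      search_factor = Inf)
  oracle <- gamma_brute_force(ev, ref, x, z, x, z,
                              0.02 * max(ref), 2)
  thr <- 0.2 * max(ref)
  oracle[ev < thr] <- NA
  expect_lt(max(abs(g$gamma - oracle), na.rm = TRUE), 1e-6)
  expect_lt(pass_rate(g), 100)
  # failures sit on the gradient
  fails <- which(g$gamma > 1, arr.ind = TRUE)
  expect_true(all(abs(fails[, 2] - 26) < 12))

  # random fields, parameterised over criteria
  set.seed(77)
  for (rep in 1:3) {
    ev2 <- matrix(stats::runif(400), 20, 20)
    rf2 <- matrix(stats::runif(400), 20, 20)
    crit2 <- gamma_criteria(3, 2.5, 10)
    g2 <- gamma_index_2d(ev2, rf2, seq(0, 19), seq(0, 19), crit = crit2,
                         interp_factor = 1, search_factor = Inf)
    o2 <- gamma_brute_force(ev2, rf2, seq(0, 19), seq(0, 19),
                            seq(0, 19), seq(0, 19), 0.03 * max(rf2), 2.5)
    o2[ev2 < 0.1 * max(rf2)] <- NA
    expect_lt(max(abs(g2$gamma - o2), na.rm = TRUE), 1e-6)
  }
})

test_that("pass rate counts gamma <= 1 above the low-dose threshold", {
  x <- seq(0, 9); z <- seq(0, 9)
  ref <- matrix(1, 10, 10)
  g <- gamma_index_2d(ref, ref, x, z)
  # hand-crafted gamma map: half the evaluable points at gamma = 2
  g$gamma[, 1:5] <- 2
  expect_equal(pass_rate(g), 50)
  # threshold masks points below 20% of normalization
  ev <- ref; ev[1:5, ] <- 0.1
  g2 <- gamma_index_2d(ev, ref, x, z)
  expect_equal(sum(is.na(g2$gamma)), 50)
  expect_equal(pass_rate(g2), 100)
  g2$gamma[] <- NA
  expect_error(pass_rate(g2), "no evaluable")
})

test_that("pass rate is scale-invariant under internal normalization", {
  set.seed(91)
  z <- seq(0, 39)
  ref <- outer(exp(-(seq(0, 39) - 20)^2 / 50), exp(-(z - 18)^2 / 60)) + 0.02
  ev <- ref * (1 + 0.015 * sin(outer(seq(0, 39), z, "+") / 5))
  g1 <- gamma_index_2d(ev, ref, seq(0, 39), z)
  g2 <- gamma_index_2d(5 * ev, 5 * ref, seq(0, 39), z)
  expect_equal(pass_rate(g1), pass_rate(g2))
  expect_equal(g1$gamma, g2$gamma, tolerance = 1e-12)
})

test_that("incommensurate grids are resampled onto the finer one", {
  xf <- seq(0, 20, by = 1); zf <- seq(0, 20, by = 1)
  xc <- seq(0, 20, by = 2); zc <- seq(0, 20, by = 2)
  f <- function(x, z) outer(1 + x / 40, 1 + z / 50)
  g <- gamma_index_2d(f(xc, zc), f(xf, zf), xc, zc, xf, zf)
  # same smooth field on both grids: everything passes easily
  expect_equal(pass_rate(g), 100)
  expect_lt(max(g$gamma, na.rm = TRUE), 0.2)
  expect_error(gamma_index_2d(f(xc, zc), f(xf, zf), xc + 100, zc, xf, zf),
               "overlap")
})
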