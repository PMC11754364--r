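toy_field <- function(vals, dims = c(7, 7, 7), f = 70, spacing = 0.01) {
  g <- voxel_grid(spacing, dims, origin = -spacing * (dims - 1) / 2)
  structure(list(grid = g,
                 Ex = array(vals, dims), Ey = array(vals * 1i, dims),
                 Ez = array(vals * 2, dims),
                 channel_id = "t", f_MHz = f, residual = 1e-4, converged = TRUE,
                 periods_run = 5L, monitors = NULL),
            class = "phasor_field")
}

toy_sar_scene <- function(dims = c(7, 7, 7), spacing = 0.01, sigma = 0.5,
                          rho = 1000) {
  g <- voxel_grid(spacing, dims, origin = -spacing * (dims - 1) / 2)
  pal <- list(material("air", 0, 1, rho = 1.2, c = 1005),
              material("muscle", sigma, 75, rho = rho))
  scene <- material_grid(g, pal, array(1L, dims))
  attr(scene, "phantom_labels") <- 1L
  scene
}

test_that("opposite phases cancel and a single channel is the identity", {
  f <- toy_field(1 + 2i)
  out <- superpose(list(a = f, b = f),
                   drive_setting(70, c(a = 1, b = 1), c(a = 0, b = 180)))
  expect_equal(max(Mod(out$Ex)), 0, tolerance = 1e-12)
  one <- superpose(list(a = f), drive_setting(70, c(a = 1)))
  expect_equal(one$Ex, f$Ex)
  expect_equal(one$Ez, f$Ez)
})

test_that("amplitudes follow sqrt(power) and grids/frequencies must agree", {
  f <- toy_field(1 + 0i)
  out <- superpose(list(a = f), drive_setting(70, c(a = 4)))
  expect_equal(out$Ex[1], 2 + 0i)  # power 4 -> amplitude 2
  g2 <- toy_field(1 + 0i, dims = c(5, 5, 5))
  expect_error(superpose(list(a = f, b = g2),
                         drive_setting(70, c(a = 1, b = 1))), "different grids")
  f80 <- toy_field(1 + 0i); f80$f_MHz <- 80
  expect_error(superpose(list(a = f80), drive_setting(70, c(a = 1))), "MHz")
})

test_that("SAR follows sigma |E|^2 / (2 rho) with zero on sigma = 0", {
  scene <- toy_sar_scene(sigma = 0.5, rho = 1000)
  # |E| = 100 V/m in a single component
  fld <- toy_field(0 + 0i)
  fld$Ey[] <- 0i; fld$Ez[] <- 0i
  fld$Ex[] <- 100 + 0i
  sar <- sar_from_efield(fld, scene)
  expect_equal(max(abs(sar$values - 2.5)), 0, tolerance = 1e-12)
  # air absorbs nothing no matter the field
  scene$labels[1, 1, 1] <- 0L
  sar2 <- sar_from_efield(fld, scene)
  expect_equal(sar2$values[1, 1, 1], 0)
  # zero field, zero SAR
  fld$Ex[] <- 0i
  expect_equal(max(sar_from_efield(fld, scene)$values), 0)
})

test_that("global phase offsets drop out of SAR", {
  scene <- toy_sar_scene()
  f1 <- toy_field(1 + 2i); f2 <- toy_field(3 - 1i)
  d0 <- drive_setting(70, c(a = 1, b = 0.5), c(a = 10, b = 200))
  d1 <- drive_setting(70, c(a = 1, b = 0.5), c(a = 10 + 77, b = 200 + 77))
  s0 <- sar_from_efield(superpose(list(a = f1, b = f2), d0), scene)
  s1 <- sar_from_efield(superpose(list(a = f1, b = f2), d1), scene)
  expect_equal(s1$values, s0$values, tolerance = 1e-10)
})

test_that("1 cc averaging: uniform fields unchanged, hot voxel spreads to 1/64", {
  scene <- toy_sar_scene(dims = c(16, 16, 16), spacing = 0.0025)
  fld <- toy_field(0i, dims = c(16, 16, 16), spacing = 0.0025)
  fld$Ex[] <- 10 + 0i
  sar <- sar_from_efield(fld, scene)
  avg <- sar_1cc_average(sar)
  expect_equal(avg$values, sar$values, tolerance = 1e-12)
  # single interior hot voxel of 64 W/kg: cc-cube mean is 1 W/kg at the voxel
  sar2 <- sar
  sar2$values[] <- 0
  sar2$values[8, 8, 8] <- 64
  avg2 <- sar_1cc_average(sar2)
  expect_equal(avg2$values[8, 8, 8], 1)
  expect_equal(sum(sar2$values), 64)
})

test_that("1 cc averaging conserves interior sigma-weighted power within 1%", {
  n <- 20L
  scene <- toy_sar_scene(dims = c(n, n, n), spacing = 0.0025)
  co <- seq_len(n) - (n + 1) / 2
  g <- exp(-outer(outer(co^2, co^2, `+`), co^2, `+`) / 16)
  fld <- toy_field(0i, dims = c(n, n, n), spacing = 0.0025)
  fld$Ex <- array(sqrt(g) + 0i, c(n, n, n))
  sar <- sar_from_efield(fld, scene)
  avg <- sar_1cc_average(sar)
  expect_lt(abs(sum(avg$values) - sum(sar$values)) / sum(sar$values), 0.01)
})

test_that("averaging never crosses the fat/muscle interface", {
  n <- 12L
  scene <- toy_sar_scene(dims = c(n, n, n), spacing = 0.0025)
  scene$palette[[3]] <- material("fat", 0.05, 11, rho = 900, c = 2430)
  scene$labels[seq_len(n / 2), , ] <- 2L
  attr(scene, "phantom_labels") <- c(1L, 2L)
  sar <- structure(list(grid = scene$grid,
                        values = array(0, c(n, n, n)), labels = scene$labels,
                        phantom_labels = c(1L, 2L),
                        rho = c(1.2, 1000, 900), averaged = FALSE,
                        normalization = list(kind = "absolute"), f_MHz = 70),
                   class = "sar_grid")
  sar$values[scene$labels == 2L] <- 100  # hot fat side, cold muscle side
  avg <- sar_1cc_average(sar)
  expect_true(all(avg$values[scene$labels == 1L] == 0))
  expect_true(all(avg$values[scene$labels == 2L] == 100))
})

test_that("temperature-rise conversion matches c dT/dt and round-trips", {
  expect_equal(sar_from_deltaT(1, 100, 4180), 41.8)
  expect_equal(sar_from_deltaT(0, 60, 4180), 0)
  x <- c(0.3, 2.7, 41.8)
  expect_equal(sar_from_deltaT(deltaT_from_sar(x, 100, 4180), 100, 4180), x)
  expect_error(sar_from_deltaT(1, 0, 4180))
})

test_that("focal phase rule reproduces every printed console setting", {
  # symmetric ring, central focus: all zero
  expect_equal(unname(focal_phases(c(0, 0), 90, 29)$phase_deg), c(0, 0, 0, 0))
  tab <- list(
    list(70, c(-2, 0), c(top = -14, bottom = -14, left = -28, right = 0)),
    list(80, c(-2, 0), c(top = -15, bottom = -15, left = -32, right = 0)),
    list(90, c(2, 0), c(top = -17, bottom = -17, left = 0, right = -36)),
    list(90, c(4, 0), c(top = -34, bottom = -34, left = 0, right = -72)),
    list(110, c(-2, 0), c(top = -21, bottom = -21, left = -44, right = 0)))
  for (row in tab) {
    got <- focal_phases(row[[2]], row[[1]], 29)$phase_deg
    expect_equal(got[names(row[[3]])], row[[3]])
  }
})

test_that("absolute power scaling hits the target integral and is linear", {
  scene <- toy_sar_scene(dims = c(9, 9, 9), spacing = 0.01)
  fld <- toy_field(0i, dims = c(9, 9, 9))
  fld$Ex <- array(complex(real = seq_len(9^3)), c(9, 9, 9))
  sar <- sar_from_efield(fld, scene)
  s1000 <- scale_to_total_power(sar, 1000)
  h3 <- scene$grid$spacing^3
  rho_v <- s1000$rho[s1000$labels + 1L]
  expect_equal(sum(s1000$values * rho_v) * h3, 1000, tolerance = 1e-9)
  s2000 <- scale_to_total_power(sar, 2000)
  expect_equal(s2000$values, 2 * s1000$values, tolerance = 1e-12)
})

test_that("power ratios are scale invariant after total-power normalization", {
  scene <- toy_sar_scene()
  f1 <- toy_field(1 + 1i); f2 <- toy_field(2 - 1i)
  f3 <- toy_field(0.5 + 0i); f4 <- toy_field(1 - 2i)
  flds <- list(top = f1, bottom = f2, left = f3, right = f4)
  dA <- drive_setting(70, c(top = 300, bottom = 300, left = 60, right = 60))
  dB <- drive_setting(70, c(top = 1, bottom = 1, left = 0.2, right = 0.2))
  sA <- scale_to_total_power(sar_from_efield(superpose(flds, dA), scene), 720)
  sB <- scale_to_total_power(sar_from_efield(superpose(flds, dB), scene), 720)
  expect_equal(sA$values, sB$values, tolerance = 1e-10)
})

test_that("drive settings validate their channel tables", {
  expect_error(drive_setting(70, c(a = 0, b = 0)))
  expect_error(drive_setting(70, c(1, 1)))  # unnamed
  d <- drive_setting(70, c(a = 1, b = 1), c(b = -120, a = 0))
  expect_equal(unname(d$phase_deg["b"]), 240)  # stored modulo 360
})
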