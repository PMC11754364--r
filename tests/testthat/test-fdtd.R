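c0_ <- 299792458
eps0_ <- 8.8541878128e-12
mu0_ <- 1.25663706212e-6

test_that("excitation waveform ramps smoothly to a unit sinusoid", {
  f <- 70
  T <- 1 / (f * 1e6)
  expect_equal(excitation_waveform(0, f), 0)
  # well past the ramp: pure unit cosine
  t_late <- seq(10 * T, 11 * T, length.out = 257)
  expect_equal(excitation_waveform(t_late, f), cos(2 * pi * f * 1e6 * t_late),
               tolerance = 1e-12)
  # continuous first derivative at the ramp end (numeric difference)
  dt <- T * 1e-5
  t_r <- 3 * T
  d_before <- (excitation_waveform(t_r - dt, f) - excitation_waveform(t_r - 2 * dt, f)) / dt
  d_after <- (excitation_waveform(t_r + 2 * dt, f) - excitation_waveform(t_r + dt, f)) / dt
  expect_lt(abs(d_after - d_before) / (2 * pi * f * 1e6), 1e-3)
})

test_that("ramp transient spectrum stays inside the resolvable band", {
  f <- 70
  fs <- 1 / (0.95 * 0.0025 / (c0_ * sqrt(3)))  # solver sampling rate at 2.5 mm
  n <- 2^16
  t <- (seq_len(n) - 1) / fs
  # isolate the transient: ramp up, hold, taper down with the same envelope,
  # so the finite pulse has no windowing discontinuity
  T <- 1 / (f * 1e6)
  t_end <- max(t) - 3 * T
  env_up <- ifelse(t < 3 * T, 0.5 * (1 - cos(pi * t / (3 * T))), 1)
  env_dn <- ifelse(t > t_end, 0.5 * (1 + cos(pi * (t - t_end) / (3 * T))), 1)
  w <- env_up * env_dn * cos(2 * pi * f * 1e6 * t)
  spec <- Mod(stats::fft(w))^2
  freq <- (seq_len(n) - 1) / n * fs
  # resolvable band: ~10 cells per wavelength in the densest medium (eps 80)
  f_max <- c0_ / sqrt(80) / (10 * 0.0025)
  hi <- freq > f_max & freq < fs / 2
  expect_lt(sum(spec[hi]) / sum(spec[freq < fs / 2]), 1e-6)
})

test_that("phasor extraction inverts the exp(+jwt) convention", {
  f <- 70
  w <- 2 * pi * f * 1e6
  n <- 700
  dt <- 1 / (f * 1e6) / 100  # 7 periods
  t <- (seq_len(n) - 1) * dt
  expect_equal(extract_phasor(cos(w * t), f, dt), 1 + 0i, tolerance = 1e-10)
  a <- extract_phasor(2 * cos(w * t - 30 * pi / 180), f, dt)
  expect_equal(Mod(a), 2, tolerance = 1e-10)
  expect_equal(Arg(a) * 180 / pi, -30, tolerance = 1e-8)
  # a third harmonic is orthogonal over integer periods
  a3 <- extract_phasor(cos(w * t) + 0.7 * cos(3 * w * t + 1), f, dt)
  expect_equal(a3, 1 + 0i, tolerance = 1e-10)
  expect_error(extract_phasor(cos(w * t[1:650]), f, dt), "integer number")
})

make_field <- function(vals, dims = c(9, 9, 9)) {
  g <- voxel_grid(0.01, dims, origin = -0.01 * (dims - 1) / 2)
  structure(list(grid = g, Ex = array(vals, dims),
                 Ey = array(0i, dims), Ez = array(0i, dims),
                 channel_id = "t", f_MHz = 70, residual = NA, converged = TRUE,
                 periods_run = 1L, monitors = NULL),
            class = "phasor_field")
}

test_that("convergence residual flags sub-tolerance and super-tolerance changes", {
  a <- make_field(1 + 0i)
  expect_equal(check_convergence(a, a)$residual, 0)
  expect_true(check_convergence(a, a)$converged)
  b <- a
  mon <- matrix(c(4L, 4L, 4L), 1)  # the monitored voxel carries the max |E|
  b$Ex[5, 5, 5] <- 2 + 0i
  a2 <- a; a2$Ex[5, 5, 5] <- 2 + 0i
  b$Ex[5, 5, 5] <- 2 * (1 - 0.005)
  res <- check_convergence(a2, b, tol = 1e-3, monitors = matrix(c(4L, 4L, 4L), 1))
  expect_false(res$converged)
  expect_gt(res$residual, 1e-3)
})

## ---- quantitative 1-D reductions of the solver discretization ----

run_1d <- function(sigma, eps_r, f_Hz, dz, nz, n_per, k_src, k_mon,
                   waveform = NULL) {
  dt0 <- 0.95 * dz / c0_
  Np <- as.integer(ceiling((1 / f_Hz) / dt0))
  dt <- (1 / f_Hz) / Np
  t <- (seq_len(n_per * Np) - 0.5) * dt
  if (is.null(waveform)) waveform <- excitation_waveform(t, f_Hz / 1e6, 3)
  out <- phasedheat:::.fdtd_run_1d(rep(sigma, nz), rep(eps_r, nz), dz, dt, Np,
                                   waveform, as.integer(k_src), as.integer(k_mon),
                                   16L, 8, 0.002, 3, 1, as.integer(n_per))
  c(out, list(dt = dt, Np = Np, t = t))
}

test_that("plane-wave attenuation in lossy muscle matches the closed form", {
  f <- 70e6; sig <- 0.55; epsr <- 75; dz <- 0.0025; nz <- 800
  out <- run_1d(sig, epsr, f, dz, nz, 14, 100, 400)
  z <- (150:350) * dz
  fit <- stats::lm(log(Mod(out$phasor[151:351])) ~ z)
  alpha_meas <- -stats::coef(fit)[[2]]
  # exact continuum attenuation constant
  w <- 2 * pi * f
  kc <- w * sqrt(mu0_ * epsr * eps0_ * (1 - 1i * sig / (w * epsr * eps0_)))
  alpha_exact <- -Im(kc)
  # attenuation of the discrete (grid-dispersion-corrected) scheme: the
  # plane-wave ansatz in the semi-implicit lossy Yee update gives
  # sin^2(k dz/2) = -(dz^2/4) mu S (eps S + sigma cos(w dt/2)), S = 2j sin(w dt/2)/dt
  S <- 2i * sin(w * out$dt / 2) / out$dt
  rhs <- -(dz^2 / 4) * mu0_ * S * (epsr * eps0_ * S + sig * cos(w * out$dt / 2))
  casin <- function(zc) -1i * log(1i * zc + sqrt(1 - zc^2))
  kt <- (2 / dz) * casin(sqrt(rhs))
  if (Im(kt) > 0) kt <- -kt
  alpha_num <- -Im(kt)
  expect_lt(abs(alpha_meas - alpha_num) / alpha_num, 0.01)
  # and the discrete correction itself is small at this sampling
  expect_lt(abs(alpha_num - alpha_exact) / alpha_exact, 0.01)
})

test_that("CPML reflects less than 0.5% of a normally incident pulse", {
  f <- 70e6; dz <- 0.0025
  dt0 <- 0.95 * dz / c0_
  Np <- as.integer(ceiling((1 / f) / dt0)); dt <- (1 / f) / Np
  n_per <- 10
  t <- (seq_len(n_per * Np) - 0.5) * dt
  T <- 1 / f
  env <- ifelse(t < 2 * T, 0.5 * (1 - cos(pi * t / (2 * T))),
                ifelse(t < 4 * T, 0.5 * (1 + cos(pi * (t - 2 * T) / (2 * T))), 0))
  pulse <- env * cos(2 * pi * f * t)
  nz_t <- 16 + 200 + 16 + 4
  nz_r <- 6000  # reference long enough that its own boundary plays no part
  tst <- phasedheat:::.fdtd_run_1d(rep(0, nz_t), rep(1, nz_t), dz, dt, Np,
                                   pulse, 60L, 200L, 16L, 8, 0.002, 3, 1,
                                   as.integer(n_per))
  ref <- phasedheat:::.fdtd_run_1d(rep(0, nz_r), rep(1, nz_r), dz, dt, Np,
                                   pulse, 60L, 200L, 16L, 8, 0.002, 3, 1,
                                   as.integer(n_per))
  refl <- max(abs(tst$monitor - ref$monitor)) / max(abs(ref$monitor))
  expect_lt(refl, 0.005)
})

## ---- small 3-D solver properties ----

test_that("no source produces a zero phasor everywhere", {
  scene <- ph_toy_scene(spacing = 0.02)
  dev <- ph_toy_device(scene, list(c(10L, 10L, 10L)))
  cfg <- ph_toy_config(0.02, periods = 6L)
  fld <- run_channel(scene, dev, "ch1", cfg, 70, drive_amplitude = 0,
                     strict = FALSE)
  expect_equal(max(Mod(fld$Ex), Mod(fld$Ey), Mod(fld$Ez)), 0)
})

test_that("doubling the drive amplitude doubles the phasor (linearity)", {
  scene <- ph_toy_scene(spacing = 0.02)
  ctr <- world_to_index(scene$grid, c(0, 0, 0))
  dev <- ph_toy_device(scene, list(ctr + c(-3L, 0L, 0L)))
  cfg <- ph_toy_config(0.02)
  f1 <- run_channel(scene, dev, "ch1", cfg, 70, drive_amplitude = 1, strict = FALSE)
  f2 <- run_channel(scene, dev, "ch1", cfg, 70, drive_amplitude = 2, strict = FALSE)
  ref <- max(Mod(f2$Ez))
  expect_lt(max(Mod(f2$Ez - 2 * f1$Ez)) / ref, 1e-4)
})

test_that("a joint two-source run equals the superposition of single runs", {
  scene <- ph_toy_scene(spacing = 0.02)
  ctr <- world_to_index(scene$grid, c(0, 0, 0))
  s1 <- ctr + c(-4L, 0L, 0L); s2 <- ctr + c(4L, 1L, 0L)
  dev <- ph_toy_device(scene, list(s1, s2))
  cfg <- ph_toy_config(0.02)
  fa <- run_channel(scene, dev, "ch1", cfg, 70, strict = FALSE)
  fb <- run_channel(scene, dev, "ch2", cfg, 70, strict = FALSE)
  # joint drive: both sites under one channel
  dev_joint <- ph_toy_device(scene, list(s1))
  dev_joint$channels[[1]]$source_sites <- c(dev$channels[[1]]$source_sites,
                                            dev$channels[[2]]$source_sites)
  fj <- run_channel(scene, dev_joint, "ch1", cfg, 70, strict = FALSE)
  sup <- superpose(list(ch1 = fa, ch2 = fb),
                   drive_setting(70, c(ch1 = 1, ch2 = 1)))
  ref <- max(Mod(fj$Ez))
  expect_lt(max(Mod(fj$Ez - sup$Ez)) / ref, 0.02)
})

test_that("source and probe exchange leaves the transfer phasor within 1%", {
  scene <- ph_toy_scene(spacing = 0.02)
  ctr <- world_to_index(scene$grid, c(0, 0, 0))
  a <- ctr + c(-4L, -2L, 0L); b <- ctr + c(4L, 2L, 0L)
  cfg <- ph_toy_config(0.02)
  dev_ab <- ph_toy_device(scene, list(a, b))
  f_a <- run_channel(scene, dev_ab, "ch1", cfg, 70, strict = FALSE)
  f_b <- run_channel(scene, dev_ab, "ch2", cfg, 70, strict = FALSE)
  t_ab <- f_a$Ez[b[1] + 1, b[2] + 1, b[3] + 1]
  t_ba <- f_b$Ez[a[1] + 1, a[2] + 1, a[3] + 1]
  expect_lt(Mod(t_ab - t_ba) / Mod(t_ab), 0.01)
})

test_that("mirroring a channel field reproduces the mirrored channel's solve", {
  scene <- ph_toy_scene(spacing = 0.02)
  ctr <- world_to_index(scene$grid, c(0, 0, 0))
  s_top <- ctr + c(0L, 4L, 0L); s_bot <- ctr + c(0L, -4L, 0L)
  dev <- ph_toy_device(scene, list(s_top, s_bot))
  cfg <- ph_toy_config(0.02)
  f_top <- run_channel(scene, dev, "ch1", cfg, 70, strict = FALSE)
  f_bot <- run_channel(scene, dev, "ch2", cfg, 70, strict = FALSE)
  f_mir <- mirror_phasor_field(f_top, 2L, "ch2")
  ref <- max(Mod(f_bot$Ez))
  expect_lt(max(Mod(f_mir$Ez - f_bot$Ez)) / ref, 1e-4)
  expect_lt(max(Mod(f_mir$Ey - f_bot$Ey)) / ref, 1e-4)
})

test_that("phasor fields round-trip through the on-disk format", {
  scene <- ph_toy_scene(spacing = 0.02)
  dev <- ph_toy_device(scene, list(world_to_index(scene$grid, c(0, 0, 0))))
  cfg <- ph_toy_config(0.02, periods = 6L)
  fld <- run_channel(scene, dev, "ch1", cfg, 70, strict = FALSE)
  path <- tempfile(fileext = ".bin")
  write_phasor_field(fld, path)
  back <- read_phasor_field(path)
  expect_equal(back$Ez, fld$Ez)
  expect_equal(back$f_MHz, fld$f_MHz)
  expect_equal(back$channel_id, fld$channel_id)
  expect_equal(back$grid$dims, fld$grid$dims)
})
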