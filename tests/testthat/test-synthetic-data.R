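test_that("radar config derives wavelength, PRF, slope and range resolution", {
  cfg <- radar_config()
  expect_equal(cfg$wavelength_m, 2.99792458e8 / 77e9)
  expect_equal(cfg$wavelength_m * 1e3, 3.893, tolerance = 1e-3)
  expect_equal(cfg$prf_hz, 2000)
  expect_gt(cfg$slope_hz_per_s, 0)
  expect_equal(cfg$range_resolution_m, 2.99792458e8 / (2 * 3.99e9))
  expect_equal(cfg$range_resolution_m * 100, 3.76, tolerance = 1e-2)
})

test_that("raised-sine kinematics honour depth, rate and cycle count", {
  cfg <- test_config()
  # degenerate zero depth: flat trace
  tr0 <- simulate_kinematics(compression_scenario(0.0001, 100, duration_s = 2),
                             cfg)
  expect_lt(max(tr0$displacement_m), 2e-6)

  tr <- simulate_kinematics(compression_scenario(5, 100, duration_s = 10), cfg)
  expect_true(all(tr$displacement_m >= 0))
  expect_equal(max(tr$displacement_m), 0.05, tolerance = 1e-6)
  # peak velocity of the raised sine: pi * D / T_c
  expect_equal(max(abs(tr$velocity_m_s)), pi * 0.05 / 0.6, tolerance = 1e-2)
  # per-cycle truth: achieved depth equals the per-cycle max displacement
  for (k in seq_len(nrow(tr$per_cycle_truth))) {
    row <- tr$per_cycle_truth[k, ]
    expect_equal(max(tr$displacement_m[row$start_idx:row$end_idx]),
                 row$depth_m, tolerance = 1e-6)
  }
  # displacement returns to (near) zero at cycle boundaries
  expect_lt(max(tr$displacement_m[tr$per_cycle_truth$start_idx]), 1e-5)

  tr55 <- simulate_kinematics(compression_scenario(5, 110, duration_s = 30), cfg)
  expect_equal(nrow(tr55$per_cycle_truth), 55)   # floor(30 * 110 / 60)

  expect_error(simulate_kinematics(compression_scenario(-1, 100)), "positive")
  low_prf <- radar_config(slow_time_interval_s = 20e-3)
  expect_error(simulate_kinematics(compression_scenario(5, 100), low_prf),
               "PRF")
})

test_that("radial projection scales by cos(theta) and rejects >= 90 deg", {
  cfg <- test_config()
  tr <- simulate_kinematics(compression_scenario(4, 100, duration_s = 2), cfg)
  expect_identical(project_radial(tr, 0)$displacement_m, tr$displacement_m)
  expect_equal(max(project_radial(tr, 60)$displacement_m), 0.02,
               tolerance = 1e-6)
  expect_equal(max(project_radial(tr, 30)$displacement_m),
               0.04 * cos(pi / 6), tolerance = 1e-6)
  # exact cos-theta amplitude law across a sweep of angles
  amps <- vapply(seq(0, 75, by = 15), function(th)
    max(project_radial(tr, th)$displacement_m), numeric(1))
  expect_equal(amps / amps[1], cos(seq(0, 75, by = 15) * pi / 180),
               tolerance = 1e-9)
  expect_true(all(diff(amps) < 0))
  expect_error(project_radial(tr, 90), "90")
})

test_that("phase synthesis obeys the Doppler and phase laws", {
  cfg <- test_config()
  # constant displacement: all energy at zero frequency
  n <- 2048
  tr_c <- linear_trace(0, n)
  tr_c$displacement_m <- rep(0.01, n)
  s <- phase_synthesize(tr_c, cfg)
  sp <- Mod(stats::fft(s$samples))^2
  expect_equal(which.max(sp), 1)

  # linear motion: single line at 2 v / lambda
  v0 <- 0.1
  s2 <- phase_synthesize(linear_trace(v0, 4096), cfg)
  sp2 <- Mod(stats::fft(s2$samples))^2
  fax <- (0:4095) * 2000 / 4096
  expect_equal(fax[which.max(sp2)], 2 * v0 / cfg$wavelength_m,
               tolerance = 2000 / 4096)  # within one FFT bin

  # unwrapped phase excursion over one cycle = 4 pi D / lambda
  tr <- simulate_kinematics(compression_scenario(5, 100, duration_s = 1.2), cfg)
  s3 <- phase_synthesize(tr, cfg)
  ph <- signal::unwrap(Arg(s3$samples))
  expect_equal(max(ph) - ph[1], 4 * pi * 0.05 / cfg$wavelength_m,
               tolerance = 1e-6)

  # phase law against displacement on every sample, noise-free
  expect_equal(ph - ph[1], 4 * pi * tr$displacement_m / cfg$wavelength_m,
               tolerance = 1e-6)

  # determinism of the noise stream
  sa <- phase_synthesize(tr, cfg, noise_snr_db = 10, seed = 42)
  sb <- phase_synthesize(tr, cfg, noise_snr_db = 10, seed = 42)
  expect_identical(sa$samples, sb$samples)
})

test_that("chirp-level synthesis matches the phase-level path", {
  cfg <- radar_config(n_frames = 1200)
  tr <- simulate_kinematics(compression_scenario(5, 100, duration_s = 0.6), cfg)
  cube <- chirp_level_synthesize(tr, cfg, standoff_range_m = 0.5)
  expect_equal(dim(cube$data),
               c(cfg$samples_per_chirp, cfg$chirps_per_frame,
                 length(tr$displacement_m)))

  # static target: constant beat frequency, constant modulus slow-time signal
  tr_s <- linear_trace(0, 400)
  tr_s$displacement_m <- rep(0, 400)
  cube_s <- chirp_level_synthesize(tr_s, cfg, standoff_range_m = 0.8)
  z_s <- range_process(cube_s)
  expect_lt(diff(range(Mod(z_s$samples))) / mean(Mod(z_s$samples)), 1e-9)

  # moving target: slow-time phase tracks 4 pi r / lambda like the fast path
  z <- range_process(cube)
  ph_chirp <- signal::unwrap(Arg(z$samples))
  ph_fast <- 4 * pi * tr$displacement_m / cfg$wavelength_m
  resid <- (ph_chirp - ph_chirp[1]) - (ph_fast - ph_fast[1])
  expect_lt(sqrt(mean(resid^2)), 1e-2)

  # two frames lambda/4 apart give a phase step of ~pi
  tr_q <- linear_trace(0, 64)
  tr_q$displacement_m <- rep(c(0, cfg$wavelength_m / 4), each = 32)
  zq <- range_process(chirp_level_synthesize(tr_q, cfg, 0.5))
  dphi <- abs(Arg(zq$samples[33] / zq$samples[32]))
  expect_equal(dphi, pi, tolerance = 0.05)

  expect_error(chirp_level_synthesize(tr, cfg, standoff_range_m = 1e5),
               "ambiguous")
  # pure-noise cube: unstable peak bin warning
  cube_n <- chirp_level_synthesize(tr_s, cfg, 0.8, noise_snr_db = -40,
                                   seed = 3)
  expect_warning(range_process(cube_n), "wanders")
})

test_that("campaign generation is a deterministic condition cross-product", {
  cfg <- test_config()
  cp <- generate_campaign(cfg, subjects = 2, depths_cm = c(4, 5),
                          rates_cpm = 100, duration_s = 5,
                          keep_signals = FALSE, seed = 7)
  expect_equal(nrow(cp$manifest), 2 * 3 * 2 * 1)
  cp2 <- generate_campaign(cfg, subjects = 2, depths_cm = c(4, 5),
                           rates_cpm = 100, duration_s = 5,
                           keep_signals = FALSE, seed = 7)
  expect_identical(cp$manifest, cp2$manifest)
  expect_identical(cp$profiles, cp2$profiles)

  # 8 subjects x 3 cases x 4 depths x 3 rates = 288 records
  cp_full <- generate_campaign(cfg, subjects = 8, keep_signals = FALSE)
  expect_equal(nrow(cp_full$manifest), 288)

  # one record of 30 s at PRF 2000 -> 60000 samples
  cp1 <- generate_campaign(cfg, subjects = 1, cases = c(case1 = 0),
                           depths_cm = 5, rates_cpm = 100, duration_s = 30,
                           noise_snr_db = Inf, seed = 3)
  expect_equal(nrow(cp1$manifest), 1)
  expect_length(cp1$records[[1]]$signal$samples, 60000)

  # identical seeds give bit-identical signals
  cp1b <- generate_campaign(cfg, subjects = 1, cases = c(case1 = 0),
                            depths_cm = 5, rates_cpm = 100, duration_s = 30,
                            noise_snr_db = Inf, seed = 3)
  expect_identical(cp1$records[[1]]$signal$samples,
                   cp1b$records[[1]]$signal$samples)

  expect_error(generate_campaign(cfg, depths_cm = numeric(0)), "non-empty")
})

test_that("campaign files round-trip through the on-disk container", {
  cfg <- test_config()
  td <- withr::local_tempdir()
  cp <- generate_campaign(cfg, subjects = 1, cases = c(case1 = 0),
                          depths_cm = 4, rates_cpm = 100, duration_s = 3,
                          seed = 5, out_dir = td)
  mf <- read.csv(file.path(td, "manifest.csv"))
  expect_equal(nrow(mf), 1)
  sig <- read.csv(file.path(td, mf$path[1]))
  expect_equal(complex(real = sig$re, imaginary = sig$im),
               cp$records[[1]]$signal$samples, tolerance = 1e-12)
})
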