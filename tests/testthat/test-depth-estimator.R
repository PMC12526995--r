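test_that("envelope detection finds the edge of an ideal band", {
  # uniform band 0..+200 Hz on a -40 dB floor: envelope within one bin of 200
  nfft <- 256L; fs <- 2000
  f <- ((-(nfft %/% 2)):(nfft %/% 2 - 1)) * fs / nfft
  P <- matrix(1e-4, nfft, 50)
  P[f >= 0 & f <= 200, ] <- 1
  tm <- mdcpr:::new_tf_map(P, f, (1:50) / 100, "STFT", prf_hz = fs)
  # raw discrete derivative (no smoothing): the ideal edge is unambiguous
  env <- detect_envelope(tm, smooth_bins = 1L, debias = FALSE)
  expect_true(all(abs(env$envelope_hz - 200) <= fs / nfft + 1e-9))

  # pure noise: zero envelope plus a warning
  Pn <- matrix(1, nfft, 50)
  tn <- mdcpr:::new_tf_map(Pn, f, (1:50) / 100, "STFT", prf_hz = fs)
  expect_warning(envn <- detect_envelope(tn, debias = FALSE), "noise")
  expect_true(all(envn$envelope_hz == 0))

  # simulated signal: envelope periodic at the compression period
  cfg <- test_config()
  tr <- simulate_kinematics(compression_scenario(5, 100, duration_s = 10), cfg)
  S <- stft_spectrogram(phase_synthesize(tr, cfg))
  e <- detect_envelope(S)
  r <- abs(e$envelope_hz)
  ac <- stats::acf(r, lag.max = 200, plot = FALSE)$acf[-1]
  lag_s <- which.max(ac[50:200]) + 49
  dt <- diff(e$time_axis_s)[1]
  expect_equal(lag_s * dt, 0.6, tolerance = dt * 2 + 1e-9)
})

test_that("cycle segmentation pairs lobes into cycles", {
  cfg <- test_config()
  tr <- simulate_kinematics(compression_scenario(5, 110, duration_s = 30), cfg)
  S <- stft_spectrogram(phase_synthesize(tr, cfg))
  cyc <- segment_cycles(detect_envelope(S))
  expect_true(abs(nrow(cyc) - 55) <= 1)
  expect_true(all(cyc$end_idx > cyc$start_idx))
  expect_true(all(cyc$peak_doppler_hz > 0))

  # constant zero envelope: empty list with a warning
  env0 <- structure(list(time_axis_s = (1:100) / 100,
                         envelope_hz = numeric(100), prf_hz = 2000,
                         smoothing = list()), class = "envelope_trace")
  expect_warning(c0 <- segment_cycles(env0), "lobes|minima")
  expect_equal(nrow(c0), 0)

  # two clean lobes: exactly one cycle whose peak is the global maximum
  tt <- seq(0, 0.6, by = 0.005)
  one <- 150 * sin(pi * tt / 0.3)^2 * rep(c(1, -1), each = 61)[1:121]
  env2 <- structure(list(time_axis_s = tt, envelope_hz = one, prf_hz = 2000,
                         smoothing = list()), class = "envelope_trace")
  c2 <- segment_cycles(env2)
  expect_equal(nrow(c2), 1)
  expect_equal(c2$peak_doppler_hz, max(abs(one)))
})

test_that("Doppler integration has the closed-form scale", {
  # constant envelope f0 over Dt on each lobe: d = (lambda/2) f0 Dt
  lam <- radar_config()$wavelength_m
  tt <- seq(0, 0.2, by = 0.001)
  env <- structure(list(time_axis_s = tt, envelope_hz = rep(200, 201),
                        prf_hz = 2000, smoothing = list()),
                   class = "envelope_trace")
  cyc <- list(start_idx = 1L, mid_idx = 101L, end_idx = 201L)
  d <- integrate_depth(cyc, env, lam)
  expect_equal(d, lam / 2 * 200 * 0.1, tolerance = 1e-12)
  expect_equal(d * 100, 3.893, tolerance = 1e-3)

  env0 <- env; env0$envelope_hz[] <- 0
  expect_equal(integrate_depth(cyc, env0, lam), 0)
  expect_error(integrate_depth(list(start_idx = 5L, mid_idx = 5L,
                                    end_idx = 5L), env, lam), "zero duration")
})

test_that("angle compensation inverts the radial projection", {
  expect_equal(compensate_angle(0.025, 60), 0.05)
  expect_identical(compensate_angle(0.031, 0), 0.031)
  for (th in c(10, 30, 45, 80)) {
    d <- 0.047
    r <- d * cos(th * pi / 180)
    expect_equal(compensate_angle(r, th), d, tolerance = 1e-12)
  }
  expect_error(compensate_angle(0.02, 95), "90")
})

test_that("noise-free pipeline recovers depth within 5% and is rate-stable", {
  cfg <- test_config()
  for (D in c(3, 5)) {
    tr <- simulate_kinematics(compression_scenario(D, 100, duration_s = 10),
                              cfg)
    est <- estimate_depths(phase_synthesize(tr, cfg), cfg)
    expect_gt(nrow(est), 10)
    expect_lt(abs(mean(est$depth_cm) - D) / D, 0.05)
  }
  # rate invariance: same depth at 90 vs 110 CPM within 10%
  m_rate <- vapply(c(90, 110), function(r) {
    tr <- simulate_kinematics(compression_scenario(4, r, duration_s = 10), cfg)
    mean(estimate_depths(phase_synthesize(tr, cfg), cfg)$depth_cm)
  }, numeric(1))
  expect_lt(abs(diff(m_rate)) / mean(m_rate), 0.10)
})

test_that("oblique geometry is recovered after compensation", {
  cfg <- test_config()
  tr <- simulate_kinematics(compression_scenario(4, 100, duration_s = 10), cfg)
  base <- mean(estimate_depths(phase_synthesize(tr, cfg), cfg)$depth_cm)
  for (th in c(30, 45)) {
    sig <- phase_synthesize(project_radial(tr, th), cfg)
    est <- estimate_depths(sig, cfg, aspect_angle_deg = th)
    expect_lt(abs(mean(est$depth_cm) - 4) / 4, 0.07)
    # compensation cancels projection: close to the frontal estimate
    expect_lt(abs(mean(est$depth_cm) - base) / base, 0.02)
  }
})

test_that("depth estimates increase strictly with simulated true depth", {
  cfg <- test_config()
  means <- vapply(c(3, 4, 5, 6), function(D) {
    tr <- simulate_kinematics(compression_scenario(D, 100, duration_s = 8), cfg)
    mean(estimate_depths(phase_synthesize(tr, cfg), cfg)$depth_cm)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("integration agrees with direct phase-unwrap displacement", {
  cfg <- test_config()
  tr <- simulate_kinematics(compression_scenario(5, 100, duration_s = 8), cfg)
  sig <- phase_synthesize(tr, cfg)
  est <- estimate_depths(sig, cfg)
  # oracle: peak-to-trough of lambda/(4 pi) * unwrapped phase per truth cycle
  ph <- signal::unwrap(Arg(sig$samples))
  d_oracle <- cfg$wavelength_m / (4 * pi) * (ph - ph[1])
  truth <- tr$per_cycle_truth
  oracle_depths <- vapply(seq_len(nrow(truth)), function(k)
    max(d_oracle[truth$start_idx[k]:truth$end_idx[k]]) -
      min(d_oracle[truth$start_idx[k]:truth$end_idx[k]]), numeric(1))
  expect_equal(mean(est$depth_cm), 100 * mean(oracle_depths), tolerance = 0.03)
})

test_that("mis-specified aspect angle degrades accuracy monotonically", {
  cfg <- test_config()
  tr <- simulate_kinematics(compression_scenario(5, 100, duration_s = 8), cfg)
  errs <- vapply(c(0, 20, 40), function(th_true) {
    sig <- phase_synthesize(project_radial(tr, th_true), cfg)
    # compensate with an angle 15 degrees short of the truth
    est <- estimate_depths(sig, cfg, aspect_angle_deg = max(th_true - 15, 0))
    abs(mean(est$depth_cm) - 5)
  }, numeric(1))
  expect_true(all(diff(errs) >= 0))
})
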