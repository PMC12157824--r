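test_that("marker ranges are Euclidean distances to the radar", {
  cfg <- radar_config(rate = 250)
  static <- function(p) {
    pos <- array(rep(p, each = 10), c(1, 10, 3))
    marker_trajectory(pos, 250)
  }
  expect_equal(unique(ranges_from_markers(static(c(0, 1.5, 0)), cfg)$ranges[1, ]),
               1.5)
  expect_equal(unique(ranges_from_markers(static(c(3, 4, 0)), cfg)$ranges[1, ]),
               5.0)
  expect_error(ranges_from_markers(static(c(0, 0, 0)), cfg), "zero range")

  # independent double-loop oracle on a random trajectory
  spec <- make_motion_template("front_kick", 5, seed = 9)
  traj <- render_trajectory(spec, 0.5, 250)
  rs <- ranges_from_markers(traj, cfg)
  for (k in seq_len(5)) {
    manual <- vapply(seq_len(dim(traj$positions)[2]), function(t) {
      sqrt(sum((traj$positions[k, t, ] - cfg$radar_position)^2))
    }, numeric(1))
    expect_equal(rs$ranges[k, ], manual, tolerance = 1e-12)
  }
})

test_that("range resampling is spline-exact for smooth inputs", {
  rs <- range_set(matrix(2 + 0.3 * sin(2 * pi * (0:999) / 250), 1), 250)
  expect_identical(resample_ranges(rs, 250), rs)

  up <- resample_ranges(rs, 5000)
  t_new <- (seq_len(ncol(up$ranges)) - 1) / 5000
  expect_lt(max(abs(up$ranges[1, ] - (2 + 0.3 * sin(2 * pi * t_new)))), 1e-6)

  const <- range_set(matrix(1.7, 1, 100), 250)
  expect_true(all(resample_ranges(const, 1000)$ranges == 1.7))
})

test_that("baseband phasors follow the two-way phase closed form", {
  cfg <- radar_config(f0 = 5.8e9, rate = 100)
  expect_equal(round(cfg$lambda, 4), 0.0517)

  half <- range_set(matrix(cfg$lambda / 2, 1, 50), 100)
  s <- simulate_baseband(half, config = cfg)
  expect_equal(s$samples, rep(complex(real = 1), 50), tolerance = 1e-12)

  quarter <- range_set(matrix(cfg$lambda / 4, 1, 50), 100)
  s <- simulate_baseband(quarter, config = cfg)
  expect_equal(s$samples, rep(complex(real = -1), 50), tolerance = 1e-12)

  expect_error(simulate_baseband(half, amplitudes = c(1, 1), config = cfg),
               "scatterers")
})

test_that("baseband superposition is linear and amplitude-bounded", {
  cfg <- radar_config(rate = 250)
  spec <- make_motion_template("squat", 6, seed = 2)
  rs <- ranges_from_markers(render_trajectory(spec, 1, 250), cfg)
  amps <- c(0.5, 1, 2, 1, 3, 0.25)
  s_all <- simulate_baseband(rs, amps, cfg)
  s_a <- simulate_baseband(range_set(rs$ranges[1:2, ], 250), amps[1:2], cfg)
  s_b <- simulate_baseband(range_set(rs$ranges[3:6, ], 250), amps[3:6], cfg)
  expect_equal(s_all$samples, s_a$samples + s_b$samples, tolerance = 1e-12)
  expect_true(all(Mod(s_all$samples) <= sum(amps) + 1e-12))
})

test_that("AWGN injection hits the requested SNR and is seeded", {
  cfg <- radar_config(rate = 1000)
  sig <- radar_signal(exp(1i * 2 * pi * (0:99999) * 0.01), 1000, cfg)
  expect_identical(add_awgn(sig, Inf, seed = 1), sig)

  noisy <- add_awgn(sig, 0, seed = 7)
  noise_pow <- mean(Mod(noisy$samples - sig$samples)^2)
  expect_lt(abs(noise_pow - 1), 0.01)

  snr_est <- 10 * log10(mean(Mod(sig$samples)^2) / noise_pow)
  expect_lt(abs(snr_est - 0), 0.1)

  expect_identical(add_awgn(sig, 10, seed = 3), add_awgn(sig, 10, seed = 3))
})

test_that("spectrogram locates DC and Doppler-shifted returns", {
  cfg <- radar_config(rate = 1000)
  const <- radar_signal(complex(real = rep(1, 1000)), 1000, cfg)
  sp <- spectrogram(const, window_s = 0.064, overlap_frac = 0.5)
  for (j in seq_along(sp$time)) {
    expect_equal(sp$freq[which.max(sp$mag[, j])], 0)
  }

  # constant radial velocity v -> Doppler at -2 v / lambda
  v <- 0.5
  r <- 1.5 + v * (0:999) / 1000
  sig <- simulate_baseband(range_set(matrix(r, 1), 1000), config = cfg)
  sp <- spectrogram(sig, window_s = 0.256, overlap_frac = 0)
  f_expect <- -2 * v / cfg$lambda
  bin_w <- 1000 * (1 / (0.256 * 1000))
  for (j in seq_along(sp$time)) {
    expect_lt(abs(sp$freq[which.max(sp$mag[, j])] - f_expect), bin_w)
  }

  # Parseval: per-frame spectral energy equals windowed time energy
  x <- radar_signal(rand_complex(512, 5), 1000, cfg)
  sp <- spectrogram(x, window_s = 0.128, overlap_frac = 0.25, window = "hann")
  L <- 128
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  starts <- seq(1, 512 - L + 1, by = round(L * 0.75))
  for (j in seq_along(starts)) {
    e_spec <- sum(sp$mag[, j]^2) / L
    e_time <- sum(Mod(w * x$samples[starts[j]:(starts[j] + L - 1)])^2)
    expect_equal(e_spec, e_time, tolerance = 1e-6)
  }

  expect_error(spectrogram(const, window_s = 2), "longer than")
})
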