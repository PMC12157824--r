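test_that("motion templates are seeded-deterministic and class-structured", {
  a <- make_motion_template("squat", 30, seed = 1)
  b <- make_motion_template("squat", 30, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, make_motion_template("squat", 30, seed = 2)))
  expect_error(make_motion_template("jumping_jack", 30, 1), "squat")

  # arm-only classes carry zero-amplitude leg components
  grp <- marker_groups(30)
  for (cls in c("arm_curl", "front_lateral_raise")) {
    spec <- make_motion_template(cls, 30, seed = 1)
    leg_amps <- unlist(lapply(spec$markers[grp$leg], function(mk) {
      vapply(mk$components, function(cp) cp$amplitude, numeric(1))
    }))
    expect_true(all(leg_amps == 0))
  }
})

test_that("front lateral raise and arm curl are the most similar class pair", {
  # brute force over all 10 unordered class pairs on mean per-marker
  # total component amplitude
  for (seed in c(1, 7)) {
    specs <- lapply(motion_classes(), make_motion_template,
                    n_markers = 30, seed = seed)
    amp_profile <- function(spec) {
      vapply(spec$markers, function(mk) {
        sum(vapply(mk$components, function(cp) cp$amplitude, numeric(1)))
      }, numeric(1))
    }
    profiles <- lapply(specs, amp_profile)
    pairs <- utils::combn(5, 2)
    dists <- apply(pairs, 2, function(ij) {
      mean(abs(profiles[[ij[1]]] - profiles[[ij[2]]]))
    })
    closest <- pairs[, which.min(dists)]
    expect_equal(sort(motion_classes()[closest]),
                 sort(c("front_lateral_raise", "arm_curl")))
  }
})

test_that("every dominant micro-motion period exceeds the analysis window", {
  for (cls in motion_classes()) {
    spec <- make_motion_template(cls, 12, seed = 3)
    dom_periods <- vapply(spec$markers, function(mk) {
      amps <- vapply(mk$components, function(cp) cp$amplitude, numeric(1))
      rates <- vapply(mk$components, function(cp) cp$angular_rate, numeric(1))
      if (all(amps == 0)) return(Inf)
      2 * pi / rates[which.max(amps)]
    }, numeric(1))
    expect_true(all(dom_periods >= 1.2))
  }
})

test_that("random micro-motion ensembles respect the requested ranges", {
  lambda <- 3e8 / 5.8e9
  spec <- sample_random_mm(4, 3, c(0, 2), c(0, 4 * pi / lambda), c(0, 2 * pi),
                           seed = 11)
  rates <- unlist(lapply(spec$markers, function(mk) {
    vapply(mk$components, function(cp) cp$angular_rate, numeric(1))
  }))
  expect_true(all(rates / (2 * pi) >= 0 & rates / (2 * pi) <= 2))

  static <- sample_random_mm(3, 2, c(0, 2), c(0, 0), c(0, 2 * pi), seed = 1)
  traj <- render_trajectory(static, 1, 100)
  expect_true(all(apply(traj$positions, c(1, 3), function(v) {
    max(v) - min(v)
  }) == 0))

  s1 <- sample_random_mm(4, 3, c(0, 2), c(0, 1), c(0, 2 * pi), seed = 1)
  s2 <- sample_random_mm(4, 3, c(0, 2), c(0, 1), c(0, 2 * pi), seed = 2)
  expect_false(identical(s1, s2))
  expect_error(sample_random_mm(4, 3, c(2, 0), c(0, 1), c(0, 2 * pi), 1),
               "max >= min")
})

test_that("rendering matches the closed form and an independent range loop", {
  spec <- motion_spec(list(list(
    static_position = c(0, 1.5, 0), motion_axis = c(0, 1, 0),
    components = list(motion_component("cosine", 0.1, 2 * pi, 0)))))
  traj <- render_trajectory(spec, 1, 250)
  y <- traj$positions[1, , 2]
  expect_equal(y[1], 1.6)
  expect_equal(y[round(0.5 * 250) + 1], 1.4, tolerance = 1e-12)
  expect_equal(y, 1.5 + 0.1 * cos(2 * pi * (0:249) / 250), tolerance = 1e-12)

  # range vs an independent per-sample loop
  cfg <- radar_config(rate = 250)
  rs <- ranges_from_markers(traj, cfg)
  manual <- vapply(seq_len(dim(traj$positions)[2]), function(t) {
    sqrt(sum(traj$positions[1, t, ]^2))
  }, numeric(1))
  expect_equal(rs$ranges[1, ], manual, tolerance = 1e-12)
})

test_that("rendering at twice the rate then decimating reproduces the grid", {
  spec <- make_motion_template("lunge", 6, seed = 5)
  hi <- render_trajectory(spec, 2, 500)
  lo <- render_trajectory(spec, 2, 250)
  expect_identical(hi$positions[, seq(1, 1000, by = 2), ], lo$positions)
})

test_that("time scaling slows the motion by the requested factor", {
  spec <- motion_spec(list(list(
    static_position = c(0, 1.5, 0), motion_axis = c(0, 1, 0),
    components = list(motion_component("cosine", 0.1, 2 * pi * 1.0, 0)))))
  traj <- render_trajectory(spec, 4, 250)
  expect_identical(time_scale(traj, 1.0), traj)
  expect_error(time_scale(traj, 0), "> 0")

  slowed <- time_scale(traj, 2.0)
  spec_half <- motion_spec(list(list(
    static_position = c(0, 1.5, 0), motion_axis = c(0, 1, 0),
    components = list(motion_component("cosine", 0.1, 2 * pi * 0.5, 0)))))
  ref <- render_trajectory(spec_half, 4, 250)
  expect_lt(max(abs(slowed$positions - ref$positions)), 1e-6)

  # spectral oracle: dominant periodogram peak scales by 1/beta
  peak_freq <- function(tr) {
    y <- tr$positions[1, , 2] - mean(tr$positions[1, , 2])
    sp <- Mod(fft(y))^2
    n <- length(y)
    k <- which.max(sp[2:floor(n / 2)])  # skip DC
    k / (n / tr$rate)
  }
  f1 <- peak_freq(traj)
  f2 <- peak_freq(slowed)
  expect_lt(abs(f2 - f1 / 2), 1 / (dim(traj$positions)[2] / traj$rate))
})

test_that("signal perturbation touches exactly the requested fraction", {
  cfg <- radar_config(rate = 1000)
  sig <- radar_signal(rand_complex(6000, 1), 1000, cfg)
  expect_identical(perturb_signal(sig, 0, 0.5, seed = 1), sig)
  expect_identical(perturb_signal(sig, 1, 0, seed = 1), sig)
  pert <- perturb_signal(sig, 0.5, 0.5, seed = 1)
  expect_identical(sum(pert$samples != sig$samples), 3000L)
  # untouched samples are bit-identical
  expect_true(all(pert$samples[pert$samples == sig$samples] ==
                  sig$samples[pert$samples == sig$samples]))
})

test_that("signal mixing is the elementwise complex sum", {
  cfg <- radar_config(rate = 1000)
  s <- radar_signal(rand_complex(100, 2), 1000, cfg)
  zero <- radar_signal(complex(real = rep(0, 100)), 1000, cfg)
  expect_equal(mix_signals(s, zero)$samples, s$samples)
  expect_equal(mix_signals(s, s)$samples, 2 * s$samples)
  other <- radar_signal(rand_complex(50, 3), 1000, cfg)
  expect_error(mix_signals(s, other), "length")
  off_carrier <- radar_signal(rand_complex(100, 4), 1000,
                              radar_config(f0 = 24e9, rate = 1000))
  expect_error(mix_signals(s, off_carrier), "carrier")
})
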