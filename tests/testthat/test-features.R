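test_that("basis functions are unit-modulus phase histories", {
  lam <- 3e8 / 5.8e9
  expect_equal(basis_function(rep(0, 10), lam)$values,
               rep(complex(real = 1), 10))
  expect_equal(basis_function(rep(lam / 4, 10), lam)$values,
               rep(complex(real = -1), 10), tolerance = 1e-12)
  b <- basis_function(runif(50, 0, 3), lam)
  expect_equal(Mod(b$values), rep(1, 50), tolerance = 1e-12)
})

test_that("max circular cross-correlation recovers matched amplitudes", {
  b <- rand_complex(256, 1)
  b <- b / Mod(b)  # unit modulus
  expect_equal(max_xcorr_amplitude(2.0 * b, b), 2.0, tolerance = 1e-9)
  for (tau in c(1, 17, 255)) {
    expect_equal(max_xcorr_amplitude(3.5 * circ_shift(b, tau), b), 3.5,
                 tolerance = 1e-9)
  }
  expect_error(max_xcorr_amplitude(b[1:10], b), "equal length")
})

test_that("FFT correlation equals the brute-force shift loop", {
  for (n in c(3, 8, 17, 33, 64)) {
    s <- rand_complex(n, n)
    b <- rand_complex(n, n + 100)
    b <- b / Mod(b)
    expect_equal(max_xcorr_amplitude(s, b), brute_xcorr_max(s, b),
                 tolerance = 1e-12)
  }
})

test_that("the feature is shift-invariant and scale-equivariant", {
  s <- rand_complex(128, 3)
  b <- rand_complex(128, 4)
  b <- b / Mod(b)
  a0 <- max_xcorr_amplitude(s, b)
  for (tau in c(5, 64, 127)) {
    expect_equal(max_xcorr_amplitude(circ_shift(s, tau), b), a0,
                 tolerance = 1e-12)
  }
  for (c in c(0.1, 2, 7.5)) {
    expect_equal(max_xcorr_amplitude(c * s, b), c * a0, tolerance = 1e-12)
  }
})

test_that("feature vectors identify the matched basis", {
  lam <- 3e8 / 5.8e9
  withr::with_seed(10, {
    ranges <- matrix(runif(5, 1, 2), 5, 400) +
      0.4 * sin(outer(runif(5, 1, 6), (0:399) / 200) * 2 * pi +
                runif(5, 0, 2 * pi))
  })
  bank <- basis_bank(ranges, lam, rate = 200)
  sig <- bank$B[, 3]
  f <- feature_vector(sig, bank)
  expect_length(f, 5)
  expect_identical(which.max(f), 3L)
  expect_equal(f[3], 1, tolerance = 1e-9)

  f0 <- feature_vector(complex(real = rep(0, 400)), bank)
  expect_equal(f0, rep(0, 5))
})

test_that("segment-count arithmetic matches the sliding-window formula", {
  expect_identical(n_segments(4.00, 1.20, 0.02), 140L)
  expect_identical(n_segments(4.00, 1.20, 0.42), 6L)
  expect_identical(n_segments(4.00, 4.00, 0.02), 1L)
  expect_identical(segment_starts(4, 4, 0.02), 0)
  expect_error(n_segments(4, 4.5, 0.02), "exceeds")

  # independent arithmetic oracle over a grid of strides
  for (dt in seq(0.02, 0.42, by = 0.1)) {
    expect_identical(n_segments(4, 1.2, dt),
                     max(1L, as.integer((4 - 1.2) / dt + 1e-9)))
  }
})

test_that("segment pairs are time-aligned across rates", {
  cfg <- radar_config(rate = 1000)
  spec <- make_motion_template("squat", 5, seed = 4)
  traj <- render_trajectory(spec, 2, 250)
  rs <- resample_ranges(ranges_from_markers(traj, cfg), 1000)
  sig <- simulate_baseband(rs, config = cfg)
  segs <- segment_recording(sig, traj, T_samp = 0.5, dt_tr = 0.25,
                            T_end = 2.0)
  expect_length(segs, n_segments(2, 0.5, 0.25))
  for (sg in segs) {
    expect_length(sg$signal$samples, 500)
    expect_identical(dim(sg$markers$positions)[2], 125L)
    expect_identical(sg$markers$t0, sg$t0)
    # marker segment matches a direct slice of the source trajectory
    j0 <- round(sg$t0 * 250)
    expect_identical(sg$markers$positions,
                     traj$positions[, (j0 + 1):(j0 + 125), , drop = FALSE])
  }
})

test_that("training database assembly, extrema and normalization", {
  db <- fixture_db()
  cfg <- fixture_cfg()
  n_per_class <- n_segments(cfg$T_end, cfg$T_samp, cfg$dt_tr)
  expect_identical(dim(db$F), c(8L, 5L * n_per_class))
  expect_identical(length(db$labels), ncol(db$F))

  # independent two-pass min/max scan
  fmin2 <- fmax2 <- numeric(nrow(db$F))
  for (j in seq_len(nrow(db$F))) {
    fmin2[j] <- min(db$F[j, ]); fmax2[j] <- max(db$F[j, ])
  }
  expect_identical(db$fmin, fmin2)
  expect_identical(db$fmax, fmax2)
  expect_equal(unname(apply(db$Fnorm, 1, min)), rep(0, 8))
  expect_equal(unname(apply(db$Fnorm, 1, max)), rep(1, 8))
})

test_that("min-max normalization is the unclipped affine map", {
  expect_equal(normalize_features(c(1, 3, 5), rep(1, 3), rep(5, 3)),
               c(0, 0.5, 1))
  expect_equal(normalize_features(7, 1, 5), 1.5)
  expect_equal(normalize_features(1, 1, 5), 0)
  expect_equal(normalize_features(5, 1, 5), 1)
  expect_error(normalize_features(c(1, 2), c(0, 1), c(2, 1)), "degenerate")
})

test_that("test features have per-class cardinality in both modes", {
  db <- fixture_db()
  test <- draw_test_segments(attr(db, "subject"), fixture_cfg(),
                             snr_db = Inf, seed = 5)
  sig <- test$segments[[1]]
  tf_pc <- test_feature(sig, db, "per_class")
  expect_identical(dim(tf_pc), c(8L, 5L))
  tf_pi <- test_feature(sig, db, "per_instance")
  expect_length(tf_pi, 5L)
  n_per_class <- table(db$labels)
  for (key in names(tf_pi)) {
    expect_identical(ncol(tf_pi[[key]]), as.integer(n_per_class[[key]]))
  }
})

test_that("a training segment fed back reproduces its stored feature", {
  db <- fixture_db()
  cfg <- fixture_cfg()
  subject <- attr(db, "subject")
  cls <- 2L
  i0 <- db$offsets[[as.character(cls)]][4]
  Ls <- db$segmentation$seg_len
  seg <- radar_signal(
    subject$recordings[[cls]]$signal$samples[(i0 + 1):(i0 + Ls)],
    cfg$rate, subject$config, label = cls)
  tf <- test_feature(seg, db, "per_instance")
  col_in_class <- 4L
  stored <- normalize_features(
    db$F[, which(db$labels == cls)[col_in_class]], db$fmin, db$fmax)
  expect_equal(tf[[as.character(cls)]][, col_in_class], stored,
               tolerance = 1e-9)
})

test_that("per-instance banks precompute to the same features", {
  db <- fixture_db()  # has precomputed banks
  db_plain <- db
  db_plain$BF_by_class <- NULL
  test <- draw_test_segments(attr(db, "subject"), fixture_cfg(),
                             snr_db = 10, seed = 6)
  sig <- test$segments[[7]]
  tf_fast <- test_feature(sig, db, "per_instance")
  tf_slow <- test_feature(sig, db_plain, "per_instance")
  for (key in names(tf_fast)) {
    expect_equal(tf_fast[[key]], tf_slow[[key]], tolerance = 1e-9)
  }
})
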