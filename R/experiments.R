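# Experiment harness: synthetic-subject pipeline, residual-term validation,
# SNR x PCA-dimension grids, segmentation sweeps and robustness studies.

# sub-seed derivation: deterministic, stays inside 32-bit integer range
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483629)
}

#' Experiment configuration
#'
#' Defaults mirror the reference measurement setup: 5 motion classes, 30
#' markers at 250 Hz, 5.8 GHz carrier sampled at 5 kHz, 4-s recordings cut
#' into 1.2-s windows every 0.02 s, PCA dimension 4, SNR grid 0-20 dB, 50
#' test segments per class.
#'
#' @param n_classes,n_markers Class and marker counts.
#' @param T_end,T_samp,dt_tr Recording duration, window length, stride (s).
#' @param rate,marker_rate Radar and mocap sampling rates (Hz).
#' @param f0 Carrier frequency (Hz).
#' @param d Retained PCA dimension.
#' @param snr_db SNR grid in dB (may include `Inf` for no noise).
#' @param n_test Test segments per class.
#' @param mode Test-feature mode, `"per_class"` or `"per_instance"`.
#' @param seed Base seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_classes = 5L, n_markers = 30L, T_end = 4.0,
                              T_samp = 1.2, dt_tr = 0.02, rate = 5000,
                              marker_rate = 250, f0 = 5.8e9, d = 4L,
                              snr_db = seq(0, 20, 5), n_test = 50L,
                              mode = "per_instance", seed = 1L) {
  stopifnot(n_classes >= 2L, n_classes <= length(motion_classes()),
            n_markers >= 4L, T_samp <= T_end, dt_tr > 0, rate > 0,
            marker_rate > 0, d >= 1L, n_test >= 1L)
  structure(list(n_classes = as.integer(n_classes),
                 n_markers = as.integer(n_markers), T_end = T_end,
                 T_samp = T_samp, dt_tr = dt_tr, rate = rate,
                 marker_rate = marker_rate, f0 = f0, d = as.integer(d),
                 snr_db = snr_db, n_test = as.integer(n_test), mode = mode,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Synthesize one subject: trajectories and radar recordings per class
#'
#' Renders a seeded motion template for each class at the mocap rate,
#' resamples marker ranges to the radar rate and simulates the clean
#' baseband recording (unit scatterer amplitudes).
#'
#' @param config An `experiment_config`.
#' @param seed Subject seed (defaults to `config$seed`).
#' @return List with the `radar_config` and, per class, the `motion_spec`,
#'   `marker_trajectory`, signal-rate `range_set` and clean `radar_signal`.
#' @export
synth_subject <- function(config, seed = config$seed) {
  rc <- radar_config(f0 = config$f0, rate = config$rate)
  classes <- motion_classes()[seq_len(config$n_classes)]
  recs <- lapply(seq_along(classes), function(i) {
    spec <- make_motion_template(classes[i], config$n_markers,
                                 seed = .sub_seed(seed, i))
    traj <- render_trajectory(spec, config$T_end, config$marker_rate)
    rs <- resample_ranges(ranges_from_markers(traj, rc), config$rate)
    sig <- simulate_baseband(rs, config = rc, label = i)
    list(spec = spec, trajectory = traj, ranges = rs, signal = sig)
  })
  names(recs) <- classes
  list(config = rc, recordings = recs)
}

#' Build the training database for a synthetic subject
#'
#' @param config An `experiment_config`.
#' @param seed Subject seed.
#' @param subject Optional pre-built [synth_subject()] output.
#' @param compress Logical; attach the PCA model at `config$d`.
#' @return A `training_db` (compressed when `compress = TRUE`), with the
#'   subject stored in `attr(, "subject")`.
#' @export
build_synthetic_db <- function(config, seed = config$seed, subject = NULL,
                               compress = TRUE) {
  subject <- subject %||% synth_subject(config, seed)
  recordings <- lapply(subject$recordings, function(r) {
    list(signal = r$signal, trajectory = r$trajectory)
  })
  db <- build_training_db(recordings, config$T_samp, config$dt_tr,
                          subject$config, T_end = config$T_end)
  if (compress) db <- compress_db(db, config$d)
  attr(db, "subject") <- subject
  db
}

#' Draw random-offset test segments from a subject's recordings
#'
#' Window starts are drawn uniformly on the signal sample grid within
#' `[0, T_end - T_samp]`; AWGN is added per segment at `snr_db`.
#'
#' @param subject A [synth_subject()] result (or one with modified signals).
#' @param config An `experiment_config`.
#' @param snr_db SNR in dB (`Inf` = no noise).
#' @param seed Seed for offsets and noise.
#' @return List with `segments` (list of `radar_signal`) and `truths`.
#' @export
draw_test_segments <- function(subject, config, snr_db = Inf,
                               seed = config$seed) {
  Ls <- round(config$T_samp * config$rate)
  segs <- list(); truths <- integer(0)
  for (i in seq_along(subject$recordings)) {
    rec <- subject$recordings[[i]]
    s <- rec$signal$samples
    max_i0 <- min(length(s), round(config$T_end * config$rate)) - Ls
    withr::with_seed(.sub_seed(seed, 100 + i), {
      i0s <- sample.int(max_i0 + 1L, config$n_test, replace = TRUE) - 1L
    })
    for (k in seq_along(i0s)) {
      seg <- radar_signal(s[(i0s[k] + 1):(i0s[k] + Ls)], config$rate,
                          subject$config, label = i)
      seg <- add_awgn(seg, snr_db, seed = .sub_seed(seed, 1000 * i + k))
      segs[[length(segs) + 1L]] <- seg
      truths <- c(truths, i)
    }
  }
  list(segments = segs, truths = truths)
}

#' Classify a list of test segments
#'
#' @param segments List of `radar_signal` windows.
#' @param db A compressed `training_db`.
#' @param mode Passed to [classify_signal()].
#' @return Integer vector of predicted labels.
#' @export
classify_segments <- function(segments, db, mode = "per_instance") {
  if (mode == "per_instance") db <- precompute_test_banks(db)
  vapply(segments, classify_signal, integer(1), db = db, mode = mode)
}

#' Residual-term validation of the matched-basis amplitude recovery
#'
#' For each trial, draws a random micro-motion ensemble (default four
#' scatterers of amplitude 2, three components each, frequencies in 0-2 Hz,
#' displacement amplitudes in `[0, 4*pi/lambda]`, phases in `[0, 2*pi)`),
#' simulates the 3-s baseband sum and splits the inner product with scatterer
#' 1's basis into the matched amplitude `A1` and the cross-scatterer residual
#' `Rs`. With periodic micro-motions and an observation much longer than
#' their periods, `|Rs|` is far below `A1`.
#'
#' @param n_trials Number of seeded trials.
#' @param seed Base seed.
#' @param f0 Carrier (Hz).
#' @param T_obs Observation duration (s).
#' @param dt Sampling interval (s).
#' @param n_scatterers,n_components Ensemble shape.
#' @param amplitude Common scatterer amplitude.
#' @return Data frame with one row per trial: recovered `A1` (modulus of the
#'   inner product), `Rs_abs` (`|inner - amplitude|`) and `Rs_direct_abs`
#'   (residual recomputed independently from the cross terms).
#' @export
validate_residual <- function(n_trials = 100L, seed = 1L, f0 = 5.8e9,
                              T_obs = 3, dt = 0.001, n_scatterers = 4L,
                              n_components = 3L, amplitude = 2) {
  lambda <- 3e8 / f0
  t <- seq(0, T_obs - dt, by = dt)
  res <- lapply(seq_len(n_trials), function(tr) {
    spec <- sample_random_mm(n_scatterers, n_components,
                             freq_range_hz = c(0, 2),
                             amp_range = c(0, 4 * pi / lambda),
                             phase_range = c(0, 2 * pi),
                             seed = .sub_seed(seed, tr))
    mm <- eval_micromotion(spec, t)
    ph <- exp(-1i * (4 * pi / lambda) * mm)
    s <- colSums(amplitude * ph)
    inner <- mean(s * Conj(ph[1, ]))
    # independent route: cross terms only
    rs_direct <- 0 + 0i
    for (i in seq_len(n_scatterers)[-1]) {
      rs_direct <- rs_direct +
        amplitude * mean(exp(1i * (4 * pi / lambda) * (mm[1, ] - mm[i, ])))
    }
    data.frame(trial = tr, A1 = Mod(inner),
               Rs_abs = Mod(inner - amplitude),
               Rs_direct_abs = Mod(rs_direct))
  })
  do.call(rbind, res)
}

# internal: classify a drawn test set and return an eval_result
.evaluate_test_set <- function(test, db, mode) {
  preds <- classify_segments(test$segments, db, mode = mode)
  evaluate(preds, test$truths, n_classes = length(db$classes))
}

#' Accuracy over an SNR x PCA-dimension grid
#'
#' Builds one synthetic subject's training database, then classifies seeded
#' random test segments for every combination of SNR and retained dimension.
#' Test offsets are shared across cells so only the noise and the projection
#' vary.
#'
#' @param config An `experiment_config` (its `snr_db` supplies the SNR grid).
#' @param dims PCA dimensions to evaluate.
#' @param seed Base seed.
#' @param db Optional pre-built database (avoids rebuilding).
#' @return List with `results` (data frame of SNR, d, Pc) and `confusions`
#'   (named list of confusion matrices).
#' @export
run_snr_d_grid <- function(config, dims = 3:6, seed = config$seed, db = NULL) {
  db <- db %||% build_synthetic_db(config, seed, compress = FALSE)
  if (config$mode == "per_instance") db <- precompute_test_banks(db)
  subject <- attr(db, "subject")
  rows <- list(); confusions <- list()
  for (snr in config$snr_db) {
    test <- draw_test_segments(subject, config, snr_db = snr, seed = seed)
    # features do not depend on d: extract once per SNR, reuse across dims
    tfs <- lapply(test$segments, test_feature, db = db, mode = config$mode)
    for (d in dims) {
      dbd <- compress_db(db, d)
      preds <- vapply(tfs, classify_from_features, integer(1), db = dbd,
                      mode = config$mode)
      ev <- evaluate(preds, test$truths, n_classes = length(db$classes))
      key <- sprintf("snr%s_d%d", snr, d)
      rows[[key]] <- data.frame(snr_db = snr, d = d, Pc = ev$Pc)
      confusions[[key]] <- ev$confusion
    }
  }
  list(results = do.call(rbind, c(rows, make.row.names = FALSE)),
       confusions = confusions)
}

#' Accuracy versus training stride dt_tr
#'
#' Rebuilds the training database for each stride; the training-vector count
#' per class follows `floor((T_end - T_samp)/dt_tr)` independently of the
#' data.
#'
#' @param config An `experiment_config` (`d`, `T_samp` fixed).
#' @param dttrs Stride values (s).
#' @param snr_db Test SNR.
#' @param seed Base seed.
#' @return Data frame of `dt_tr`, `N_tr` (per class), `Pc`.
#' @export
run_dttr_sweep <- function(config, dttrs = seq(0.02, 0.42, by = 0.10),
                           snr_db = 10, seed = config$seed) {
  subject <- synth_subject(config, seed)
  rows <- lapply(dttrs, function(dt_tr) {
    cfg <- config; cfg$dt_tr <- dt_tr
    db <- build_synthetic_db(cfg, seed, subject = subject)
    test <- draw_test_segments(subject, cfg, snr_db = snr_db, seed = seed)
    ev <- .evaluate_test_set(test, db, cfg$mode)
    data.frame(dt_tr = dt_tr,
               N_tr = n_segments(cfg$T_end, cfg$T_samp, dt_tr),
               Pc = ev$Pc)
  })
  do.call(rbind, rows)
}

#' Accuracy versus window length T_samp
#'
#' @param config An `experiment_config`.
#' @param tsamps Window lengths (s).
#' @param snr_db Test SNR.
#' @param seed Base seed.
#' @return Data frame of `T_samp`, `N_tr` (per class), `Pc`.
#' @export
run_tsamp_sweep <- function(config, tsamps = seq(0.4, 1.2, by = 0.2),
                            snr_db = 10, seed = config$seed) {
  subject <- synth_subject(config, seed)
  rows <- lapply(tsamps, function(T_samp) {
    cfg <- config; cfg$T_samp <- T_samp
    db <- build_synthetic_db(cfg, seed, subject = subject)
    test <- draw_test_segments(subject, cfg, snr_db = snr_db, seed = seed)
    ev <- .evaluate_test_set(test, db, cfg$mode)
    data.frame(T_samp = T_samp,
               N_tr = n_segments(cfg$T_end, T_samp, cfg$dt_tr),
               Pc = ev$Pc)
  })
  do.call(rbind, rows)
}

#' Robustness studies: time scaling, two-motion mixtures, body variation
#'
#' * `time_scale`: test trajectories are slowed by factors `beta`, re-simulated
#'   and classified (training unchanged); `beta = 1` reproduces the baseline
#'   exactly under the same seeds.
#' * `mixture`: pairs of test segments from different classes are summed; a
#'   prediction counts as correct when it matches either component's label
#'   (stated in the output attributes).
#' * `body_variation`: each test segment passes through [perturb_signal()]
#'   with the given fraction and magnitude.
#'
#' @param config An `experiment_config`.
#' @param test One of `"time_scale"`, `"mixture"`, `"body_variation"`.
#' @param betas Time-scale factors (time_scale only).
#' @param snr_db Test SNR (the robustness studies use a high SNR so the
#'   perturbation, not noise, dominates).
#' @param fraction,magnitude Perturbation parameters (body_variation only).
#' @param seed Base seed.
#' @param db Optional pre-built compressed database.
#' @return Data frame of condition and `Pc`; mixtures carry
#'   `attr(, "scoring") = "either_label"`.
#' @export
run_robustness <- function(config,
                           test = c("time_scale", "mixture", "body_variation"),
                           betas = seq(1.0, 2.0, by = 0.1), snr_db = 30,
                           fraction = 0.5, magnitude = 0.5,
                           seed = config$seed, db = NULL) {
  test <- match.arg(test)
  db <- db %||% build_synthetic_db(config, seed)
  if (config$mode == "per_instance") db <- precompute_test_banks(db)
  subject <- attr(db, "subject")

  if (test == "time_scale") {
    rows <- lapply(betas, function(beta) {
      subj_b <- subject
      for (i in seq_along(subj_b$recordings)) {
        traj_b <- time_scale(subj_b$recordings[[i]]$trajectory, beta)
        rs_b <- resample_ranges(ranges_from_markers(traj_b, subject$config),
                                config$rate)
        subj_b$recordings[[i]]$signal <-
          simulate_baseband(rs_b, config = subject$config, label = i)
      }
      cfg <- config
      # slowed recordings keep their duration; segment within the support
      test_set <- draw_test_segments(subj_b, cfg, snr_db = snr_db, seed = seed)
      ev <- .evaluate_test_set(test_set, db, config$mode)
      data.frame(beta = beta, Pc = ev$Pc)
    })
    do.call(rbind, rows)
  } else if (test == "mixture") {
    test_set <- draw_test_segments(subject, config, snr_db = Inf, seed = seed)
    n <- length(test_set$segments)
    withr::with_seed(.sub_seed(seed, 7), {
      ia <- sample.int(n)
      ib <- vapply(ia, function(i) {
        pool <- which(test_set$truths != test_set$truths[i])
        pool[sample.int(length(pool), 1L)]
      }, integer(1))
    })
    correct <- logical(length(ia))
    for (k in seq_along(ia)) {
      mixed <- mix_signals(test_set$segments[[ia[k]]],
                           test_set$segments[[ib[k]]])
      mixed <- add_awgn(mixed, snr_db, seed = .sub_seed(seed, 5000 + k))
      pred <- classify_signal(mixed, db, mode = config$mode)
      correct[k] <- pred %in% c(test_set$truths[ia[k]], test_set$truths[ib[k]])
    }
    out <- data.frame(condition = "two_motion_mixture",
                      Pc = mean(correct), n = length(ia))
    attr(out, "scoring") <- "either_label"
    out
  } else {
    test_set <- draw_test_segments(subject, config, snr_db = snr_db,
                                   seed = seed)
    segs <- lapply(seq_along(test_set$segments), function(k) {
      perturb_signal(test_set$segments[[k]], fraction, magnitude,
                     seed = .sub_seed(seed, 9000 + k))
    })
    ev <- .evaluate_test_set(list(segments = segs, truths = test_set$truths),
                             db, config$mode)
    data.frame(condition = "body_variation", Pc = ev$Pc,
               fraction = fraction, magnitude = magnitude)
  }
}

#' Write an experiment results table to a tab-delimited file
#' @param df Data frame.
#' @param file Output path.
#' @export
write_results_table <- function(df, file) {
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a confusion matrix to a tab-delimited file
#' @param confusion Square count matrix.
#' @param file Output path.
#' @export
write_confusion <- function(confusion, file) {
  write.table(confusion, file, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(file)
}
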