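# Basis functions and maximum circular cross-correlation features.
#
# Marker k's range history defines the unit-modulus basis
#   b_k(t) = exp(-j 4 pi r_k(t) / lambda),
# and the feature extracted from a radar signal s(t) is the maximum over all
# integer circular shifts tau of |(1/T) sum_t s(t) conj(b_k(t - tau))|,
# computed in the frequency domain. The basis spectrum is conjugated so the
# fast form realizes a correlation (not a convolution); the 1/T averaging
# means a basis-matched signal of amplitude A returns exactly A.

#' Build a unit-modulus basis function from a range series
#'
#' @param range_series Numeric vector of ranges in meters (finite; offsets are
#'   immaterial, only phase differences matter).
#' @param lambda Wavelength in meters.
#' @param marker_index,rate,class_label Optional metadata.
#' @return A `basis_function` with complex `values` of modulus 1.
#' @export
basis_function <- function(range_series, lambda, marker_index = NA_integer_,
                           rate = NA_real_, class_label = NA_integer_) {
  stopifnot(is.numeric(range_series), all(is.finite(range_series)))
  .check_number(lambda, "lambda", min = 0, strict_min = TRUE)
  structure(list(values = exp(-1i * (4 * pi / lambda) * range_series),
                 marker_index = as.integer(marker_index), rate = rate,
                 class_label = as.integer(class_label)),
            class = "basis_function")
}

#' Build a bank of basis functions from per-marker ranges
#'
#' @param ranges `n_markers x T` matrix of ranges in meters.
#' @param lambda Wavelength in meters.
#' @param rate Sampling rate in Hz.
#' @param class_label Class the reference recording belongs to.
#' @param t0 Start time of the source window in the recording (s).
#' @return A `basis_bank`: complex `B` (`T x n_markers`), its precomputed
#'   conjugated spectra `BF`, and metadata.
#' @export
basis_bank <- function(ranges, lambda, rate, class_label = NA_integer_,
                       t0 = 0) {
  if (is.null(dim(ranges))) ranges <- matrix(ranges, nrow = 1L)
  stopifnot(all(is.finite(ranges)))
  B <- t(exp(-1i * (4 * pi / lambda) * ranges))
  structure(list(B = B, BF = Conj(mvfft(B)), rate = rate,
                 class_label = as.integer(class_label), t0 = t0,
                 n_markers = ncol(B)),
            class = "basis_bank")
}

#' @export
print.basis_bank <- function(x, ...) {
  cat(sprintf("<basis_bank> %d bases x %d samples @ %g Hz (class %s, t0 %.3f)\n",
              x$n_markers, nrow(x$B), x$rate, x$class_label, x$t0))
  invisible(x)
}

.as_complex_vec <- function(x) {
  if (inherits(x, "radar_signal")) x$samples
  else if (inherits(x, "basis_function")) x$values
  else as.complex(x)
}

#' Maximum circular cross-correlation amplitude
#'
#' `A_k = max_tau | (1/T) sum_t s(t) conj(b(t - tau mod T)) |`, evaluated for
#' all integer shifts at once via FFT. Shift-invariant in the signal and
#' scale-equivariant; a signal equal to `A * b` (up to circular shift)
#' returns `A`.
#'
#' @param signal A `radar_signal` or complex vector.
#' @param basis A `basis_function` or complex vector of the same length.
#' @return Nonnegative scalar amplitude.
#' @export
max_xcorr_amplitude <- function(signal, basis) {
  s <- .as_complex_vec(signal)
  b <- .as_complex_vec(basis)
  if (length(s) != length(b))
    stop("signal and basis must have equal length", call. = FALSE)
  nT <- length(s)
  cc <- fft(fft(s) * Conj(fft(b)), inverse = TRUE) / nT
  max(Mod(cc)) / nT
}

#' Feature vector of a signal against a basis bank
#'
#' Element `k` is [max_xcorr_amplitude()] of the signal against basis `k`.
#'
#' @param signal A `radar_signal` or complex vector whose length matches the
#'   bank's.
#' @param bank A `basis_bank`.
#' @return Numeric feature vector of length `n_markers` (unnormalized).
#' @export
feature_vector <- function(signal, bank) {
  stopifnot(inherits(bank, "basis_bank"))
  if (bank$n_markers < 1L) stop("empty basis bank", call. = FALSE)
  s <- .as_complex_vec(signal)
  nT <- nrow(bank$B)
  if (length(s) != nT)
    stop("signal length does not match the basis bank", call. = FALSE)
  S <- fft(s)
  cc <- mvfft(S * bank$BF, inverse = TRUE) / nT
  apply(Mod(cc), 2, max) / nT
}

# Segment-count arithmetic: floor((T_end - T_samp)/dt_tr) windows starting at
# 0, dt_tr, 2 dt_tr, ...; a single full-length window when T_samp = T_end.
# The small epsilon guards against binary-representation shortfall
# (e.g. 2.8/0.02 evaluating just below 140).

#' Number of sliding-window segments in a recording
#'
#' @param T_end Recording duration (s).
#' @param T_samp Window length (s), `<= T_end`.
#' @param dt_tr Window stride (s), `> 0`.
#' @return Integer segment count.
#' @export
n_segments <- function(T_end, T_samp, dt_tr) {
  .check_number(T_end, "T_end", min = 0, strict_min = TRUE)
  .check_number(T_samp, "T_samp", min = 0, strict_min = TRUE)
  .check_number(dt_tr, "dt_tr", min = 0, strict_min = TRUE)
  if (T_samp > T_end + 1e-12)
    stop("T_samp exceeds the recording duration", call. = FALSE)
  max(1L, as.integer(floor((T_end - T_samp) / dt_tr + 1e-9)))
}

#' Segment start times
#' @inheritParams n_segments
#' @return Numeric vector of window start times (s).
#' @export
segment_starts <- function(T_end, T_samp, dt_tr) {
  (seq_len(n_segments(T_end, T_samp, dt_tr)) - 1) * dt_tr
}

#' Clip a recording into time-aligned signal/marker segment pairs
#'
#' Windows of length `T_samp` start at `0, dt_tr, 2*dt_tr, ...`; each pair
#' shares its start time `t0`.
#'
#' @param signal A `radar_signal` covering the recording.
#' @param traj The time-aligned `marker_trajectory` (possibly at a different
#'   rate).
#' @param T_samp Window length (s).
#' @param dt_tr Stride (s).
#' @param T_end Nominal recording duration (s); defaults to the signal
#'   duration.
#' @return List of `list(signal =, markers =, t0 =)` pairs.
#' @export
segment_recording <- function(signal, traj, T_samp, dt_tr, T_end = NULL) {
  stopifnot(inherits(signal, "radar_signal"),
            inherits(traj, "marker_trajectory"))
  T_end <- T_end %||% (length(signal$samples) / signal$rate)
  starts <- segment_starts(T_end, T_samp, dt_tr)
  Ls <- round(T_samp * signal$rate)
  Lm <- round(T_samp * traj$rate)
  lapply(starts, function(t0) {
    i0 <- round(t0 * signal$rate)
    j0 <- round(t0 * traj$rate)
    if (i0 + Ls > length(signal$samples) ||
        j0 + Lm > dim(traj$positions)[2])
      stop("segment extends beyond the available samples", call. = FALSE)
    list(signal = radar_signal(signal$samples[(i0 + 1):(i0 + Ls)],
                               signal$rate, signal$config, signal$label),
         markers = marker_trajectory(
           traj$positions[, (j0 + 1):(j0 + Lm), , drop = FALSE],
           traj$rate, t0 = t0, class_label = traj$class_label),
         t0 = t0)
  })
}

#' Min-max normalize feature vectors with stored training extrema
#'
#' `(f - fmin) / (fmax - fmin)` per coordinate. Test values outside the
#' training range map outside `[0, 1]` and are not clipped.
#'
#' @param f Feature vector, or matrix with one feature vector per column.
#' @param fmin,fmax Per-feature training minima and maxima
#'   (`fmax > fmin` elementwise).
#' @return Normalized vector or matrix.
#' @export
normalize_features <- function(f, fmin, fmax) {
  if (any(!(fmax > fmin)))
    stop("fmax must exceed fmin in every coordinate; degenerate rows: ",
         paste(which(!(fmax > fmin)), collapse = ", "), call. = FALSE)
  if (is.matrix(f)) (f - fmin) / (fmax - fmin)
  else (f - fmin) / (fmax - fmin)
}

# internal: signal-rate ranges for one recording (marker rate -> signal rate)
.signal_rate_ranges <- function(traj, config) {
  rs <- ranges_from_markers(traj, config)
  resample_ranges(rs, config$rate)
}

#' Build the training database from labeled recordings
#'
#' For every class recording, per-marker ranges are resampled to the radar
#' rate; each clipped training window's feature vector is computed against a
#' basis bank built from its own time-aligned marker segment. The assembled
#' `n_markers x N_tr` feature matrix is min-max normalized per feature.
#'
#' @param recordings List of `list(signal =, trajectory =)` pairs, one per
#'   class (labels taken from the trajectory, or the signal as fallback).
#' @param T_samp Window length (s).
#' @param dt_tr Stride (s).
#' @param config A `radar_config`.
#' @param T_end Nominal recording duration (s); defaults to the signal
#'   duration of each recording.
#' @return A `training_db` with the raw and normalized feature matrices,
#'   labels, per-feature extrema, per-class signal-rate range matrices and
#'   offset-0 basis banks, and the segmentation parameters.
#' @export
build_training_db <- function(recordings, T_samp, dt_tr, config,
                              T_end = NULL) {
  stopifnot(is.list(recordings), inherits(config, "radar_config"))
  labels_in <- vapply(recordings, function(rec) {
    lb <- rec$trajectory$class_label
    if (is.na(lb)) lb <- rec$signal$label
    as.integer(lb)
  }, integer(1))
  if (any(is.na(labels_in)) || length(unique(labels_in)) < 2L)
    stop("need labeled recordings from at least 2 classes", call. = FALSE)

  feats <- list(); labels <- integer(0)
  ranges_by_class <- list(); banks0 <- list(); offsets_by_class <- list()
  Ls <- round(T_samp * config$rate)
  for (rec in recordings) {
    lb <- rec$trajectory$class_label
    if (is.na(lb)) lb <- rec$signal$label
    rs <- .signal_rate_ranges(rec$trajectory, config)
    s <- rec$signal$samples
    Tsig <- min(ncol(rs$ranges), length(s))
    Te <- T_end %||% (length(s) / config$rate)
    starts <- segment_starts(Te, T_samp, dt_tr)
    i0s <- round(starts * config$rate)
    if (any(i0s + Ls > Tsig))
      stop("training windows extend beyond the recording", call. = FALSE)
    fmat <- vapply(i0s, function(i0) {
      bank <- basis_bank(rs$ranges[, (i0 + 1):(i0 + Ls), drop = FALSE],
                         config$lambda, config$rate, class_label = lb,
                         t0 = i0 / config$rate)
      feature_vector(s[(i0 + 1):(i0 + Ls)], bank)
    }, numeric(nrow(rs$ranges)))
    feats[[length(feats) + 1L]] <- fmat
    labels <- c(labels, rep(lb, length(i0s)))
    key <- as.character(lb)
    ranges_by_class[[key]] <- rs$ranges[, seq_len(Tsig), drop = FALSE]
    offsets_by_class[[key]] <- i0s
    banks0[[key]] <- basis_bank(rs$ranges[, 1:Ls, drop = FALSE],
                                config$lambda, config$rate,
                                class_label = lb, t0 = 0)
  }
  F <- do.call(cbind, feats)
  fmin <- apply(F, 1, min)
  fmax <- apply(F, 1, max)
  if (any(fmax <= fmin))
    stop("degenerate feature row(s) (fmax == fmin): ",
         paste(which(fmax <= fmin), collapse = ", "), call. = FALSE)
  structure(list(
    F = F, Fnorm = normalize_features(F, fmin, fmax),
    labels = labels, classes = sort(unique(labels)),
    fmin = fmin, fmax = fmax,
    ranges = ranges_by_class, banks0 = banks0,
    offsets = offsets_by_class,
    segmentation = list(T_end = T_end, T_samp = T_samp, dt_tr = dt_tr,
                        seg_len = Ls),
    config = config, pca = NULL, X = NULL),
    class = "training_db")
}

#' @export
print.training_db <- function(x, ...) {
  cat(sprintf("<training_db> %d features x %d segments, %d classes%s\n",
              nrow(x$F), ncol(x$F), length(x$classes),
              if (is.null(x$pca)) "" else sprintf(", PCA d = %d", x$pca$d)))
  invisible(x)
}

#' Precompute per-instance basis-bank spectra for fast test features
#'
#' For every training window of every class, stores the conjugated FFT
#' spectra of that window's time-aligned basis functions, so that
#' `per_instance` test features reduce to one batched inverse FFT per class.
#' Memory grows as `window length x n_markers x N_tr` complex values, so this
#' is intended for desk-scale configurations.
#'
#' @param db A `training_db`.
#' @return The database with the spectra attached (`BF_by_class`).
#' @export
precompute_test_banks <- function(db) {
  stopifnot(inherits(db, "training_db"))
  if (!is.null(db$BF_by_class)) return(db)
  Ls <- db$segmentation$seg_len
  lambda <- db$config$lambda
  db$BF_by_class <- lapply(as.character(db$classes), function(key) {
    R <- db$ranges[[key]]
    slabs <- lapply(db$offsets[[key]], function(i0) {
      t(exp(-1i * (4 * pi / lambda) * R[, (i0 + 1):(i0 + Ls), drop = FALSE]))
    })
    Conj(mvfft(do.call(cbind, slabs)))  # Ls x (n_markers * n_windows)
  })
  names(db$BF_by_class) <- as.character(db$classes)
  db
}

#' Compute per-class test features for a radar signal
#'
#' In `per_instance` mode (default) the feature vector is computed against
#' every training window's own time-aligned basis bank, reconstructing the
#' conditions under which each stored training feature was extracted; this is
#' how test features are matched to a database whose windows sample motion
#' cycles longer than the window itself. In `per_class` mode a single
#' offset-0 bank per class is used (fast approximation: the circular-shift
#' maximum only partially absorbs window misalignment).
#'
#' @param signal A `radar_signal` of exactly one training window length.
#' @param db A `training_db` (run [precompute_test_banks()] first for speed
#'   in `per_instance` mode).
#' @param mode `"per_instance"` or `"per_class"`.
#' @return `per_class`: `n_markers x P` matrix (one normalized feature vector
#'   per class). `per_instance`: list over classes of
#'   `n_markers x n_windows` normalized feature matrices.
#' @export
test_feature <- function(signal, db, mode = c("per_instance", "per_class")) {
  stopifnot(inherits(db, "training_db"))
  mode <- match.arg(mode)
  s <- .as_complex_vec(signal)
  Ls <- db$segmentation$seg_len
  if (length(s) != Ls)
    stop("test signal must have exactly one window length (", Ls, " samples)",
         call. = FALSE)
  keys <- as.character(db$classes)
  n_feat <- nrow(db$F)
  if (mode == "per_class") {
    out <- vapply(keys, function(key) {
      normalize_features(feature_vector(s, db$banks0[[key]]),
                         db$fmin, db$fmax)
    }, numeric(n_feat))
    colnames(out) <- keys
    return(out)
  }
  S <- fft(s)
  res <- lapply(keys, function(key) {
    if (!is.null(db$BF_by_class)) {
      BF <- db$BF_by_class[[key]]
      cc <- mvfft(S * BF, inverse = TRUE)
      m2 <- Re(cc)^2 + Im(cc)^2  # defer the sqrt to the per-column maximum
      peak <- m2[cbind(max.col(t(m2), "first"), seq_len(ncol(m2)))]
      f <- matrix(sqrt(peak) / (Ls * Ls), nrow = n_feat)
    } else {
      R <- db$ranges[[key]]
      f <- vapply(db$offsets[[key]], function(i0) {
        bank <- basis_bank(R[, (i0 + 1):(i0 + Ls), drop = FALSE],
                           db$config$lambda, db$config$rate)
        feature_vector(s, bank)
      }, numeric(n_feat))
      f <- matrix(f, nrow = n_feat)
    }
    normalize_features(f, db$fmin, db$fmax)
  })
  names(res) <- keys
  res
}
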