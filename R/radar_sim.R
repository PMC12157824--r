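# CW-radar baseband point-scatterer simulation.
#
# A continuous-wave radar at carrier f0 sees scatterer i at range r_i(t) as
# the baseband phasor A_i exp(-j 4 pi r_i(t) / lambda); the received signal
# is the coherent sum over scatterers. Down-conversion is not simulated
# explicitly: the baseband form is generated directly.

#' Radar configuration
#'
#' @param f0 Carrier frequency in Hz (default 5.8 GHz).
#' @param rate Baseband sample rate in Hz (default 5 kHz).
#' @param radar_position Radar coordinates, meters (origin convention).
#' @param c0 Propagation speed, m/s.
#' @return A `radar_config` with derived wavelength `lambda = c0/f0`.
#' @export
radar_config <- function(f0 = 5.8e9, rate = 5000, radar_position = c(0, 0, 0),
                         c0 = 3e8) {
  .check_number(f0, "f0", min = 0, strict_min = TRUE)
  .check_number(rate, "rate", min = 0, strict_min = TRUE)
  stopifnot(length(radar_position) == 3L, all(is.finite(radar_position)))
  structure(list(f0 = f0, c0 = c0, lambda = c0 / f0, rate = rate,
                 radar_position = as.numeric(radar_position)),
            class = "radar_config")
}

#' @export
print.radar_config <- function(x, ...) {
  cat(sprintf("<radar_config> f0 = %.4g GHz (lambda = %.4f m), rate = %g Hz\n",
              x$f0 / 1e9, x$lambda, x$rate))
  invisible(x)
}

#' Per-marker range histories
#'
#' @param ranges `n_markers x T` matrix of ranges in meters. Entries may be
#'   relative (offset) ranges: only the phase they induce is used downstream.
#' @param rate Sampling rate in Hz.
#' @return A `range_set` object.
#' @export
range_set <- function(ranges, rate) {
  if (is.null(dim(ranges))) ranges <- matrix(ranges, nrow = 1L)
  stopifnot(is.matrix(ranges), all(is.finite(ranges)))
  .check_number(rate, "rate", min = 0, strict_min = TRUE)
  structure(list(ranges = ranges, rate = rate), class = "range_set")
}

#' Complex baseband radar signal container
#'
#' @param samples Complex sample vector (length >= 1, finite).
#' @param rate Sample rate in Hz.
#' @param config A `radar_config`.
#' @param label Integer class label or `NA`.
#' @return A `radar_signal` object.
#' @export
radar_signal <- function(samples, rate, config, label = NA_integer_) {
  samples <- as.complex(samples)
  stopifnot(length(samples) >= 1L, all(is.finite(Re(samples))),
            all(is.finite(Im(samples))), inherits(config, "radar_config"))
  structure(list(samples = samples, rate = rate, config = config,
                 label = as.integer(label)),
            class = "radar_signal")
}

#' @export
print.radar_signal <- function(x, ...) {
  cat(sprintf("<radar_signal> %d samples @ %g Hz (%.3f s), label %s\n",
              length(x$samples), x$rate, length(x$samples) / x$rate, x$label))
  invisible(x)
}

#' Euclidean marker-to-radar ranges
#'
#' @param traj A `marker_trajectory`.
#' @param config A `radar_config` (supplies the radar position).
#' @return A `range_set` of per-marker, per-sample distances.
#' @export
ranges_from_markers <- function(traj, config) {
  stopifnot(inherits(traj, "marker_trajectory"),
            inherits(config, "radar_config"))
  rp <- config$radar_position
  p <- traj$positions
  r <- sqrt((p[, , 1, drop = FALSE] - rp[1])^2 +
            (p[, , 2, drop = FALSE] - rp[2])^2 +
            (p[, , 3, drop = FALSE] - rp[3])^2)
  r <- matrix(r, dim(p)[1], dim(p)[2])
  if (any(r < 1e-9))
    stop("a marker coincides with the radar position (zero range)",
         call. = FALSE)
  range_set(r, traj$rate)
}

#' Resample range histories onto a new rate by cubic splines
#'
#' Interpolates each marker's range series onto the target grid over the
#' common time support (no extrapolation).
#'
#' @param rs A `range_set`.
#' @param target_rate Target sampling rate in Hz (> 0).
#' @return A `range_set` at `target_rate`.
#' @export
resample_ranges <- function(rs, target_rate) {
  stopifnot(inherits(rs, "range_set"))
  .check_number(target_rate, "target_rate", min = 0, strict_min = TRUE)
  if (target_rate == rs$rate) return(rs)
  nT <- ncol(rs$ranges)
  t_src <- (seq_len(nT) - 1) / rs$rate
  t_new <- (0:floor(t_src[nT] * target_rate + 1e-9)) / target_rate
  if (max(t_new) > t_src[nT] + 1e-12)
    stop("resampling would extrapolate beyond the source support",
         call. = FALSE)
  out <- matrix(0, nrow(rs$ranges), length(t_new))
  for (k in seq_len(nrow(rs$ranges))) {
    out[k, ] <- spline(t_src, rs$ranges[k, ], xout = t_new, method = "fmm")$y
  }
  range_set(out, target_rate)
}

#' Simulate the received complex baseband signal
#'
#' `samples[t] = sum_i A_i * exp(-j * 4 * pi * r_i(t) / lambda)`.
#'
#' @param rs A `range_set` at the radar sample rate.
#' @param amplitudes Length-`n_markers` nonnegative scatterer amplitudes
#'   (default all 1).
#' @param config A `radar_config` with `rate` equal to `rs$rate`.
#' @param label Optional class label carried on the output.
#' @return A `radar_signal`.
#' @export
simulate_baseband <- function(rs, amplitudes = NULL, config, label = NA_integer_) {
  stopifnot(inherits(rs, "range_set"), inherits(config, "radar_config"))
  if (rs$rate != config$rate)
    stop("range_set rate must equal the radar sample rate", call. = FALSE)
  n <- nrow(rs$ranges)
  if (is.null(amplitudes)) amplitudes <- rep(1, n)
  if (length(amplitudes) != n)
    stop("length(amplitudes) must equal the number of scatterers",
         call. = FALSE)
  stopifnot(all(is.finite(amplitudes)), all(amplitudes >= 0))
  ph <- exp(-1i * (4 * pi / config$lambda) * rs$ranges)
  samples <- colSums(amplitudes * ph)
  radar_signal(samples, config$rate, config, label = label)
}

#' Add circularly-symmetric complex white Gaussian noise at a target SNR
#'
#' Noise variance is set against the mean power of the input segment:
#' `sigma^2 = mean(|s|^2) / 10^(snr_db/10)`. `snr_db = Inf` is the no-noise
#' sentinel and returns the input unchanged.
#'
#' @param signal A `radar_signal`.
#' @param snr_db Target signal-to-noise ratio in dB (may be `Inf`).
#' @param seed Integer seed.
#' @return A `radar_signal`.
#' @export
add_awgn <- function(signal, snr_db, seed = 1L) {
  stopifnot(inherits(signal, "radar_signal"), length(signal$samples) >= 1L)
  if (is.infinite(snr_db) && snr_db > 0) return(signal)
  .check_number(snr_db, "snr_db")
  ps <- mean(Mod(signal$samples)^2)
  sigma2 <- ps / 10^(snr_db / 10)
  nT <- length(signal$samples)
  withr::with_seed(seed, {
    noise <- sqrt(sigma2 / 2) * complex(real = rnorm(nT), imaginary = rnorm(nT))
  })
  signal$samples <- signal$samples + noise
  signal
}

#' Short-time Fourier spectrogram of a baseband signal
#'
#' Hann-windowed STFT magnitude with a two-sided Doppler-frequency axis
#' centered at 0 Hz (baseband convention). A scatterer with radial velocity
#' `v = dr/dt` appears at Doppler frequency `-2 v / lambda`.
#'
#' @param signal A `radar_signal`.
#' @param window_s Window length in seconds (`window_s * rate >= 8`).
#' @param overlap_frac Fractional overlap between windows, in `[0, 1)`.
#' @param window Window taper: `"hann"` or `"rect"`.
#' @return A `radar_spectrogram`: list with `time` (frame centers, s),
#'   `freq` (Hz, ascending, 0-centered) and `mag` (`length(freq) x n_frames`
#'   magnitude matrix).
#' @export
spectrogram <- function(signal, window_s = 0.1, overlap_frac = 0.9,
                        window = c("hann", "rect")) {
  stopifnot(inherits(signal, "radar_signal"))
  window <- match.arg(window)
  L <- round(window_s * signal$rate)
  if (L < 8) stop("window must span at least 8 samples", call. = FALSE)
  if (!(overlap_frac >= 0 && overlap_frac < 1))
    stop("overlap_frac must be in [0, 1)", call. = FALSE)
  nT <- length(signal$samples)
  if (L > nT) stop("window longer than the signal", call. = FALSE)
  hop <- max(1L, round(L * (1 - overlap_frac)))
  starts <- seq(1L, nT - L + 1L, by = hop)
  w <- if (window == "hann") 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
       else rep(1, L)
  f_raw <- (0:(L - 1)) / L * signal$rate
  f_ctr <- ifelse(f_raw >= signal$rate / 2, f_raw - signal$rate, f_raw)
  ord <- order(f_ctr)
  mag <- vapply(starts, function(s0) {
    Mod(fft(w * signal$samples[s0:(s0 + L - 1L)]))[ord]
  }, numeric(L))
  structure(list(time = (starts - 1 + (L - 1) / 2) / signal$rate,
                 freq = f_ctr[ord], mag = mag,
                 window = window, window_s = window_s),
            class = "radar_spectrogram")
}

#' @export
print.radar_spectrogram <- function(x, ...) {
  cat(sprintf("<radar_spectrogram> %d freq bins x %d frames\n",
              length(x$freq), length(x$time)))
  invisible(x)
}

#' @export
plot.radar_spectrogram <- function(x, db_floor = -50, ...) {
  z <- 20 * log10(pmax(t(x$mag) / max(x$mag), 10^(db_floor / 20)))
  graphics::image(x$time, x$freq, z, xlab = "time (s)",
                  ylab = "Doppler frequency (Hz)", useRaster = TRUE, ...)
  invisible(x)
}
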