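# Synthetic marker micro-motion generation.
#
# Each marker (point scatterer) carries a scalar micro-motion
#   m(t) = sum_j a_j cos(w_j t + phi_j) + sum_j b_j sin(w_j t + phi_j)
# displacing it from a static 3-D offset along a fixed unit axis. This is the
# simplest geometry for which the marker range seen by the radar is, to first
# order, a static standoff plus the projected sinusoidal micro-motion.

#' Names of the built-in exercise motion classes
#'
#' @return Character vector of the five supported class names, in label order
#'   (class label 1 corresponds to the first name).
#' @export
motion_classes <- function() {
  c("squat", "lunge", "front_kick", "front_lateral_raise", "arm_curl")
}

#' Create a single sinusoidal micro-motion component
#'
#' @param kind `"cosine"` or `"sine"`.
#' @param amplitude Displacement amplitude in meters (>= 0).
#' @param angular_rate Angular rate in rad/s (>= 0).
#' @param phase Initial phase in radians; wrapped into `[0, 2*pi)`.
#' @return A `motion_component` list.
#' @export
motion_component <- function(kind, amplitude, angular_rate, phase = 0) {
  kind <- match.arg(kind, c("cosine", "sine"))
  .check_number(amplitude, "amplitude", min = 0)
  .check_number(angular_rate, "angular_rate", min = 0)
  .check_number(phase, "phase")
  structure(list(kind = kind, amplitude = amplitude,
                 angular_rate = angular_rate, phase = phase %% (2 * pi)),
            class = "motion_component")
}

#' Assemble a motion specification from per-marker entries
#'
#' @param markers List with one entry per marker; each entry is a list with
#'   `static_position` (3-vector, meters, radar at the origin), `motion_axis`
#'   (3-vector, normalized internally) and `components` (list of
#'   [motion_component()]).
#' @param class_label Integer class label (or `NA` for unknown).
#' @param class_name Optional class name.
#' @return A `motion_spec` object.
#' @export
motion_spec <- function(markers, class_label = NA_integer_,
                        class_name = NA_character_) {
  if (!is.list(markers) || length(markers) < 1L)
    stop("`markers` must be a non-empty list", call. = FALSE)
  markers <- lapply(markers, function(mk) {
    stopifnot(length(mk$static_position) == 3L, length(mk$motion_axis) == 3L)
    nrm <- sqrt(sum(mk$motion_axis^2))
    if (!is.finite(nrm) || nrm == 0)
      stop("motion_axis must be a nonzero 3-vector", call. = FALSE)
    # already-unit axes pass through untouched (keeps serialization exact)
    if (abs(nrm - 1) > 1e-12) mk$motion_axis <- mk$motion_axis / nrm
    mk
  })
  structure(list(markers = markers, class_label = as.integer(class_label),
                 class_name = class_name),
            class = "motion_spec")
}

#' @export
print.motion_spec <- function(x, ...) {
  cat(sprintf("<motion_spec> class %s (%s), %d markers\n",
              x$class_label, x$class_name, length(x$markers)))
  invisible(x)
}

# Per-class parameter envelopes for the template generator. Amplitudes are in
# meters per body region; f_dom is the dominant cycle frequency range in Hz
# (all dominant periods exceed 1.2 s, so short analysis windows undersample
# the motion cycle). front_lateral_raise and arm_curl share an amplitude
# envelope on purpose: they are the arm-only, hardest-to-separate pair.
.class_envelopes <- list(
  squat = list(
    f_dom = c(0.45, 0.55),
    amp = list(torso = c(0.18, 0.28), arm = c(0.02, 0.05), leg = c(0.12, 0.20)),
    axis = c(0, 0.30, -0.95)),
  lunge = list(
    f_dom = c(0.35, 0.42),
    amp = list(torso = c(0.08, 0.14), arm = c(0.03, 0.06), leg = c(0.20, 0.32)),
    axis = c(0, 0.70, -0.71)),
  front_kick = list(
    f_dom = c(0.60, 0.70),
    amp = list(torso = c(0.03, 0.06), arm = c(0.02, 0.04), leg = c(0.25, 0.45)),
    axis = c(0, 0.95, 0.31)),
  front_lateral_raise = list(
    f_dom = c(0.48, 0.52),
    amp = list(torso = c(0.004, 0.010), arm = c(0.25, 0.35), leg = c(0, 0)),
    axis = c(0.55, 0.45, 0.70)),
  arm_curl = list(
    f_dom = c(0.60, 0.66),
    amp = list(torso = c(0.004, 0.010), arm = c(0.25, 0.35), leg = c(0, 0)),
    axis = c(0, 0.75, 0.66))
)

#' Partition marker indices into torso/arm/leg groups
#'
#' Roughly 20% torso, 40% arms, 40% legs, each group non-empty.
#'
#' @param n_markers Total marker count (>= 4).
#' @return Named list of integer index vectors `torso`, `arm`, `leg`.
#' @export
marker_groups <- function(n_markers) {
  stopifnot(n_markers >= 4L)
  n_torso <- max(1L, round(0.2 * n_markers))
  n_arm <- max(1L, round(0.4 * n_markers))
  n_leg <- n_markers - n_torso - n_arm
  if (n_leg < 1L) {
    n_arm <- n_arm - (1L - n_leg)
    n_leg <- 1L
  }
  list(torso = seq_len(n_torso),
       arm = n_torso + seq_len(n_arm),
       leg = n_torso + n_arm + seq_len(n_leg))
}

#' Generate a seeded motion template for one exercise class
#'
#' Draws one "subject" performing the named exercise: a subject-level dominant
#' cycle frequency plus per-marker amplitudes, phases and motion axes inside a
#' fixed per-class envelope. Distinct marker groups are active per class
#' (lower body for squat/lunge/front kick; arms only for front lateral raise
#' and arm curl, whose amplitude envelopes coincide so they form the most
#' similar pair). Each marker carries a dominant component (period > 1.2 s)
#' and a weaker second harmonic.
#'
#' @param class_name One of [motion_classes()].
#' @param n_markers Number of markers (>= 4; default 30).
#' @param seed Integer seed; the same seed reproduces the same subject.
#' @return A `motion_spec` with `class_label` set to the class index.
#' @export
make_motion_template <- function(class_name, n_markers = 30L, seed = 1L) {
  if (!is.character(class_name) || length(class_name) != 1L ||
      !(class_name %in% motion_classes()))
    stop("unknown class_name; valid names: ",
         paste(motion_classes(), collapse = ", "), call. = FALSE)
  stopifnot(n_markers >= 4L)
  env <- .class_envelopes[[class_name]]
  grp <- marker_groups(n_markers)
  group_of <- character(n_markers)
  for (g in names(grp)) group_of[grp[[g]]] <- g

  withr::with_seed(seed, {
    f_dom <- runif(1, env$f_dom[1], env$f_dom[2])
    w_dom <- 2 * pi * f_dom
    markers <- vector("list", n_markers)
    for (k in seq_len(n_markers)) {
      g <- group_of[k]
      static <- switch(g,
        torso = c(runif(1, -0.15, 0.15), 1.5 + runif(1, -0.08, 0.08),
                  runif(1, 0.9, 1.4)),
        arm = c(sample(c(-1, 1), 1) * runif(1, 0.15, 0.45),
                1.5 + runif(1, -0.12, 0.12), runif(1, 0.8, 1.6)),
        leg = c(sample(c(-1, 1), 1) * runif(1, 0.05, 0.20),
                1.5 + runif(1, -0.10, 0.10), runif(1, 0.05, 0.90)))
      axis <- env$axis + rnorm(3, sd = 0.08)
      a <- runif(1, env$amp[[g]][1], env$amp[[g]][2])
      kind1 <- if (runif(1) < 0.5) "cosine" else "sine"
      kind2 <- if (kind1 == "cosine") "sine" else "cosine"
      comps <- list(
        motion_component(kind1, a, w_dom, runif(1, 0, 2 * pi)),
        motion_component(kind2, 0.25 * a, 2 * w_dom, runif(1, 0, 2 * pi)))
      markers[[k]] <- list(static_position = static, motion_axis = axis,
                           components = comps)
    }
    motion_spec(markers,
                class_label = match(class_name, motion_classes()),
                class_name = class_name)
  })
}

#' Draw a random micro-motion ensemble
#'
#' Every scatterer receives `n_components` sinusoidal components with the
#' kind (cosine/sine) chosen uniformly and the frequency, amplitude and
#' initial phase drawn uniformly from the given ranges. Amplitudes are in
#' meters. Scatterers sit at the origin and displace along the radar
#' boresight (y); for this ensemble the micro-motion itself plays the role of
#' the range history.
#'
#' @param n_scatterers Number of scatterers (>= 1).
#' @param n_components Components per scatterer (>= 1).
#' @param freq_range_hz Length-2 frequency range in Hz.
#' @param amp_range Length-2 amplitude range in meters.
#' @param phase_range Length-2 initial-phase range in radians.
#' @param seed Integer seed.
#' @return A `motion_spec`.
#' @export
sample_random_mm <- function(n_scatterers, n_components, freq_range_hz,
                             amp_range, phase_range, seed = 1L) {
  stopifnot(n_scatterers >= 1L, n_components >= 1L)
  for (rg in list(freq_range_hz, amp_range, phase_range)) {
    if (length(rg) != 2L || !all(is.finite(rg)) || rg[2] < rg[1])
      stop("ranges must be finite length-2 vectors with max >= min",
           call. = FALSE)
  }
  withr::with_seed(seed, {
    markers <- lapply(seq_len(n_scatterers), function(i) {
      comps <- lapply(seq_len(n_components), function(j) {
        motion_component(
          kind = if (runif(1) < 0.5) "cosine" else "sine",
          amplitude = runif(1, amp_range[1], amp_range[2]),
          angular_rate = 2 * pi * runif(1, freq_range_hz[1], freq_range_hz[2]),
          phase = runif(1, phase_range[1], phase_range[2]) %% (2 * pi))
      })
      list(static_position = c(0, 0, 0), motion_axis = c(0, 1, 0),
           components = comps)
    })
    motion_spec(markers)
  })
}

#' Evaluate the scalar micro-motion of every marker at given times
#'
#' @param spec A `motion_spec`.
#' @param t Numeric vector of times in seconds.
#' @return `n_markers x length(t)` matrix of displacements in meters.
#' @export
eval_micromotion <- function(spec, t) {
  stopifnot(inherits(spec, "motion_spec"))
  n <- length(spec$markers)
  mm <- matrix(0, n, length(t))
  for (k in seq_len(n)) {
    for (cp in spec$markers[[k]]$components) {
      fn <- if (cp$kind == "cosine") cos else sin
      mm[k, ] <- mm[k, ] + cp$amplitude * fn(cp$angular_rate * t + cp$phase)
    }
  }
  mm
}

#' Construct a marker trajectory container
#'
#' @param positions `n_markers x T x 3` array of coordinates in meters.
#' @param rate Sampling rate in Hz.
#' @param t0 Segment start time in the source recording (s).
#' @param class_label Integer class label or `NA`.
#' @return A `marker_trajectory` object.
#' @export
marker_trajectory <- function(positions, rate, t0 = 0,
                              class_label = NA_integer_) {
  stopifnot(is.array(positions), length(dim(positions)) == 3L,
            dim(positions)[3] == 3L, all(is.finite(positions)))
  .check_number(rate, "rate", min = 0, strict_min = TRUE)
  structure(list(positions = positions, rate = rate, t0 = t0,
                 class_label = as.integer(class_label)),
            class = "marker_trajectory")
}

#' @export
print.marker_trajectory <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("<marker_trajectory> %d markers x %d frames @ %g Hz (%.3f s)\n",
              d[1], d[2], x$rate, d[2] / x$rate))
  invisible(x)
}

#' Render a motion specification into a marker trajectory
#'
#' Positions are evaluated at `t = n/rate`, `n = 0 .. ceiling(duration*rate)-1`
#' as `static_position + motion_axis * micromotion(t)`. Deterministic.
#'
#' @param spec A `motion_spec`.
#' @param duration Duration in seconds (> 0).
#' @param rate Sampling rate in Hz (> 0).
#' @return A `marker_trajectory`.
#' @export
render_trajectory <- function(spec, duration, rate) {
  .check_number(duration, "duration", min = 0, strict_min = TRUE)
  .check_number(rate, "rate", min = 0, strict_min = TRUE)
  nT <- as.integer(ceiling(duration * rate))
  t <- (seq_len(nT) - 1) / rate
  mm <- eval_micromotion(spec, t)
  n <- length(spec$markers)
  pos <- array(0, c(n, nT, 3L))
  for (k in seq_len(n)) {
    st <- spec$markers[[k]]$static_position
    ax <- spec$markers[[k]]$motion_axis
    for (j in 1:3) pos[k, , j] <- st[j] + ax[j] * mm[k, ]
  }
  marker_trajectory(pos, rate, t0 = 0, class_label = spec$class_label)
}

#' Temporally scale a trajectory (slow the motion down)
#'
#' Output positions at time `t` are the source positions at `t/beta`
#' (cubic-spline interpolated), so `beta > 1` slows the motion. Sampling rate
#' is preserved; for `beta >= 1` the duration is preserved, for `beta < 1`
#' the output is truncated to the available source support.
#'
#' @param traj A `marker_trajectory`.
#' @param beta Time-scale factor (> 0); 1 is the identity.
#' @return A `marker_trajectory`.
#' @export
time_scale <- function(traj, beta) {
  stopifnot(inherits(traj, "marker_trajectory"))
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("`beta` must be a single number > 0", call. = FALSE)
  if (beta == 1) return(traj)
  d <- dim(traj$positions)
  t_src <- (seq_len(d[2]) - 1) / traj$rate
  t_out <- t_src
  t_need <- t_out / beta
  keep <- t_need <= t_src[d[2]] + 1e-12
  t_need <- t_need[keep]
  out <- array(0, c(d[1], length(t_need), 3L))
  for (k in seq_len(d[1])) {
    for (j in 1:3) {
      out[k, , j] <- spline(t_src, traj$positions[k, , j],
                            xout = t_need, method = "fmm")$y
    }
  }
  marker_trajectory(out, traj$rate, t0 = traj$t0, class_label = traj$class_label)
}

#' Randomly perturb amplitudes and phases of a radar signal
#'
#' A seeded random subset of `floor(fraction * T)` samples has its amplitude
#' multiplied by `1 + u` and its principal-value phase angle multiplied by an
#' independent `1 + u'`, with `u, u' ~ Uniform(-magnitude, magnitude)`.
#' Untouched samples are bit-identical to the input. Emulates body-dependent
#' scattering variability (RCS differences between individuals).
#'
#' @param signal A `radar_signal`.
#' @param fraction Proportion of samples perturbed, in `[0, 1]`.
#' @param magnitude Relative perturbation bound (>= 0); 0.5 means +/-50%.
#' @param seed Integer seed.
#' @return A `radar_signal`.
#' @export
perturb_signal <- function(signal, fraction, magnitude, seed = 1L) {
  stopifnot(inherits(signal, "radar_signal"))
  .check_number(fraction, "fraction", min = 0)
  stopifnot(fraction <= 1)
  .check_number(magnitude, "magnitude", min = 0)
  nT <- length(signal$samples)
  n_sel <- floor(fraction * nT)
  if (n_sel == 0L || magnitude == 0) return(signal)
  withr::with_seed(seed, {
    idx <- sample.int(nT, n_sel)
    u_amp <- runif(n_sel, -magnitude, magnitude)
    u_ph <- runif(n_sel, -magnitude, magnitude)
  })
  s <- signal$samples
  s[idx] <- Mod(s[idx]) * (1 + u_amp) * exp(1i * Arg(s[idx]) * (1 + u_ph))
  signal$samples <- s
  signal
}

#' Sum two radar signals sample-wise
#'
#' Used to emulate two subjects observed simultaneously.
#'
#' @param a,b `radar_signal` objects with equal length, rate and carrier.
#' @return A `radar_signal` (label `NA`).
#' @export
mix_signals <- function(a, b) {
  stopifnot(inherits(a, "radar_signal"), inherits(b, "radar_signal"))
  if (length(a$samples) != length(b$samples) || a$rate != b$rate ||
      a$config$f0 != b$config$f0)
    stop("signals must share length, sample rate and carrier frequency",
         call. = FALSE)
  radar_signal(a$samples + b$samples, a$rate, a$config, label = NA_integer_)
}
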