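## Synthetic-data generators: marker trajectories, scrum-engagement load
## profiles and EMG-like signals, each with known ground truth, plus toy
## model constructors used as oracles. Every generator is deterministic
## under a fixed seed and emits its ground truth alongside the observables.

#' Synthetic motion specification
#'
#' @param movement one of `"flexion_extension"`, `"lateral_bending"`,
#'   `"axial_rotation"`, `"humeral_elevation"`, `"scrum_engagement"`.
#' @param amplitude motion amplitude (deg) or peak force (N).
#' @param duration duration (s).
#' @param rate sampling rate (Hz).
#' @param noise_sd marker noise SD (m) or force noise fraction.
#' @param seed integer seed fixing all randomness.
#' @return list of class `cd_motion_spec`.
#' @export
motion_spec <- function(movement = "flexion_extension", amplitude = 40,
                        duration = 4, rate = 100, noise_sd = 0,
                        seed = 1L) {
  if (duration <= 0 || rate <= 0) {
    stop("duration and rate must be positive", call. = FALSE)
  }
  structure(list(movement = movement, amplitude = amplitude,
                 duration = duration, rate = rate, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "cd_motion_spec")
}

## smooth C^2 bump: 0 at the ends, 1 at mid-motion (raised-cosine squared)
smooth_bump <- function(s) (0.5 - 0.5 * cos(2 * pi * s))^2

#' Synthesize marker trajectories from a known coordinate motion
#'
#' Generates a smooth (C^2) trajectory of the coordinates that drive the
#' requested functional movement, runs forward kinematics of the model's
#' virtual marker set, and adds seeded isotropic Gaussian noise. The true
#' coordinate trajectory is returned alongside, so inverse-kinematics
#' round-trips have an exact reference.
#'
#' @param am a `cd_assembled` with virtual markers.
#' @param spec a `cd_motion_spec`.
#' @return list with `markers` (a `cd_markers`), `q_true` (data.frame
#'   `time` + coordinate columns, radians) and `spec`.
#' @export
synth_markers <- function(am, spec) {
  t <- seq(0, spec$duration, by = 1 / spec$rate)
  s <- t / spec$duration
  amp <- deg2rad(spec$amplitude)
  drive <- switch(spec$movement,
                  flexion_extension = list(neck_flexion = amp),
                  lateral_bending = list(neck_bending = amp),
                  axial_rotation = list(neck_rotation = amp),
                  humeral_elevation = list(humeral_elev_r = amp),
                  stop("unsupported movement '", spec$movement, "'",
                       call. = FALSE))
  qdef <- default_q(am)
  n <- length(t)
  qs <- matrix(rep(qdef, each = n), n, am$n_coords,
               dimnames = list(NULL, am$coords$name))
  for (nm in names(drive)) {
    ci <- am$coord_index[[nm]]
    if (is.na(ci)) stop("model lacks coordinate '", nm, "'", call. = FALSE)
    target <- qdef[ci] + drive[[nm]] * smooth_bump(s)
    lo <- am$coords$min[ci]; hi <- am$coords$max[ci]
    if (any(target < lo - 1e-9 | target > hi + 1e-9)) {
      stop("amplitude drives '", nm, "' outside its range", call. = FALSE)
    }
    qs[, ci] <- target
  }
  for (r in seq_len(n)) qs[r, ] <- enforce_couplers(am, qs[r, ])

  set.seed(spec$seed)
  mk_names <- vapply(am$markers, `[[`, character(1L), "name")
  mk <- lapply(seq_along(am$markers), function(i) {
    matrix(0, n, 3L)
  })
  names(mk) <- mk_names
  for (r in seq_len(n)) {
    fk <- forward_kinematics(am, qs[r, ], enforce = FALSE)
    for (i in seq_along(am$markers)) {
      d <- am$markers[[i]]
      mk[[i]][r, ] <- point_world(am, fk, d$segment, d$offset)
    }
  }
  if (spec$noise_sd > 0) {
    for (i in seq_along(mk)) {
      mk[[i]] <- mk[[i]] + matrix(stats::rnorm(3L * n, 0, spec$noise_sd),
                                  n, 3L)
    }
  }
  q_true <- data.frame(time = t, qs, check.names = FALSE)
  list(markers = marker_set(t, mk, rate = spec$rate), q_true = q_true,
       spec = spec)
}

#' Synthesize scrum-engagement external loads
#'
#' Emulates machine-scrummaging load streams: two shoulder forces applied at
#' the scapulae and two foot ground reactions. The profile has a
#' pre-engagement ramp, an engagement transient and a sustained-push phase
#' (a documented stylization of the phase structure of machine scrummaging,
#' not a fit to measured force spectra). Foot reactions carry body weight
#' plus the vertical component of the push reaction; seeded band-limited
#' jitter is added at `noise_sd` fraction of the peak.
#'
#' @param spec a `cd_motion_spec` (`amplitude` = peak horizontal engagement
#'   force in N; `movement` is ignored).
#' @param body_mass supported body mass (kg) for the foot loads.
#' @param t_engage engagement onset time (s).
#' @param push_fraction sustained-push force as a fraction of peak.
#' @return list of class `cd_scrum_loads`: `time`, `shoulder_r`,
#'   `shoulder_l`, `foot_r`, `foot_l` (n x 3 force matrices, ground frame:
#'   x forward, y up), `t_engage`, and the ground-truth `profile`.
#' @export
synth_scrum_loads <- function(spec, body_mass = 110, t_engage = NULL,
                              push_fraction = 0.6) {
  t <- seq(0, spec$duration, by = 1 / spec$rate)
  n <- length(t)
  peak <- spec$amplitude
  if (peak < 0) stop("peak force must be non-negative", call. = FALSE)
  if (is.null(t_engage)) t_engage <- 0.4 * spec$duration
  t_peak <- t_engage + 0.08            # engagement transient ~80 ms
  t_sustain <- t_peak + 0.25
  profile <- numeric(n)
  ramp <- t >= t_engage & t < t_peak
  profile[ramp] <- peak * (t[ramp] - t_engage) / (t_peak - t_engage)
  decay <- t >= t_peak & t < t_sustain
  profile[decay] <- peak * (push_fraction + (1 - push_fraction) *
                              (1 - (t[decay] - t_peak) /
                                 (t_sustain - t_peak)))
  profile[t >= t_sustain] <- peak * push_fraction
  ## small pre-engagement crouch/bind bump, finished well before onset so
  ## the engagement time is recoverable to one sample
  pre <- t < 0.8 * t_engage
  profile[pre] <- 0.002 * peak * smooth_bump(
    pmin(t[pre] / max(0.8 * t_engage, 1e-9), 1))

  set.seed(spec$seed + 1L)
  jitter <- function() {
    if (spec$noise_sd <= 0 || peak == 0) return(numeric(n))
    raw <- stats::rnorm(n)
    ma <- moving_average(raw, max(3L, round(spec$rate * 0.02)))
    spec$noise_sd * peak * ma / max(stats::sd(ma), 1e-12)
  }
  half <- profile / 2
  shoulder <- function() {
    cbind(x = -(half + jitter()), y = -0.15 * (half + jitter()), z = 0)
  }
  g <- 9.81
  w_half <- body_mass * g / 2
  foot <- function() {
    cbind(x = half + jitter(),            # push reaction through the feet
          y = w_half + 0.1 * (half + jitter()), z = 0)
  }
  structure(list(time = t, shoulder_r = shoulder(), shoulder_l = shoulder(),
                 foot_r = foot(), foot_l = foot(),
                 t_engage = t_engage, profile = profile, spec = spec),
            class = "cd_scrum_loads")
}

#' Segment the engagement onset from a scrum load trace
#'
#' Detects the first sample where the shoulder force magnitude rises above
#' the pre-engagement baseline (0.5% of peak plus baseline noise), the
#' generator's definition of engagement onset.
#'
#' @param loads a `cd_scrum_loads`.
#' @return onset time (s).
#' @export
detect_engagement <- function(loads) {
  mag <- sqrt(rowSums(loads$shoulder_r^2) + rowSums(loads$shoulder_l^2))
  pk <- max(mag)
  if (pk <= 0) return(NA_real_)
  ## baseline from the first decile of samples; onset = first sample
  ## exceeding 0.5% of peak above baseline noise
  base <- mag[seq_len(max(2L, length(mag) %/% 10L))]
  thr <- max(0.005 * pk, max(base) + 5 * stats::sd(base))
  loads$time[which(mag > thr)[1L]]
}

#' Synthesize an EMG-like signal from a known activation profile
#'
#' Band-limited (20-450 Hz) zero-mean Gaussian noise amplitude-modulated by
#' the activation trace; deterministic under the seed. The modulation is
#' linear, so envelope amplitudes scale with activation.
#'
#' @param activation activation trace in `[0, 1]` (vector, resampled to the
#'   output length).
#' @param duration signal duration (s).
#' @param rate sampling rate (Hz), at least 1000.
#' @param seed integer seed.
#' @param gain microvolt-scale amplitude of a fully active signal.
#' @return list of class `cd_synth_emg`: `time`, `raw`, `activation_true`,
#'   `rate`.
#' @export
synth_emg <- function(activation, duration, rate = 2000, seed = 1L,
                      gain = 1) {
  if (rate < 1000) {
    stop("EMG synthesis requires rate >= 1000 Hz", call. = FALSE)
  }
  if (any(activation < 0 | activation > 1)) {
    stop("activation must lie in [0, 1]", call. = FALSE)
  }
  t <- seq(0, duration, by = 1 / rate)
  n <- length(t)
  act <- stats::approx(seq(0, 1, length.out = length(activation)),
                       activation, xout = seq(0, 1, length.out = n))$y
  set.seed(seed)
  carrier <- bandpass_filter(stats::rnorm(n), rate, band = c(20, 450),
                             order = 2L, bidirectional = TRUE)
  carrier <- carrier / stats::sd(carrier)
  structure(list(time = t, raw = gain * act * carrier,
                 activation_true = act, rate = rate),
            class = "cd_synth_emg")
}

## ---------------------------------------------------------------------
## Toy model constructors (oracle fixtures)

#' Toy model constructors
#'
#' Small closed-form models used as oracles: a planar pendulum
#' (`toy_pendulum_model`), an n-link serial chain with seeded random
#' geometry (`random_chain_model`), and a toy neck: a stack of pin joints
#' with optional point-to-point muscles on both sides
#' (`toy_neck_model`).
#'
#' @param length,mass pendulum geometry (m, kg); the bob is a point mass at
#'   the distal end.
#' @param axis rotation axis of the pendulum pin.
#' @return a `cd_model`.
#' @export
toy_pendulum_model <- function(length = 1, mass = 1, axis = c(0, 0, 1)) {
  load_model_description(list(
    name = "pendulum", gravity = c(0, -9.81, 0),
    segments = list(list(name = "link", mass = mass,
                         com = c(0, -length, 0), inertia = c(0, 0, 0))),
    joints = list(list(name = "pin", parent = "ground", child = "link",
                       coordinates = list(list(name = "theta",
                                               axis = axis,
                                               range = c(-720, 720),
                                               default = 0))))))
}

#' @rdname toy_pendulum_model
#' @param n_links number of links.
#' @param seed seed for link lengths, axes, masses.
#' @param translational include a prismatic coordinate (last link).
#' @export
random_chain_model <- function(n_links = 4, seed = 1, translational = FALSE) {
  set.seed(seed)
  segs <- list(); joints <- list()
  parent <- "ground"
  for (i in seq_len(n_links)) {
    nm <- paste0("link", i)
    len <- stats::runif(1, 0.2, 0.8)
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    I12 <- stats::runif(2, 0.02, 0.05)
    I3 <- stats::runif(1, abs(diff(I12)) * 1.01 + 1e-4,
                       sum(I12) * 0.99)
    segs[[i]] <- list(name = nm, mass = stats::runif(1, 0.5, 3),
                      com = c(stats::runif(1, -0.1, 0.1), -len / 2,
                              stats::runif(1, -0.1, 0.1)),
                      inertia = c(I12, I3))
    kind <- if (translational && i == n_links) "translational" else
      "rotational"
    joints[[i]] <- list(
      name = paste0("j", i), parent = parent, child = nm,
      location_in_parent = if (i == 1) c(0, 0, 0) else
        c(0, -stats::runif(1, 0.2, 0.8), 0),
      orientation_in_parent = stats::runif(3, -20, 20),
      coordinates = list(list(name = paste0("q", i), kind = kind,
                              axis = ax,
                              range = if (kind == "rotational")
                                c(-720, 720) else c(-2, 2),
                              default = if (kind == "rotational")
                                stats::runif(1, -30, 30) else 0)))
    parent <- nm
  }
  load_model_description(list(name = paste0("chain", n_links),
                              gravity = c(0, -9.81, 0),
                              segments = segs, joints = joints))
}

#' @rdname toy_pendulum_model
#' @param n_joints number of stacked pin joints (flexion axis z).
#' @param with_muscles attach an anterior/posterior muscle pair spanning the
#'   whole stack.
#' @param f_max,l_opt muscle parameters for the attached pair.
#' @param segment_length,segment_mass per-vertebra geometry.
#' @export
toy_neck_model <- function(n_joints = 2, with_muscles = TRUE, f_max = 500,
                           l_opt = 0.1, segment_length = 0.05,
                           segment_mass = 0.5) {
  segs <- list(list(name = "base", mass = 10, com = c(0, -0.1, 0),
                    inertia = c(0.05, 0.05, 0.05)))
  joints <- list(list(name = "weld_base", parent = "ground", child = "base"))
  parent <- "base"
  for (i in seq_len(n_joints)) {
    nm <- paste0("vert", i)
    segs[[length(segs) + 1L]] <-
      list(name = nm, mass = segment_mass,
           com = c(0, segment_length / 2, 0),
           inertia = c(2e-4, 1e-4, 2e-4))
    joints[[length(joints) + 1L]] <- list(
      name = paste0("neck", i), parent = parent, child = nm,
      location_in_parent = if (i == 1) c(0, 0, 0) else
        c(0, segment_length, 0),
      coordinates = list(list(name = paste0("flex", i), axis = c(0, 0, 1),
                              range = c(-90, 90), default = 0)))
    parent <- nm
  }
  top <- parent
  muscles <- list()
  if (with_muscles) {
    ytop <- segment_length
    muscles <- list(
      list(name = "ant", group = "flexors", action = "flexor",
           path = list(list(segment = "base", point = c(0.04, 0, 0)),
                       list(segment = top, point = c(0.04, ytop, 0))),
           f_max = f_max, l_opt = l_opt,
           l_slack = 0.02, pennation = 0),
      list(name = "post", group = "extensors", action = "extensor",
           path = list(list(segment = "base", point = c(-0.04, 0, 0)),
                       list(segment = top, point = c(-0.04, ytop, 0))),
           f_max = f_max, l_opt = l_opt,
           l_slack = 0.02, pennation = 0))
  }
  load_model_description(list(name = "toyneck", gravity = c(0, -9.81, 0),
                              segments = segs, joints = joints,
                              muscles = muscles))
}
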