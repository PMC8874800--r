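#' Parameters of the synthetic subject
#'
#' Defaults emulate the calibration protocol of the target system: a
#' standing user, head tracker ~1.6 m high, hands held at the shoulders in
#' the baseline pose, out-and-back excursions with reach amplitudes of
#' 0.4-0.65 m completed in 0.7 s each way (mean one-way speed ~0.86 m/s for
#' a 0.6 m reach), ~1 s baseline dwells between repetitions, and an 89 Hz
#' sample rate. Two noise sources are modelled. Sensor jitter is i.i.d.
#' Gaussian per sample: 0.25 mm on positions (the sample-to-sample jitter
#' of the optical tracking, distinct from its mm-scale absolute accuracy),
#' 0.5 degrees on controller angles, and 0.02 degrees on the head-mounted
#' display's angles (IMU-fused attitude is far steadier than the hand
#' controllers; head attitude jitter also leaks into every head-relative
#' position through a ~0.5 m lever arm, so it matters). Physiological
#' tremor is modelled as movement-locked 7-11 Hz oscillation whose
#' amplitude follows the speed profile — signal-dependent motor noise,
#' absent at rest — with ~8 mm position and ~3 degree angle amplitude at
#' peak speed.
#'
#' @param sample_rate_hz sampling rate, Hz.
#' @param move_duration one-way excursion duration, s.
#' @param dwell_duration baseline dwell after each repetition, s.
#' @param lead_in initial dwell before the first movement, s.
#' @param pos_noise_sd position sensor jitter SD, m (all devices).
#' @param ang_noise_sd controller angle sensor jitter SD, rad.
#' @param hmd_ang_noise_sd head angle sensor jitter SD, rad.
#' @param tremor_pos_amp,tremor_ang_amp peak movement-locked tremor
#'   amplitude on controller positions (m) and angles (rad); 0 disables.
#' @param tremor_freq_range tremor frequency band, Hz.
#' @param hmd_position head position in the global frame, m.
#' @param baseline_right,baseline_left baseline controller positions, m.
#' @param amplitudes named list (per gesture class) of length-2 reach
#'   amplitudes \code{c(right, left)} in meters.
#' @return list of class \code{subject_params}.
#' @export
subject_params <- function(sample_rate_hz = 89,
                           move_duration = 0.7,
                           dwell_duration = 1.0,
                           lead_in = 1.0,
                           pos_noise_sd = 0.00025,
                           ang_noise_sd = 0.5 * pi / 180,
                           hmd_ang_noise_sd = 0.02 * pi / 180,
                           tremor_pos_amp = 0.008,
                           tremor_ang_amp = 0.05,
                           tremor_freq_range = c(7, 11),
                           hmd_position = c(0, 1.60, 0),
                           baseline_right = c(0.20, 1.35, 0.15),
                           baseline_left = c(-0.20, 1.35, 0.15),
                           amplitudes = list(
                             abduction_right = c(0.60, 0.40),
                             abduction_left = c(0.40, 0.60),
                             flexion_up = c(0.60, 0.60),
                             extension_down = c(0.65, 0.65),
                             push_forward = c(0.45, 0.45))) {
  stopifnot(sample_rate_hz > 0, move_duration > 0, dwell_duration > 0,
            pos_noise_sd >= 0, ang_noise_sd >= 0, hmd_ang_noise_sd >= 0,
            tremor_pos_amp >= 0, tremor_ang_amp >= 0,
            all(unlist(amplitudes) > 0))
  structure(as.list(environment()), class = "subject_params")
}

# Per-gesture kinematic programme: primary global reach direction, a
# secondary arc component per hand (reaches are not straight lines: lateral
# reaches drift forward, raising the hands arcs them forward, pushing
# converges the hands), Tait-Bryan excursion amplitudes (rad) for each
# hand, and the strongly driven orientation variables recorded as ground
# truth for saliency recovery. All excursions share one time profile, so a
# single coordinated direction carries the movement variance.
gesture_defs <- function() {
  list(
    abduction_right = list(
      dir = c(1, 0, 0),
      arc_right = c(0, 0, 0.12), arc_left = c(0, 0, 0.12),
      ang_right = c(gamma = 0.9, beta = 0.45, alpha = -0.8),
      ang_left = c(gamma = 0.7, beta = -0.45, alpha = -0.9),
      driving = c("gamma_H_R", "alpha_H_R", "gamma_H_L", "alpha_H_L")),
    abduction_left = list(
      dir = c(-1, 0, 0),
      arc_right = c(0, 0, 0.12), arc_left = c(0, 0, 0.12),
      ang_right = c(gamma = -0.7, beta = 0.45, alpha = 0.9),
      ang_left = c(gamma = -0.9, beta = -0.45, alpha = 0.8),
      driving = c("gamma_H_R", "alpha_H_R", "gamma_H_L", "alpha_H_L")),
    flexion_up = list(
      dir = c(0, 1, 0),
      arc_right = c(0, 0, 0.15), arc_left = c(0, 0, 0.15),
      ang_right = c(gamma = 0.8, beta = 0.6, alpha = 0.7),
      ang_left = c(gamma = 0.8, beta = -0.6, alpha = -0.7),
      driving = c("gamma_H_R", "beta_H_R", "alpha_H_R",
                  "gamma_H_L", "beta_H_L", "alpha_H_L")),
    extension_down = list(
      dir = c(0, -1, 0),
      arc_right = c(0, 0, -0.10), arc_left = c(0, 0, -0.10),
      ang_right = c(gamma = 0.35, beta = 0.30, alpha = 0.35),
      ang_left = c(gamma = 0.9, beta = 0.40, alpha = -0.9),
      driving = c("gamma_H_L", "alpha_H_L")),
    push_forward = list(
      dir = c(0, 0, 1),
      arc_right = c(-0.10, 0, 0), arc_left = c(0.10, 0, 0),
      ang_right = c(gamma = 0.35, beta = 0.35, alpha = 1.0),
      ang_left = c(gamma = -0.35, beta = -0.35, alpha = -1.0),
      driving = c("alpha_H_R", "alpha_H_L")))
}

#' Minimum-jerk position profile
#'
#' The quintic \eqn{s(\tau) = 10\tau^3 - 15\tau^4 + 6\tau^5} on
#' \eqn{\tau \in [0,1]}, the standard model of point-to-point reaching. Its
#' speed peaks at \eqn{1.875/T} of the amplitude per second, so the
#' mean/max speed ratio of one excursion is \eqn{1/1.875 \approx 0.533}.
#'
#' @param tau normalized time in [0, 1] (clamped).
#' @return normalized displacement in [0, 1].
#' @export
min_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# segmented reaching profile: k sequential minimum-jerk submovements, each
# active over a fraction of its time slot (micro-pauses in between), as seen
# in stiff or recovering movement
segmented_profile <- function(tau, k, active_frac = 0.8) {
  tau <- pmin(pmax(tau, 0), 1)
  slot <- pmin(floor(tau * k), k - 1)
  local <- (tau - slot / k) * k / active_frac
  (slot + min_jerk(local)) / k
}

# normalized minimum-jerk speed shape (peak 1 at tau = 0.5); doubles as
# the envelope of the movement-locked tremor
min_jerk_envelope <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / 1.875
}

# movement-locked tremor for one out-and-back repetition: independent
# random frequency and phase per channel, amplitude following the speed
# envelope so it vanishes at rest (signal-dependent motor noise)
tremor_block <- function(n_move, fs, params) {
  if (params$tremor_pos_amp == 0 && params$tremor_ang_amp == 0)
    return(matrix(0, 2 * n_move, 6))
  tau <- c(seq_len(n_move) / n_move, ((n_move - 1):0) / n_move)
  env <- min_jerk_envelope(tau)
  t_abs <- seq_len(2 * n_move) / fs
  amp <- rep(c(params$tremor_pos_amp, params$tremor_ang_amp), each = 3)
  vapply(1:6, function(ch) {
    f <- stats::runif(1, params$tremor_freq_range[1],
                      params$tremor_freq_range[2])
    phi <- stats::runif(1, 0, 2 * pi)
    amp[ch] * sin(2 * pi * f * t_abs + phi) * env
  }, numeric(2 * n_move))
}

# one gesture block: positions/angles/labels for reps repetitions
# (out, back, dwell each) plus ground-truth interval rows; caller supplies
# a seeded RNG context (tremor draws happen here)
build_gesture_block <- function(class, params, reps, offset,
                                impair = NULL) {
  def <- gesture_defs()[[class]]
  fs <- params$sample_rate_hz
  n_move <- round(params$move_duration * fs)
  n_dwell <- round(params$dwell_duration * fs)
  amp <- params$amplitudes[[class]]

  profile_for <- function(hand) {
    out_tau <- seq_len(n_move) / n_move
    back_tau <- ((n_move - 1):0) / n_move
    f <- min_jerk
    scale <- 1
    if (!is.null(impair) && impair$side == hand) {
      if (impair$submovements > 1)
        f <- function(tau) segmented_profile(tau, impair$submovements,
                                             impair$active_frac)
      scale <- impair$amplitude_factor
    }
    rep(c(f(out_tau), f(back_tau), numeric(n_dwell)), reps) * scale
  }
  prof_r <- profile_for("right")
  prof_l <- profile_for("left")
  n_block <- length(prof_r)

  pose <- function(prof, baseline, amp_hand, arc, ang) {
    drive <- def$dir * amp_hand + arc
    out <- cbind(baseline[1] + drive[1] * prof,
                 baseline[2] + drive[2] * prof,
                 baseline[3] + drive[3] * prof,
                 ang[1] * prof, ang[2] * prof, ang[3] * prof)
    for (r in seq_len(reps)) {
      move_rows <- (r - 1) * (2 * n_move + n_dwell) + seq_len(2 * n_move)
      out[move_rows, ] <- out[move_rows, ] + tremor_block(n_move, fs, params)
    }
    out
  }
  rep_len_steps <- 2 * n_move + n_dwell
  labels <- rep(c(rep(class, 2 * n_move), rep("no_movement", n_dwell)), reps)
  truth <- data.frame(
    class = class, repetition = seq_len(reps),
    out_start = offset + (seq_len(reps) - 1) * rep_len_steps + 1L,
    out_end = offset + (seq_len(reps) - 1) * rep_len_steps + n_move,
    ret_start = offset + (seq_len(reps) - 1) * rep_len_steps + n_move + 1L,
    ret_end = offset + (seq_len(reps) - 1) * rep_len_steps + 2L * n_move)
  list(right = pose(prof_r, params$baseline_right, amp[1], def$arc_right,
                    def$ang_right),
       left = pose(prof_l, params$baseline_left, amp[2], def$arc_left,
                   def$ang_left),
       labels = labels, truth = truth, n = n_block)
}

build_session <- function(classes, params, reps, seed, impair = NULL) {
  fs <- params$sample_rate_hz
  n_lead <- round(params$lead_in * fs)
  noisy <- NULL
  blocks <- list()
  with_seed(seed, {
    offset <- n_lead
    for (cl in classes) {
      b <- build_gesture_block(cl, params, reps, offset, impair)
      blocks[[cl]] <- b
      offset <- offset + b$n
    }
    n <- offset
    lead6 <- function(baseline) {
      m <- matrix(0, n_lead, 6)
      m[, 1:3] <- rep(baseline, each = n_lead)
      m
    }
    right <- rbind(lead6(params$baseline_right),
                   do.call(rbind, lapply(blocks, `[[`, "right")))
    left <- rbind(lead6(params$baseline_left),
                  do.call(rbind, lapply(blocks, `[[`, "left")))
    hmd <- lead6(params$hmd_position)[rep(1, n), , drop = FALSE]
    add_noise <- function(m, ang_sd) {
      m[, 1:3] <- m[, 1:3] + stats::rnorm(3 * n, sd = params$pos_noise_sd)
      m[, 4:6] <- m[, 4:6] + stats::rnorm(3 * n, sd = ang_sd)
      df <- as.data.frame(m)
      names(df) <- c("x", "y", "z", "gamma", "beta", "alpha")
      df
    }
    noisy <- list(hmd = add_noise(hmd, params$hmd_ang_noise_sd),
                  right = add_noise(right, params$ang_noise_sd),
                  left = add_noise(left, params$ang_noise_sd))
  })
  n <- n_lead + sum(vapply(blocks, `[[`, numeric(1), "n"))
  labels <- c(rep("no_movement", n_lead),
              unlist(lapply(blocks, `[[`, "labels"), use.names = FALSE))
  truth <- do.call(rbind, lapply(blocks, `[[`, "truth"))
  rownames(truth) <- NULL
  driving <- lapply(gesture_defs()[classes], `[[`, "driving")
  session <- vr_session(time = (seq_len(n) - 1) / fs,
                        hmd = noisy$hmd, right = noisy$right,
                        left = noisy$left, labels = labels,
                        sample_rate_hz = fs, convention = "zxy",
                        metadata = list(seed = seed, generator = "vrmotion"))
  list(session = session,
       truth = list(repetitions = truth, driving_variables = driving,
                    classes = classes))
}

#' Generate repetitions of one calibration gesture
#'
#' Minimum-jerk out-and-back reach in the gesture's direction for both
#' controllers, with coupled Tait-Bryan excursions (the forearm rolls and
#' the controller yaws during a lateral reach) so that, as on real
#' recordings, controller orientation variables carry coordinated variance
#' during movement. The head is static up to sensor jitter. Per-step
#' ground-truth labels mark excursion and return steps with the gesture
#' class and dwell steps as \code{"no_movement"}.
#'
#' @param class one of [movement_classes()].
#' @param params a [subject_params()].
#' @param reps number of repetitions.
#' @param seed integer seed; sessions are deterministic given a seed.
#' @return list with \code{session} (a [vr_session()]) and \code{truth}
#'   (repetition boundaries as 1-based inclusive sample indices, and the
#'   programmed driving orientation variables).
#' @export
generate_gesture <- function(class, params = subject_params(), reps = 1,
                             seed = 1) {
  if (!class %in% movement_classes())
    stop("unknown movement class: ", class, call. = FALSE)
  build_session(class, params, reps, seed)
}

#' Generate a full synthetic calibration session
#'
#' The five bimanual gestures in protocol order (abduction right, abduction
#' left, flexion up, extension down, push forward), \code{reps} repetitions
#' each with a return to baseline after every excursion, preceded by a short
#' baseline dwell. With \code{reps = 5} this produces 50 movement
#' excursions forming 25 repetition units.
#'
#' @inheritParams generate_gesture
#' @return as [generate_gesture()].
#' @export
generate_calibration_session <- function(params = subject_params(),
                                         reps = 5, seed = 1) {
  stopifnot(reps >= 1)
  build_session(movement_classes(), params, reps, seed)
}

#' Generate a session with an impaired arm
#'
#' One arm's reaches are scaled down in amplitude (hence in speed, on the
#' shared timeline) and optionally segmented into several minimum-jerk
#' submovements separated by micro-pauses, the multi-peaked speed profile
#' typical of stiff or recovering movement. Used to exercise the
#' sensitivity of the motor-performance metrics; no clinical claim is made.
#'
#' @inheritParams generate_calibration_session
#' @param side \code{"left"} or \code{"right"}: the affected arm.
#' @param amplitude_factor reach-amplitude scale for the affected arm,
#'   in (0, 1].
#' @param submovements number of submovements per excursion (1 = smooth).
#' @param active_frac fraction of each submovement slot spent moving.
#' @return as [generate_gesture()].
#' @export
generate_impaired_session <- function(params = subject_params(), reps = 5,
                                      seed = 1, side = "left",
                                      amplitude_factor = 0.5,
                                      submovements = 3,
                                      active_frac = 0.8) {
  stopifnot(side %in% c("left", "right"),
            amplitude_factor > 0, amplitude_factor <= 1,
            submovements >= 1, active_frac > 0, active_frac <= 1)
  build_session(movement_classes(), params, reps, seed,
                impair = list(side = side,
                              amplitude_factor = amplitude_factor,
                              submovements = submovements,
                              active_frac = active_frac))
}
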