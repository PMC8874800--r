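#' Combined-controller speed statistic
#'
#' Per-time-step scalar speed derived from both controllers' positional
#' finite differences, used to detect movement against stillness. The
#' default combination is the mean of the two controllers' instantaneous
#' speeds \eqn{\|\Delta P\|/dt}; for symmetric bimanual gestures mean and
#' max are nearly equivalent, and the mean is more robust to one-sided
#' jitter. A midpoint-speed rule (speed of the midway point) is also
#' offered.
#'
#' @param right_positions,left_positions N x 3 matrices of controller
#'   positions (meters, any common frame).
#' @param dt sampling interval in seconds.
#' @param rule combination rule: \code{"mean"}, \code{"max"} or
#'   \code{"midpoint"}.
#' @return numeric vector of length N-1, in m/s.
#' @export
omega_series <- function(right_positions, left_positions, dt,
                         rule = c("mean", "max", "midpoint")) {
  rule <- match.arg(rule)
  if (nrow(right_positions) != nrow(left_positions))
    stop("controller series have different lengths", call. = FALSE)
  speed <- function(p) {
    d <- finite_difference_series(p, dt)
    sqrt(rowSums(d^2))
  }
  switch(rule,
         mean = (speed(right_positions) + speed(left_positions)) / 2,
         max = pmax(speed(right_positions), speed(left_positions)),
         midpoint = speed((right_positions + left_positions) / 2))
}

#' Detect movement intervals from the speed statistic
#'
#' A movement interval is a maximal run of consecutive samples whose speed
#' statistic exceeds \code{speed_threshold} and whose duration strictly
#' exceeds \code{min_duration} (runs need at least
#' \code{ceiling(min_duration/dt) + 1} samples); shorter excursions are
#' discarded as jitter. The study's empirically derived defaults are
#' 0.077 m/s and 0.2 s; both are per-user settings in practice. Surviving
#' intervals are assigned alternating roles, outward excursion first, then
#' the return to baseline.
#'
#' @param omega speed series from [omega_series()].
#' @param speed_threshold movement threshold in m/s.
#' @param min_duration minimal duration in seconds (strict).
#' @param dt sampling interval in seconds.
#' @return data frame with columns \code{start}, \code{end} (0-based,
#'   half-open indices into the omega series), \code{role}
#'   (\code{"outward"}/\code{"return"}); zero rows when nothing moves.
#' @export
detect_intervals <- function(omega, speed_threshold = 0.077,
                             min_duration = 0.2, dt = 1 / 89) {
  stopifnot(speed_threshold > 0, min_duration > 0, dt > 0)
  above <- omega > speed_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_samples <- as.integer(ceiling(min_duration / dt)) + 1L
  keep <- r$values & r$lengths >= min_samples
  out <- data.frame(start = starts[keep] - 1L, end = ends[keep])
  out$role <- rep_len(c("outward", "return"), nrow(out))
  out
}

#' Default movement classes, in calibration protocol order
#'
#' The calibration protocol prescribes, in order: horizontal shoulder
#' abduction to the right, the same to the left, shoulder flexion raising
#' both hands, elbow extension lowering both hands, and a simultaneous
#' shoulder flexion + elbow extension pushing both hands forward.
#'
#' @return character vector of the five gesture class names.
#' @export
movement_classes <- function() {
  c("abduction_right", "abduction_left", "flexion_up",
    "extension_down", "push_forward")
}

#' Pair movement intervals into repetition segments
#'
#' Consecutive interval pairs (outward excursion + return) together with the
#' time steps enclosed between them form one repetition segment. For a clean
#' calibration of 5 gestures x \code{reps} repetitions this yields
#' \code{5 * reps} segments (25 in the study protocol), labelled from the
#' known protocol order. A dangling unpaired final interval is dropped with
#' a warning.
#'
#' @param intervals data frame from [detect_intervals()].
#' @param protocol character vector of gesture classes in performance order.
#' @param reps repetitions per gesture used for labelling; when the segment
#'   count does not equal \code{length(protocol) * reps}, labels are left
#'   \code{NA} with a warning.
#' @return data frame with columns \code{start}, \code{end} (0-based
#'   half-open span covering both intervals and the enclosed dwell),
#'   \code{out_start}, \code{out_end}, \code{ret_start}, \code{ret_end},
#'   \code{class}, \code{repetition}.
#' @export
build_segments <- function(intervals, protocol = movement_classes(),
                           reps = 5) {
  n_int <- nrow(intervals)
  if (n_int %% 2 == 1) {
    warning("odd number of intervals; dropping the dangling final interval",
            call. = FALSE)
    intervals <- intervals[-n_int, , drop = FALSE]
    n_int <- n_int - 1L
  }
  n_seg <- n_int %/% 2
  if (n_seg == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      out_start = integer(0), out_end = integer(0),
                      ret_start = integer(0), ret_end = integer(0),
                      class = character(0), repetition = integer(0)))
  first <- intervals[seq(1, n_int, by = 2), ]
  second <- intervals[seq(2, n_int, by = 2), ]
  seg <- data.frame(start = first$start, end = second$end,
                    out_start = first$start, out_end = first$end,
                    ret_start = second$start, ret_end = second$end)
  if (n_seg == length(protocol) * reps) {
    seg$class <- rep(protocol, each = reps)
    seg$repetition <- rep(seq_len(reps), times = length(protocol))
  } else {
    warning("segment count (", n_seg, ") does not match protocol (",
            length(protocol) * reps, "); labels left NA", call. = FALSE)
    seg$class <- NA_character_
    seg$repetition <- NA_integer_
  }
  seg
}

#' Write segments to CSV
#'
#' @param segments data frame from [build_segments()].
#' @param path CSV file path.
#' @export
write_segments <- function(segments, path) {
  utils::write.csv(segments, path, row.names = FALSE)
  invisible(path)
}
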