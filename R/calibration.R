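#' Average range-of-motion excursion over calibration repetitions
#'
#' During calibration the user repeats each gesture (5 times in the study
#' protocol) and the software averages, per axis, the maximal absolute
#' displacement of the controller midpoint from the instantaneous head
#' position: \eqn{\bar D = \frac{1}{n}\sum_n \max_t |P^G_h(t) - P^G_H(t)|}.
#'
#' @param repetitions list of integer index vectors (or two-column
#'   start/end matrices interpreted as half-open ranges), one time slice per
#'   repetition.
#' @param midpoint_series N x 3 matrix of controller-midpoint positions.
#' @param hmd_series N x 3 matrix of head positions on the same time base.
#' @return named numeric vector \code{c(x, y, z)}: per-axis average maximal
#'   excursion in meters.
#' @export
average_excursion <- function(repetitions, midpoint_series, hmd_series) {
  stopifnot(length(repetitions) >= 1,
            nrow(midpoint_series) == nrow(hmd_series))
  disp <- abs(midpoint_series - hmd_series)
  per_rep <- vapply(repetitions, function(idx) {
    if (is.matrix(idx)) idx <- seq.int(idx[1], idx[2] - 1L)
    if (length(idx) == 0) stop("empty repetition slice", call. = FALSE)
    apply(disp[idx, , drop = FALSE], 2, max)
  }, numeric(3))
  d_bar <- rowMeans(per_rep)
  names(d_bar) <- c("x", "y", "z")
  d_bar
}

#' Build a per-user calibration profile
#'
#' Cursor thresholds are placed at a fraction (25% in the study) of the
#' user's average excursion along each axis, so users with a smaller range
#' of motion drive the cursor with proportionally smaller movements. An axis
#' whose average excursion is zero is disabled (its threshold is \code{NA})
#' with a warning.
#'
#' @param d_bar per-axis average excursion from [average_excursion()].
#' @param fraction threshold fraction in (0, 1], default 0.25.
#' @return object of class \code{calibration_profile} with elements
#'   \code{d_bar}, \code{fraction}, \code{thresholds}.
#' @export
make_profile <- function(d_bar, fraction = 0.25) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be a scalar in (0, 1]", call. = FALSE)
  stopifnot(length(d_bar) == 3, all(d_bar >= 0))
  d_bar <- stats::setNames(as.numeric(d_bar), c("x", "y", "z"))
  thr <- fraction * d_bar
  dead <- thr == 0
  if (any(dead)) {
    warning("zero excursion on axis ", paste(names(thr)[dead], collapse = ", "),
            "; axis disabled", call. = FALSE)
    thr[dead] <- NA_real_
  }
  structure(list(d_bar = d_bar, fraction = fraction, thresholds = thr),
            class = "calibration_profile")
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat("<calibration_profile> fraction =", x$fraction, "\n")
  print(rbind(d_bar = x$d_bar, threshold = x$thresholds))
  invisible(x)
}

# screen direction for the positive / negative side of each axis;
# pushing forward (+z) selects, there is no backward command
cursor_direction_map <- function() {
  list(x = c(pos = "left", neg = "right"),
       y = c(pos = "up", neg = "down"),
       z = c(pos = "forward", neg = NA_character_))
}

#' Cursor command from a midpoint displacement
#'
#' Emits the screen directions whose per-axis signed displacement of the
#' controller midpoint (relative to the instantaneous head position) exceeds
#' the calibrated threshold. Several axes may be active at once (diagonal
#' motion); opposite directions on one axis are mutually exclusive by
#' construction. There is no time constraint on activation.
#'
#' @param midpoint_rel_hmd length-3 displacement vector (meters).
#' @param profile a [make_profile()] result.
#' @return list with \code{directions} (character subset of left, right, up,
#'   down, forward) and \code{exceedance} (per-axis displacement magnitude
#'   beyond the threshold, 0 when inactive).
#' @export
cursor_command <- function(midpoint_rel_hmd, profile) {
  stopifnot(inherits(profile, "calibration_profile"),
            length(midpoint_rel_hmd) == 3)
  d <- as.numeric(midpoint_rel_hmd)
  thr <- profile$thresholds
  map <- cursor_direction_map()
  dirs <- character(0)
  exceed <- stats::setNames(numeric(3), c("x", "y", "z"))
  for (i in 1:3) {
    if (is.na(thr[i])) next
    if (abs(d[i]) > thr[i]) {
      dir <- map[[i]][if (d[i] > 0) "pos" else "neg"]
      if (!is.na(dir)) {
        dirs <- c(dirs, unname(dir))
        exceed[i] <- abs(d[i]) - thr[i]
      }
    }
  }
  list(directions = dirs, exceedance = exceed)
}

#' Persist a calibration profile as JSON
#'
#' @param profile a \code{calibration_profile}.
#' @param path JSON file path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "calibration_profile"))
  jsonlite::write_json(list(d_bar = profile$d_bar,
                            fraction = profile$fraction,
                            thresholds = profile$thresholds),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  prof <- make_profile(unlist(x$d_bar), x$fraction)
  prof
}
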