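#' Range of motion along an anatomical axis
#'
#' Maximum absolute displacement of a controller over a movement, along one
#' of the head-frame axes (x = mediolateral, y = vertical,
#' z = anteroposterior) or as the 3-D Euclidean distance
#' (\code{axis = "all"}). By default displacement is measured from the first
#' sample of the series, so an out-and-back excursion of amplitude A yields
#' A; with \code{reference = "origin"} the raw coordinate magnitude (the
#' distance from the headset when the series is head-relative) is used
#' instead.
#'
#' @param positions N x 3 matrix of positions (meters), typically the
#'   controller relative to the head frame.
#' @param axis \code{"x"}, \code{"y"}, \code{"z"} or \code{"all"}.
#' @param reference \code{"start"} (displacement from the first sample) or
#'   \code{"origin"} (raw coordinates).
#' @return range of motion in meters.
#' @export
range_of_motion <- function(positions, axis = c("all", "x", "y", "z"),
                            reference = c("start", "origin")) {
  axis <- match.arg(axis)
  reference <- match.arg(reference)
  p <- as.matrix(positions)
  if (nrow(p) < 1) stop("empty position series", call. = FALSE)
  if (reference == "start")
    p <- sweep(p, 2, p[1, ])
  if (axis == "all") max(sqrt(rowSums(p^2)))
  else max(abs(p[, match(axis, c("x", "y", "z"))]))
}

instantaneous_speeds <- function(positions, dt) {
  d <- finite_difference_series(as.matrix(positions), dt)
  sqrt(rowSums(d^2))
}

#' Mean movement speed
#'
#' Arithmetic mean of the instantaneous speeds \eqn{\|\Delta P\|/dt}.
#'
#' @param positions N x 3 position matrix (N >= 2).
#' @param dt sampling interval in seconds.
#' @return mean speed in m/s.
#' @export
mean_speed <- function(positions, dt) {
  mean(instantaneous_speeds(positions, dt))
}

#' Movement smoothness
#'
#' Ratio of the mean to the maximal instantaneous speed, a dimensionless
#' number in (0, 1]; 1 means perfectly constant speed, small values indicate
#' spiky, segmented motion. Some of the rehabilitation literature reports
#' the reciprocal (max/mean >= 1); set \code{reciprocal = TRUE} for that
#' scale. A motionless series has no defined smoothness and returns
#' \code{NA} with a warning.
#'
#' @inheritParams mean_speed
#' @param reciprocal report max/mean instead of mean/max.
#' @return dimensionless smoothness score.
#' @export
smoothness <- function(positions, dt, reciprocal = FALSE) {
  v <- instantaneous_speeds(positions, dt)
  vmax <- max(v)
  if (vmax == 0) {
    warning("no motion in series; smoothness undefined", call. = FALSE)
    return(NA_real_)
  }
  if (reciprocal) vmax / mean(v) else mean(v) / vmax
}

#' Path length
#'
#' Sum of Euclidean distances between consecutive samples.
#'
#' @param positions N x 3 position matrix (N >= 2).
#' @return total path length in meters.
#' @export
path_length <- function(positions) {
  p <- as.matrix(positions)
  if (nrow(p) < 2) stop("need at least two samples", call. = FALSE)
  sum(sqrt(rowSums(diff(p)^2)))
}

# metrics for one hand over one segment, pooled over the two movement
# intervals (the enclosed dwell is excluded: the metrics describe movement)
segment_hand_metrics <- function(rel_positions, segment, dt, axis,
                                 reciprocal = FALSE) {
  slices <- list(seq.int(segment$out_start + 1L, segment$out_end),
                 seq.int(segment$ret_start + 1L, segment$ret_end))
  speeds <- unlist(lapply(slices, function(ix)
    instantaneous_speeds(rel_positions[ix, , drop = FALSE], dt)))
  rom <- max(vapply(slices, function(ix)
    range_of_motion(rel_positions[ix, , drop = FALSE], axis), numeric(1)))
  pl <- sum(vapply(slices, function(ix)
    path_length(rel_positions[ix, , drop = FALSE]), numeric(1)))
  sm <- if (max(speeds) == 0) NA_real_
        else if (reciprocal) max(speeds) / mean(speeds)
        else mean(speeds) / max(speeds)
  data.frame(range_of_motion = rom, mean_speed = mean(speeds),
             smoothness = sm, path_length = pl)
}

#' Per-movement motor-performance summary
#'
#' Computes range of motion, mean speed, smoothness and path length for each
#' hand over each labelled repetition segment, then summarises mean and SD
#' across repetitions per movement class and hand (the layout of a clinical
#' motor-performance table). Metrics are computed on the two movement
#' intervals of a segment only, on the controller positions relative to the
#' head frame.
#'
#' @param table a variable table from [assemble_variable_table()].
#' @param segments labelled segments from [build_segments()].
#' @param axis axis for range of motion (default \code{"all"}: 3-D
#'   displacement magnitude).
#' @param reciprocal report smoothness as max/mean instead of mean/max.
#' @return list with \code{per_segment} (one row per segment x hand) and
#'   \code{summary} (mean and SD per class x hand; SD is 0 for a single
#'   repetition).
#' @export
summarize_metrics <- function(table, segments, axis = "all",
                              reciprocal = FALSE) {
  if (any(is.na(segments$class)))
    stop("segments must be labelled", call. = FALSE)
  dt <- attr(table, "dt")
  if (is.null(dt)) stop("variable table lacks its dt attribute", call. = FALSE)
  rel <- list(right = as.matrix(table[c("X_H_R", "Y_H_R", "Z_H_R")]),
              left = as.matrix(table[c("X_H_L", "Y_H_L", "Z_H_L")]))
  rows <- do.call(rbind, lapply(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    do.call(rbind, lapply(names(rel), function(hand) {
      m <- segment_hand_metrics(rel[[hand]], seg, dt, axis, reciprocal)
      cbind(data.frame(class = seg$class, repetition = seg$repetition,
                       hand = hand), m)
    }))
  }))
  metric_cols <- c("range_of_motion", "mean_speed", "smoothness",
                   "path_length")
  agg <- function(f) stats::aggregate(rows[metric_cols],
                                      by = rows[c("class", "hand")], FUN = f)
  mu <- agg(function(v) mean(v, na.rm = TRUE))
  sdv <- agg(function(v) if (sum(!is.na(v)) < 2) 0 else stats::sd(v, na.rm = TRUE))
  names(mu)[-(1:2)] <- paste0(metric_cols, "_mean")
  names(sdv)[-(1:2)] <- paste0(metric_cols, "_sd")
  list(per_segment = rows, summary = merge(mu, sdv, by = c("class", "hand")))
}
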