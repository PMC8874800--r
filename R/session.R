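#' Assemble a tracked VR session
#'
#' A session bundles the synchronous 6-DoF pose streams of the three tracked
#' devices (head-mounted display and the right and left hand controllers),
#' sampled at a common rate (89 Hz on the target hardware). Each track is a
#' data frame with columns \code{x, y, z} (meters, global frame) and
#' \code{gamma, beta, alpha} (Tait-Bryan angles, radians).
#'
#' @param time numeric vector of timestamps in seconds, strictly increasing.
#' @param hmd,right,left data frames with columns
#'   \code{x, y, z, gamma, beta, alpha}, one row per time step.
#' @param labels optional character vector of per-step true movement classes
#'   (one of the five calibration gestures or \code{"no_movement"}).
#' @param sample_rate_hz nominal sampling rate, Hz.
#' @param convention Tait-Bryan rotation order used by the angle columns.
#' @param metadata optional named list (participant id, seed, ...).
#' @return an object of class \code{vr_session}.
#' @export
vr_session <- function(time, hmd, right, left, labels = NULL,
                       sample_rate_hz = 89,
                       convention = c("zxy", "xyz", "zyx"),
                       metadata = list()) {
  convention <- match.arg(convention)
  n <- length(time)
  if (n < 2) stop("a session needs at least two time steps", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  cols <- c("x", "y", "z", "gamma", "beta", "alpha")
  for (nm in c("hmd", "right", "left")) {
    tr <- get(nm, inherits = FALSE)
    if (!is.data.frame(tr) || !all(cols %in% names(tr)))
      stop("track '", nm, "' must have columns ",
           paste(cols, collapse = ", "), call. = FALSE)
    if (nrow(tr) != n)
      stop("track '", nm, "' length differs from the time base", call. = FALSE)
    if (!all(vapply(tr[cols], function(v) all(is.finite(v)), logical(1))))
      stop("track '", nm, "' contains non-finite values", call. = FALSE)
  }
  if (!is.null(labels) && length(labels) != n)
    stop("labels must have one entry per time step", call. = FALSE)
  structure(list(time = as.numeric(time),
                 hmd = hmd[cols], right = right[cols], left = left[cols],
                 labels = if (!is.null(labels)) as.character(labels),
                 sample_rate_hz = sample_rate_hz,
                 convention = convention,
                 metadata = metadata),
            class = "vr_session")
}

#' @export
print.vr_session <- function(x, ...) {
  cat("<vr_session> ", length(x$time), " steps @ ", x$sample_rate_hz,
      " Hz (", sprintf("%.1f", diff(range(x$time))), " s), convention ",
      x$convention, if (!is.null(x$labels)) ", labelled" else "", "\n", sep = "")
  invisible(x)
}

#' Duration of a step count at a sampling rate
#'
#' Converts a number of time steps to seconds, e.g. 13 steps at 89 Hz is
#' 0.15 s (the default classification window) and a full calibration corpus
#' of 142,916 steps spans 1605.80 s.
#'
#' @param n_steps number of samples.
#' @param sample_rate_hz sampling rate in Hz.
#' @return duration in seconds.
#' @export
steps_to_seconds <- function(n_steps, sample_rate_hz = 89) {
  stopifnot(sample_rate_hz > 0)
  n_steps / sample_rate_hz
}

session_device_cols <- function() {
  cols <- c("x", "y", "z", "gamma", "beta", "alpha")
  c("t",
    paste0("hmd_", cols), paste0("right_", cols), paste0("left_", cols))
}

#' Read / write a session as delimited text
#'
#' One row per time step; columns \code{t}, then
#' \code{hmd_x ... hmd_alpha}, \code{right_x ... right_alpha},
#' \code{left_x ... left_alpha}, and optionally \code{label}. Unknown extra
#' columns are ignored with a warning; missing required columns are an error.
#'
#' @param path CSV file path.
#' @param session a \code{vr_session}.
#' @param ... passed to [vr_session()] (e.g. \code{sample_rate_hz},
#'   \code{convention}).
#' @return \code{read_session()} returns a \code{vr_session};
#'   \code{write_session()} returns \code{path} invisibly.
#' @export
read_session <- function(path, ...) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- session_device_cols()
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("session file is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), c(need, "label"))
  if (length(extra))
    warning("ignoring unknown columns: ", paste(extra, collapse = ", "),
            call. = FALSE)
  grab <- function(dev) {
    out <- df[paste0(dev, "_", c("x", "y", "z", "gamma", "beta", "alpha"))]
    names(out) <- c("x", "y", "z", "gamma", "beta", "alpha")
    out
  }
  vr_session(df$t, grab("hmd"), grab("right"), grab("left"),
             labels = if ("label" %in% names(df)) df$label, ...)
}

#' @rdname read_session
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "vr_session"))
  flat <- data.frame(t = session$time)
  for (dev in c("hmd", "right", "left")) {
    tr <- session[[dev]]
    names(tr) <- paste0(dev, "_", names(tr))
    flat <- cbind(flat, tr)
  }
  if (!is.null(session$labels)) flat$label <- session$labels
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}
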