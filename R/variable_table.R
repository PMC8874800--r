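#' Canonical names of the 30 kinematic variables
#'
#' The per-time-step analysis substrate holds, in this order: the head-mounted
#' display's linear and angular velocity in the global frame \{G\}; then, for
#' each controller (right, left), its position and orientation relative to the
#' head frame \{H\} and its linear and angular velocity in \{G\}. Velocity
#' columns carry a \code{dot} suffix on the coordinate name; angular velocity
#' is the finite-difference rate of each unwrapped Tait-Bryan angle.
#'
#' @return character vector of length 30.
#' @export
variable_names <- function() {
  vel <- function(frame, dev)
    paste0(c("Xdot_", "Ydot_", "Zdot_", "gammadot_", "betadot_", "alphadot_"),
           frame, "_", dev)
  rel <- function(dev)
    paste0(c("X_H_", "Y_H_", "Z_H_", "gamma_H_", "beta_H_", "alpha_H_"), dev)
  c(vel("G", "H"),
    rel("R"), vel("G", "R"),
    rel("L"), vel("G", "L"))
}

#' Finite-difference velocity of a sampled series
#'
#' @param series numeric vector or matrix (one column per coordinate).
#' @param dt sampling interval in seconds.
#' @param scheme \code{"forward"} (default): \eqn{(x_{i+1}-x_i)/dt}, length
#'   N-1, attributed to the left node; \code{"central"}:
#'   \eqn{(x_{i+1}-x_{i-1})/(2 dt)}, length N-2.
#' @return numeric vector/matrix of per-step rates.
#' @export
finite_difference_series <- function(series, dt,
                                     scheme = c("forward", "central")) {
  scheme <- match.arg(scheme)
  stopifnot(dt > 0)
  x <- if (is.matrix(series)) series else matrix(series, ncol = 1)
  n <- nrow(x)
  if (n < if (scheme == "forward") 2 else 3)
    stop("series too short for the ", scheme, " difference", call. = FALSE)
  v <- if (scheme == "forward") {
    (x[-1, , drop = FALSE] - x[-n, , drop = FALSE]) / dt
  } else {
    (x[-(1:2), , drop = FALSE] - x[-((n - 1):n), , drop = FALSE]) / (2 * dt)
  }
  if (is.matrix(series)) v else drop(v)
}

# rows lost at the end (forward) or both ends (central) of the table
stencil_rows <- function(n, scheme) {
  if (scheme == "forward") list(keep = seq_len(n - 1), n_out = n - 1L)
  else list(keep = 2:(n - 1), n_out = n - 2L)
}

track_matrix <- function(tr) {
  cbind(as.matrix(tr[c("x", "y", "z")]),
        as.matrix(tr[c("gamma", "beta", "alpha")]))
}

# Relative pose of one controller with respect to the head, vectorised over
# all time steps. Returns list(pos = N x 3, ang = N x 3 unwrapped).
relative_pose_series <- function(hmd, ctrl, convention) {
  eh <- rot_elements(hmd$gamma, hmd$beta, hmd$alpha, convention)
  ec <- rot_elements(ctrl$gamma, ctrl$beta, ctrl$alpha, convention)
  dx <- ctrl$x - hmd$x
  dy <- ctrl$y - hmd$y
  dz <- ctrl$z - hmd$z
  # columns of eh are (r11,r21,r31, r12,r22,r32, r13,r23,r33)
  # t(R_H) %*% d : component i = sum_k H[k,i] * d_k
  pos <- cbind(eh[, 1] * dx + eh[, 2] * dy + eh[, 3] * dz,
               eh[, 4] * dx + eh[, 5] * dy + eh[, 6] * dz,
               eh[, 7] * dx + eh[, 8] * dy + eh[, 9] * dz)
  # R_rel = t(R_H) %*% R_C, element (i,j) = sum_k H[k,i] C[k,j]
  rel <- matrix(NA_real_, nrow(eh), 9)
  for (j in 0:2) for (i in 0:2) {
    rel[, 3 * j + i + 1] <-
      eh[, 3 * i + 1] * ec[, 3 * j + 1] +
      eh[, 3 * i + 2] * ec[, 3 * j + 2] +
      eh[, 3 * i + 3] * ec[, 3 * j + 3]
  }
  ang <- angles_from_elements(rel, convention)
  list(pos = pos, ang = apply(ang, 2, signal::unwrap))
}

#' Assemble the 30-variable kinematic table
#'
#' Converts a session's raw device streams into the 30 named per-time-step
#' variables used throughout the analysis: head linear/angular velocity in
#' the global frame, controller positions and orientations relative to the
#' head frame \{H\} (via the inverse homogeneous transform), and controller
#' linear/angular velocities in \{G\}. Angle series are unwrapped before
#' differencing so angular-velocity columns contain no wrap-around spikes.
#' The velocity stencil costs one row (forward) or two (central); per-step
#' labels, when present, are truncated to match and returned as an attribute.
#'
#' @param session a [vr_session()].
#' @param scheme finite-difference scheme, see [finite_difference_series()].
#' @return a data frame with the 30 columns of [variable_names()], plus
#'   attributes \code{labels} (truncated per-row classes, if the session is
#'   labelled), \code{time}, \code{dt} and \code{scheme}.
#' @export
assemble_variable_table <- function(session, scheme = c("forward", "central")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(session, "vr_session"))
  n <- length(session$time)
  dt <- 1 / session$sample_rate_hz
  keep <- stencil_rows(n, scheme)$keep

  vel6 <- function(tr) {
    ang <- apply(as.matrix(tr[c("gamma", "beta", "alpha")]), 2, signal::unwrap)
    finite_difference_series(cbind(as.matrix(tr[c("x", "y", "z")]), ang),
                             dt, scheme)
  }
  rel_r <- relative_pose_series(session$hmd, session$right, session$convention)
  rel_l <- relative_pose_series(session$hmd, session$left, session$convention)

  tab <- cbind(vel6(session$hmd),
               rel_r$pos[keep, ], rel_r$ang[keep, ], vel6(session$right),
               rel_l$pos[keep, ], rel_l$ang[keep, ], vel6(session$left))
  tab <- as.data.frame(tab)
  names(tab) <- variable_names()
  attr(tab, "labels") <- if (!is.null(session$labels)) session$labels[keep]
  attr(tab, "time") <- session$time[keep]
  attr(tab, "dt") <- dt
  attr(tab, "scheme") <- scheme
  tab
}

#' Read / write a variable table as CSV
#'
#' @param table a variable table from [assemble_variable_table()].
#' @param path CSV file path.
#' @return \code{read_variable_table()} returns the table (with a
#'   \code{labels} attribute when a \code{label} column is present).
#' @export
write_variable_table <- function(table, path) {
  out <- table
  if (!is.null(attr(table, "labels"))) out$label <- attr(table, "labels")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variable_table
#' @export
read_variable_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(variable_names(), names(df))
  if (length(missing))
    stop("variable table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab <- df[variable_names()]
  if ("label" %in% names(df)) attr(tab, "labels") <- df$label
  tab
}
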