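#' Rotation matrix from Tait-Bryan angles
#'
#' Composes the three elemental rotations about the X- (\code{gamma}),
#' Y- (\code{beta}) and Z-axis (\code{alpha}) in an intrinsic order. The
#' default \code{"zxy"} order matches the convention of the Unity/Oculus
#' runtime that logs the pose streams this package consumes; the downstream
#' saliency results depend on this choice, so it is configurable everywhere
#' a conversion happens.
#'
#' @param gamma rotation about the X-axis, radians.
#' @param beta rotation about the Y-axis, radians.
#' @param alpha rotation about the Z-axis, radians.
#' @param convention intrinsic rotation order, one of \code{"zxy"},
#'   \code{"xyz"}, \code{"zyx"}.
#' @param degrees logical; interpret the angles as degrees.
#' @return a 3x3 orthonormal rotation matrix with determinant +1, whose
#'   columns are the child-frame basis vectors expressed in the parent frame.
#' @seealso [tait_bryan_from_rotation()] for the inverse conversion.
#' @export
#' @examples
#' rotation_from_tait_bryan(0, 0, pi / 2)
rotation_from_tait_bryan <- function(gamma, beta, alpha,
                                     convention = c("zxy", "xyz", "zyx"),
                                     degrees = FALSE) {
  convention <- match.arg(convention)
  stopifnot(is.finite(gamma), is.finite(beta), is.finite(alpha))
  if (degrees) {
    gamma <- gamma * pi / 180
    beta <- beta * pi / 180
    alpha <- alpha * pi / 180
  }
  el <- rot_elements(gamma, beta, alpha, convention)
  matrix(el[1, ], 3, 3)
}

# Vectorised rotation-matrix elements for N angle triples.
# Returns an N x 9 matrix in column-major element order
# (r11, r21, r31, r12, r22, r32, r13, r23, r33).
rot_elements <- function(gamma, beta, alpha, convention = "zxy") {
  cg <- cos(gamma); sg <- sin(gamma)
  cb <- cos(beta);  sb <- sin(beta)
  ca <- cos(alpha); sa <- sin(alpha)
  if (convention == "zxy") {
    # R = Rz(alpha) %*% Rx(gamma) %*% Ry(beta)
    cbind(ca * cb - sa * sg * sb,  sa * cb + ca * sg * sb, -cg * sb,
          -sa * cg,                ca * cg,                 sg,
          ca * sb + sa * sg * cb,  sa * sb - ca * sg * cb,  cg * cb,
          deparse.level = 0)
  } else if (convention == "xyz") {
    # R = Rx(gamma) %*% Ry(beta) %*% Rz(alpha)
    cbind(cb * ca,                      cg * sa + sg * sb * ca,  sg * sa - cg * sb * ca,
          -cb * sa,                     cg * ca - sg * sb * sa,  sg * ca + cg * sb * sa,
          sb,                          -sg * cb,                 cg * cb,
          deparse.level = 0)
  } else if (convention == "zyx") {
    # R = Rz(alpha) %*% Ry(beta) %*% Rx(gamma)
    cbind(ca * cb,                 sa * cb,                -sb,
          ca * sb * sg - sa * cg,  sa * sb * sg + ca * cg,  cb * sg,
          ca * sb * cg + sa * sg,  sa * sb * cg - ca * sg,  cb * cg,
          deparse.level = 0)
  } else {
    stop("unknown Tait-Bryan convention: ", convention, call. = FALSE)
  }
}

# Vectorised inverse conversion on an N x 9 element matrix;
# returns an N x 3 matrix with columns gamma, beta, alpha.
angles_from_elements <- function(el, convention = "zxy") {
  if (convention == "zxy") {
    g <- asin(pmin(pmax(el[, 6], -1), 1))          # r32
    b <- atan2(-el[, 3], el[, 9])                  # -r31, r33
    a <- atan2(-el[, 4], el[, 5])                  # -r12, r22
  } else if (convention == "xyz") {
    b <- asin(pmin(pmax(el[, 7], -1), 1))          # r13
    g <- atan2(-el[, 8], el[, 9])                  # -r23, r33
    a <- atan2(-el[, 4], el[, 1])                  # -r12, r11
  } else if (convention == "zyx") {
    b <- asin(pmin(pmax(-el[, 3], -1), 1))         # -r31
    g <- atan2(el[, 6], el[, 9])                   # r32, r33
    a <- atan2(el[, 2], el[, 1])                   # r21, r11
  } else {
    stop("unknown Tait-Bryan convention: ", convention, call. = FALSE)
  }
  cbind(gamma = g, beta = b, alpha = a)
}

#' Tait-Bryan angles from a rotation matrix
#'
#' @param R a 3x3 rotation matrix.
#' @inheritParams rotation_from_tait_bryan
#' @return named numeric vector \code{c(gamma, beta, alpha)} in radians
#'   (or degrees when \code{degrees = TRUE}). Away from gimbal lock this
#'   round-trips with [rotation_from_tait_bryan()].
#' @export
tait_bryan_from_rotation <- function(R, convention = c("zxy", "xyz", "zyx"),
                                     degrees = FALSE) {
  convention <- match.arg(convention)
  check_rotation(R)
  ang <- angles_from_elements(matrix(as.vector(R), 1, 9), convention)
  out <- c(gamma = ang[1, 1], beta = ang[1, 2], alpha = ang[1, 3])
  if (degrees) out * 180 / pi else out
}

check_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || !identical(dim(R), c(3L, 3L)))
    stop("expected a 3x3 matrix", call. = FALSE)
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("matrix is not orthonormal within tolerance ", tol, call. = FALSE)
  if (abs(det(R) - 1) > tol)
    stop("matrix determinant is not +1 (improper rotation?)", call. = FALSE)
  invisible(R)
}

#' Orientation of a child frame relative to a reference frame
#'
#' Given the head-mounted display's rotation \eqn{R^G_H} and a controller's
#' rotation \eqn{R^G_C}, both expressed in the global frame, returns the
#' controller's orientation in the head frame,
#' \eqn{R^H_C = (R^G_H)^{-1} R^G_C = (R^G_H)^T R^G_C}.
#'
#' @param R_GH rotation of the reference (head) frame in the global frame.
#' @param R_GC rotation of the child (controller) frame in the global frame.
#' @return the 3x3 relative rotation \eqn{R^H_C}.
#' @export
relative_orientation <- function(R_GH, R_GC) {
  check_rotation(R_GH)
  check_rotation(R_GC)
  crossprod(R_GH, R_GC)
}

#' Position of a point expressed in a reference frame
#'
#' Inverse homogeneous transform applied to a global-frame point: returns
#' \eqn{(R^G_H)^T (P^G_C - P^G_H)}, the controller position in the head
#' frame \{H\}.
#'
#' @param P_GH global position of the reference-frame origin (head).
#' @param R_GH rotation of the reference frame in the global frame.
#' @param P_GC global position of the point (controller).
#' @return length-3 numeric vector: the point in \{H\} coordinates.
#' @export
relative_position <- function(P_GH, R_GH, P_GC) {
  stopifnot(length(P_GH) == 3, length(P_GC) == 3,
            all(is.finite(P_GH)), all(is.finite(P_GC)))
  check_rotation(R_GH)
  drop(crossprod(R_GH, P_GC - P_GH))
}

#' Midpoint of the two controllers
#'
#' The cursor in the interface is driven by the point midway between the two
#' hand controllers, the componentwise mean of their positions (in any
#' common frame).
#'
#' @param P_GR,P_GL length-3 positions of the right and left controller.
#' @return length-3 numeric vector.
#' @export
controller_midpoint <- function(P_GR, P_GL) {
  stopifnot(length(P_GR) == 3, length(P_GL) == 3)
  (P_GR + P_GL) / 2
}
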