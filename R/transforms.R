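#' Rigid transforms
#'
#' A rigid transform maps source-frame coordinates \code{x} (mm) to
#' target-frame coordinates \code{R x + t} (active convention). Rotations are
#' proper (det = +1); reflections are rejected.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric vector (mm).
#' @return An object of class \code{rigid_transform} with elements
#'   \code{rotation} and \code{translation}.
#' @examples
#' tr <- rigid_transform(rot_y(30), c(1, 0, 0))
#' apply_transform(tr, c(0, 0, 1))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be proper (det = +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
transform_identity <- function() rigid_transform()

#' @param x object to test.
#' @rdname rigid_transform
#' @export
is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' Elementary rotations
#'
#' Rotation matrices about the anatomical axes (+x cranial, +y left/mediolateral,
#' +z dorsal), angle in degrees.
#'
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rot_y <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), 0, -sin(a),
           0,      1,  0,
           sin(a), 0,  cos(a)), 3, 3)
}

#' @rdname rot_y
#' @export
rot_x <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3)
}

#' @rdname rot_y
#' @export
rot_z <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), sin(a), 0,
           -sin(a), cos(a), 0,
           0, 0, 1), 3, 3)
}

#' Rotation about an arbitrary axis and pivot
#'
#' @param pivot length-3 point the axis passes through (mm).
#' @param axis length-3 direction vector (normalized internally).
#' @param angle_deg rotation angle in degrees (right-handed about \code{axis}).
#' @return \code{rigid_transform}.
#' @export
rotation_about <- function(pivot, axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  rigid_transform(R, as.numeric(pivot - R %*% pivot))
}

#' Apply, compose and invert rigid transforms
#'
#' @param tr a \code{rigid_transform}.
#' @param points n x 3 matrix (or length-3 vector) of coordinates in mm.
#' @return \code{apply_transform}: transformed points, same shape as input.
#' @export
apply_transform <- function(tr, points) {
  stopifnot(is_rigid_transform(tr))
  if (is.null(dim(points))) {
    as.numeric(tr$rotation %*% points + tr$translation)
  } else {
    sweep(points %*% t(tr$rotation), 2, tr$translation, "+")
  }
}

#' @param a,b transforms; the composition applies \code{b} first, then \code{a}.
#' @rdname apply_transform
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation + a$translation))
}

#' @rdname apply_transform
#' @export
invert_transform <- function(tr) {
  Rt <- t(tr$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% tr$translation))
}

#' @param m 4x4 homogeneous matrix.
#' @rdname apply_transform
#' @export
transform_from_matrix <- function(m) {
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' @rdname apply_transform
#' @export
transform_to_matrix <- function(tr) {
  m <- diag(4)
  m[1:3, 1:3] <- tr$rotation
  m[1:3, 4] <- tr$translation
  m
}

#' Axis-angle decomposition of a rotation
#'
#' @param R 3x3 proper rotation matrix.
#' @return list with \code{angle_deg} in [0, 180] and unit \code{axis}
#'   (arbitrary for the identity).
#' @export
axis_angle <- function(R) {
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop("not a proper rotation matrix")
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  angle <- acos(ct)
  if (angle < 1e-12) {
    axis <- c(0, 1, 0)
  } else if (abs(angle - pi) < 1e-6) {
    # near 180 deg: axis from the largest diagonal entry of (R + I)/2
    B <- (R + diag(3)) / 2
    i <- which.max(diag(B))
    axis <- B[, i] / sqrt(max(B[i, i], .Machine$double.eps))
    axis <- axis / sqrt(sum(axis^2))
  } else {
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(angle))
  }
  list(angle_deg = angle * 180 / pi, axis = as.numeric(axis))
}

#' @export
print.rigid_transform <- function(x, ...) {
  aa <- axis_angle(x$rotation)
  cat(sprintf("rigid transform: %.3f deg about (%.3f, %.3f, %.3f), t = (%.3f, %.3f, %.3f) mm\n",
              aa$angle_deg, aa$axis[1], aa$axis[2], aa$axis[3],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}
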