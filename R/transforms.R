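#' Affine transform on physical coordinates
#'
#' A 4x4 homogeneous matrix mapping fixed-space physical coordinates (um) to
#' moving-space physical coordinates. Warping pulls moving-image values back
#' through this map onto the fixed grid. The last row must be (0,0,0,1) and
#' the linear block must be invertible.
#'
#' @param matrix 4x4 homogeneous matrix.
#' @return An object of class `affine3d`.
#' @export
affine3d <- function(matrix) {
  matrix <- as.matrix(matrix)
  stopifnot(all(dim(matrix) == c(4, 4)))
  if (any(abs(matrix[4, ] - c(0, 0, 0, 1)) > 1e-9))
    stop("affine3d: last row must be (0, 0, 0, 1)")
  if (abs(det(matrix[1:3, 1:3])) < 1e-12)
    stop("affine3d: linear block is singular")
  structure(list(matrix = matrix), class = "affine3d")
}

#' @export
print.affine3d <- function(x, ...) {
  cat("<affine3d>\n"); print(signif(x$matrix, 6)); invisible(x)
}

#' @rdname affine3d
#' @export
affine_identity <- function() affine3d(diag(4))

#' Pure translation transform
#' @param t translation vector (um).
#' @export
affine_translation <- function(t) {
  m <- diag(4); m[1:3, 4] <- t; affine3d(m)
}

# Rotation matrix about a unit axis by angle (Rodrigues).
rotation_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1], axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Euler rotation (intrinsic z-y-x): R = Rz(rz) %*% Ry(ry) %*% Rx(rx).
rotation_euler <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx); cy <- cos(ry); sy <- sin(ry); cz <- cos(rz); sz <- sin(rz)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Rigid transform from rotation and translation about a centre
#'
#' Builds `T(v) = R (v - c) + c + t` with `R` the intrinsic z-y-x Euler
#' rotation, so rotations pivot about `center` rather than the physical
#' origin.
#'
#' @param rotation Euler angles (rx, ry, rz) in radians.
#' @param translation translation (um).
#' @param center pivot point (um).
#' @export
affine_rigid <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                         center = c(0, 0, 0)) {
  R <- rotation_euler(rotation[1], rotation[2], rotation[3])
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- center + translation - R %*% center
  affine3d(m)
}

# General linear + translation about a centre: T(v) = A (v - c) + c + t.
affine_linear <- function(A, translation = c(0, 0, 0), center = c(0, 0, 0)) {
  m <- diag(4)
  m[1:3, 1:3] <- A
  m[1:3, 4] <- center + translation - A %*% center
  affine3d(m)
}

#' Compose and invert affine transforms
#'
#' `compose_affine(a, b)` is the map `v -> a(b(v))`.
#' @param a,b,t `affine3d` objects.
#' @export
compose_affine <- function(a, b) affine3d(a$matrix %*% b$matrix)

#' @rdname compose_affine
#' @export
invert_affine <- function(t) affine3d(solve(t$matrix))

#' Apply an affine transform to physical points
#' @param t an `affine3d`.
#' @param pts n x 3 matrix of physical coordinates (um).
#' @return n x 3 matrix of transformed coordinates.
#' @export
apply_affine <- function(t, pts) {
  pts <- matrix(pts, ncol = 3)
  h <- cbind(pts, 1) %*% t(t$matrix)
  h[, 1:3, drop = FALSE]
}

#' Rotation angle of a rigid transform
#'
#' Extracts the rotation angle from the linear block via
#' `acos((tr(R) - 1) / 2)`.
#' @param t an `affine3d` with orthonormal linear block.
#' @return angle in radians.
#' @export
rotation_angle <- function(t) {
  tr <- sum(diag(t$matrix[1:3, 1:3]))
  acos(pmin(1, pmax(-1, (tr - 1) / 2)))
}
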