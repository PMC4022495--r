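deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle into (-180, 180]
#'
#' @param x angle(s) in degrees.
#' @return wrapped angle(s) in degrees, in the half-open interval (-180, 180].
#' @examples
#' wrap_angle(181)  # -179
#' wrap_angle(-179) # -179
#' @export
wrap_angle <- function(x) {
  x - 360 * ceiling((x - 180) / 360)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}

#' Torsion (dihedral) angle of four points
#'
#' Standard IUPAC sign convention: looking down the p2->p3 bond, a clockwise
#' rotation of the far bond relative to the near bond is positive.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Cartesian, Angstrom).
#' @return torsion angle in degrees, in (-180, 180].
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(rad2deg(atan2(-y, x)))
}

#' Bond angle at the middle point of three points
#'
#' @param p1,p2,p3 numeric 3-vectors; the angle is measured at `p2`.
#' @return angle in degrees, in [0, 180].
#' @export
bond_angle <- function(p1, p2, p3) {
  v1 <- unitv(p1 - p2)
  v2 <- unitv(p3 - p2)
  rad2deg(acos(max(-1, min(1, sum(v1 * v2)))))
}

#' Rotation matrix about an arbitrary axis (Rodrigues)
#'
#' @param axis 3-vector (normalized internally).
#' @param angle_deg rotation in degrees, right-handed about `axis`.
#' @return 3x3 proper rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- unitv(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Angle and axis of a rotation matrix
#'
#' The angle is reported in [0, 180] degrees and the axis sign is chosen so
#' the rotation is right-handed about it.  Near 0 and 180 degrees the axis is
#' recovered from the symmetric part (eigenvector for eigenvalue +1).
#'
#' @param R 3x3 proper rotation matrix.
#' @return list with `angle` (degrees) and `axis` (unit 3-vector).
#' @export
rotation_angle_axis <- function(R) {
  tr <- sum(diag(R))
  cth <- max(-1, min(1, (tr - 1) / 2))
  angle <- rad2deg(acos(cth))
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  s <- vnorm(v)
  if (s > 1e-8) {
    axis <- v / s
  } else if (angle < 90) {
    axis <- c(0, 0, 1)                      # angle ~ 0: axis undefined
  } else {
    # angle ~ 180: axis from eigenvector of (R + I)
    M <- R + diag(3)
    j <- which.max(colSums(M^2))
    axis <- unitv(M[, j])
    if (vnorm(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])) > 0) {
      if (sum(axis * v) < 0) axis <- -axis
    }
  }
  list(angle = angle, axis = axis)
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Places point D bonded to C, given reference points A, B, C, a bond length
#' `r` (C-D), a bond angle `theta` (B-C-D) and a torsion `tau` defined as
#' `torsion_angle(A, B, C, D)`.
#'
#' @param A,B,C numeric 3-vectors of the three reference atoms.
#' @param r bond length C-D in Angstrom.
#' @param theta bond angle B-C-D in degrees.
#' @param tau torsion A-B-C-D in degrees.
#' @return position of D as a numeric 3-vector.
#' @export
place_atom <- function(A, B, C, r, theta, tau) {
  thr <- deg2rad(theta)
  tar <- deg2rad(tau)
  bc <- unitv(C - B)
  n <- unitv(cross3(B - A, bc))
  m <- cross3(n, bc)
  d <- c(-r * cos(thr), r * sin(thr) * cos(tar), r * sin(thr) * sin(tar))
  C + d[1] * bc + d[2] * m + d[3] * n
}
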