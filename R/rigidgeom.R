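# Rigid-body least-squares superposition and axis-angle / screw decomposition.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1).
#' @param translation length-3 numeric, Angstrom.
#' @param rmsd non-negative fit residual, Angstrom.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            rmsd = 0) {
  rotation <- unname(as.matrix(rotation))
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    .stopf("rotation matrix is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    .stopf("rotation matrix is not proper (det != +1)")
  if (rmsd < 0) .stopf("negative rmsd")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 rmsd = rmsd), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  aa <- rotation_to_axis_angle(x)
  cat(sprintf("rigid_transform: rotation %.4f deg, |t| = %.3f A, rmsd %.4f A\n",
              aa$angle, sqrt(sum(x$translation^2)), x$rmsd))
  invisible(x)
}

#' Least-squares (Kabsch) superposition of paired point sets
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `R %*% mobile + t` against `target`; reflections are excluded by the
#' determinant correction of the SVD solution.
#'
#' @param mobile,target n x 3 coordinate matrices (or data.frames with
#'   x/y/z), n >= 3, rows paired.
#' @return A [rigid_transform()] carrying the residual RMSD.
#' @export
kabsch_superpose <- function(mobile, target) {
  if (is.data.frame(mobile)) mobile <- .xyz(mobile)
  if (is.data.frame(target)) target <- .xyz(target)
  mobile <- unname(as.matrix(mobile)); target <- unname(as.matrix(target))
  if (nrow(mobile) != nrow(target))
    .stopf("point lists differ in length (%d vs %d)",
           nrow(mobile), nrow(target))
  if (nrow(mobile) < 3L) .stopf("need at least 3 points, got %d", nrow(mobile))
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  # collinearity check: centered points must span at least a plane
  sd_ <- svd(A, nu = 0, nv = 0)$d
  if (sd_[2] < 1e-9 * max(1, sd_[1]))
    .stopf("degenerate geometry: mobile points are collinear")
  H <- crossprod(A, B)           # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- ct - as.numeric(R %*% cm)
  fitted <- sweep(tcrossprod(mobile, R), 2, t, "+")
  rmsd <- sqrt(mean(rowSums((fitted - target)^2)))
  rigid_transform(R, t, rmsd)
}

#' Convert a rotation to axis-angle (screw) form
#'
#' Angle in degrees in \[0, 180\]; the axis sign is chosen so the angle is
#' non-negative. `point_on_axis` is the screw-axis anchor: the point (of
#' minimal norm) whose in-plane displacement under the transform vanishes.
#' The identity rotation reports angle 0 with the conventional axis (0,0,1).
#'
#' @param transform a [rigid_transform()] (or bare 3x3 rotation matrix).
#' @return List with `axis` (unit 3-vector), `angle` (degrees),
#'   `point_on_axis` (3-vector, Angstrom), class `axis_angle`.
#' @export
rotation_to_axis_angle <- function(transform) {
  if (is.matrix(transform)) transform <- rigid_transform(transform)
  R <- transform$rotation; tr <- transform$translation
  cosang <- (sum(diag(R)) - 1) / 2
  cosang <- min(1, max(-1, cosang))
  v0 <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  sinang <- sqrt(sum(v0^2)) / 2
  # atan2 keeps full precision for small angles where acos loses half the
  # significant digits; near 180 deg sinang vanishes and the eigenvector
  # branch below takes over
  angle <- atan2(sinang, cosang)      # radians, [0, pi]
  if (angle < 1e-12) {
    out <- list(axis = c(0, 0, 1), angle = 0, point_on_axis = c(0, 0, 0))
    class(out) <- "axis_angle"
    return(out)
  }
  if (pi - angle > 1e-6) {
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    axis <- v / (2 * sin(angle))
  } else {
    # near 180 deg: antisymmetric part vanishes; use the +1 eigenvector
    ei <- eigen(R)
    k <- which.min(abs(ei$values - 1))
    axis <- Re(ei$vectors[, k])
    axis <- axis / sqrt(sum(axis^2))
    # fix the sign so sin(angle) >= 0 w.r.t. the antisymmetric remnant
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    if (sum(v * axis) < 0) axis <- -axis
  }
  axis <- axis / sqrt(sum(axis^2))
  # screw anchor: solve the in-plane part of (I - R) p = t_perp
  t_perp <- tr - sum(tr * axis) * axis
  half <- angle / 2
  p <- 0.5 * (t_perp + .cross3(axis, t_perp) / tan(half))
  out <- list(axis = as.numeric(axis), angle = angle * 180 / pi,
              point_on_axis = as.numeric(p))
  class(out) <- "axis_angle"
  out
}

#' @export
print.axis_angle <- function(x, ...) {
  cat(sprintf("axis_angle: %.4f deg about (%.4f, %.4f, %.4f)\n",
              x$angle, x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

#' Build a rotation matrix from axis and angle (Rodrigues)
#' @param axis 3-vector (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
axis_angle_to_rotation <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to coordinates
#' @param positions n x 3 matrix or data.frame with x/y/z columns.
#' @param transform a [rigid_transform()].
#' @return Object of the same shape with transformed coordinates.
#' @export
apply_transform <- function(positions, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(positions, "structure_model")) {
    positions$atoms[, c("x", "y", "z")] <-
      apply_transform(.xyz(positions$atoms), transform)
    return(positions)
  }
  df <- is.data.frame(positions)
  xyz <- if (df) .xyz(positions) else as.matrix(positions)
  out <- sweep(tcrossprod(xyz, transform$rotation), 2,
               transform$translation, "+")
  if (df) {
    positions[, c("x", "y", "z")] <- out
    positions
  } else out
}

#' Compose two rigid transforms (`second` after `first`)
#' @param second,first [rigid_transform()] objects.
#' @return The composite [rigid_transform()].
#' @export
compose_transforms <- function(second, first) {
  rigid_transform(second$rotation %*% first$rotation,
                  as.numeric(second$rotation %*% first$translation) +
                    second$translation)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}
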