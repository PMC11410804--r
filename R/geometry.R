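## Rigid-body geometry: rotations, least-squares superposition, screw axes.

#' Rotation matrix about an arbitrary axis
#'
#' @param axis numeric(3) axis direction (need not be normalized).
#' @param angle rotation angle in degrees.
#' @return 3x3 proper rotation matrix.
#' @export
rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  c1 <- cos(th); s1 <- sin(th)
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + s1 * K + (1 - c1) * (K %*% K)
}

#' Rigid transform as an S3 object
#'
#' A proper rotation plus translation, applied as `x -> x R^T + t` for row
#' coordinate matrices.
#'
#' @param rotation 3x3 orthonormal matrix with det +1.
#' @param translation numeric(3), Angstrom.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation must be orthonormal (R'R = I within 1e-8)")
  if (det(rotation) < 0)
    stop("rotation must be proper (det +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to an N x 3 coordinate matrix
#' @param tr a [rigid_transform].
#' @param xyz N x 3 matrix of coordinates.
#' @return transformed N x 3 matrix.
#' @export
apply_transform <- function(tr, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  sweep(xyz %*% t(tr$rotation), 2, tr$translation, "+")
}

#' Compose two rigid transforms (first `b`, then `a`)
#' @keywords internal
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @keywords internal
invert_transform <- function(tr) {
  rigid_transform(t(tr$rotation), as.numeric(-t(tr$rotation) %*% tr$translation))
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation)
  cat(sprintf("rigid_transform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) A\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' matched coordinate sets, mapping `coords_b` onto `coords_a`.
#'
#' @param coords_a,coords_b N x 3 matrices of matched points (N >= 3,
#'   non-collinear).
#' @return list with `transform` (a [rigid_transform] such that
#'   `apply_transform(transform, coords_b)` best fits `coords_a`) and `rmsd`
#'   in Angstrom.
#' @export
kabsch <- function(coords_a, coords_b) {
  a <- matrix(as.numeric(coords_a), ncol = 3)
  b <- matrix(as.numeric(coords_b), ncol = 3)
  if (nrow(a) != nrow(b)) stop("point sets must have equal length")
  if (nrow(a) < 3) stop("need at least 3 points")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  ## collinearity check: rank of the centered set
  if (svd(b0)$d[2] < 1e-8 * max(1, svd(b0)$d[1]))
    stop("degenerate (collinear) point set")
  H <- crossprod(b0, a0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- ca - as.numeric(R %*% cb)
  tr <- rigid_transform(R, tvec)
  fit <- apply_transform(tr, b)
  rmsd <- sqrt(mean(rowSums((fit - a)^2)))
  list(transform = tr, rmsd = rmsd)
}

#' Rotation angle of a rotation matrix, degrees in [0, 180]
#' @keywords internal
rotation_angle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Rotation axis (unit vector) of a rotation matrix
#'
#' For angles near 180 degrees the skew-symmetric part vanishes and the axis
#' is recovered from the symmetric part instead.
#' @keywords internal
rotation_axis <- function(R) {
  ang <- rotation_angle(R)
  if (ang < 1e-7) return(c(0, 0, 1))
  if (ang < 179.9) {
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    return(v / sqrt(sum(v^2)))
  }
  ## near 180 deg: axis from R + I (columns proportional to axis)
  M <- R + diag(3)
  i <- which.max(colSums(M^2))
  v <- M[, i]
  v / sqrt(sum(v^2))
}

#' Decompose a rigid transform into a screw motion
#'
#' Extracts the rotation axis direction, an anchor point on the axis (the
#' point on the axis closest to the origin), the rotation angle and the
#' translation component along the axis (screw shift).
#'
#' @param tr a [rigid_transform].
#' @return list with `angle` (degrees), `direction` (unit 3-vector),
#'   `anchor` (point on axis), `screw_shift` (Angstrom, signed along
#'   `direction`).
#' @export
screw_decompose <- function(tr) {
  R <- tr$rotation; tv <- tr$translation
  ang <- rotation_angle(R)
  u <- rotation_axis(R)
  s <- sum(tv * u)                    # shift along axis
  tp <- tv - s * u                    # in-plane translation
  ## solve (I - R) p = tp for a point on the axis; (I - R) is singular along u,
  ## use least squares and project out the axis component of p.
  A <- diag(3) - R
  p <- tryCatch(qr.solve(A, tp, tol = 1e-12),
                error = function(e) as.numeric(pseudo_inverse(A) %*% tp))
  p <- p - sum(p * u) * u
  list(angle = ang, direction = u, anchor = as.numeric(p), screw_shift = s)
}

## tiny Moore-Penrose fallback for the singular 180-degree case
pseudo_inverse <- function(A, tol = 1e-10) {
  sv <- svd(A)
  pos <- sv$d > tol * max(sv$d)
  dinv <- ifelse(pos, 1 / sv$d, 0)
  sv$v %*% (dinv * t(sv$u))
}

#' Minimal rotation taking unit vector `from` to unit vector `to`
#' @keywords internal
rotation_between <- function(from, to) {
  f <- from / sqrt(sum(from^2)); t2 <- to / sqrt(sum(to^2))
  v <- c(f[2] * t2[3] - f[3] * t2[2],
         f[3] * t2[1] - f[1] * t2[3],
         f[1] * t2[2] - f[2] * t2[1])
  s <- sqrt(sum(v^2)); c1 <- sum(f * t2)
  if (s < 1e-12) {
    if (c1 > 0) return(diag(3))
    ## opposite: rotate 180 about any axis perpendicular to f
    perp <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- perp - sum(perp * f) * f
    return(rotation_about(ax, 180))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c1) / s^2)
}
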