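#' Affine transform in world (mm) coordinates
#'
#' A 4x4 homogeneous matrix mapping moving-space world coordinates to
#' fixed-space world coordinates. All transforms in the package use this
#' convention; voxel-space conversion happens only at resampling boundaries.
#'
#' @param matrix 4x4 numeric matrix with bottom row (0,0,0,1); must be
#'   invertible.
#' @return An object of class `mvseg_affine`.
#' @export
affine_transform <- function(matrix) {
  matrix <- unname(as.matrix(matrix))
  stopifnot(all(dim(matrix) == c(4L, 4L)))
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("bottom row of an affine transform must be (0, 0, 0, 1)")
  if (abs(det(matrix[1:3, 1:3])) < 1e-12)
    stop("affine transform is not invertible")
  structure(list(matrix = matrix), class = "mvseg_affine")
}

#' @rdname affine_transform
#' @export
identity_transform <- function() affine_transform(diag(4))

as_affine <- function(x) {
  if (inherits(x, "mvseg_affine")) x else affine_transform(x)
}

#' Compose two affine transforms
#'
#' `compose(a, b)` applies `b` first, then `a` (matrix product `a %*% b`),
#' the concatenation used to chain sequence-to-T1 and T1-to-standard
#' transforms.
#'
#' @param a,b [affine_transform()] objects.
#' @return The composed [affine_transform()].
#' @export
compose <- function(a, b) {
  affine_transform(as_affine(a)$matrix %*% as_affine(b)$matrix)
}

#' Invert an affine transform
#' @param a an [affine_transform()].
#' @return The inverse transform.
#' @export
invert <- function(a) affine_transform(solve(as_affine(a)$matrix))

#' Apply a transform to points
#' @param a an [affine_transform()].
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of mapped coordinates.
#' @export
apply_transform <- function(a, pts) {
  pts <- rbind(t(as.matrix(pts)), 1)
  out <- as_affine(a)$matrix %*% pts
  t(out[1:3, , drop = FALSE])
}

#' Rigid component of an affine transform
#'
#' Returns the transform with the same translation and the rotation factor of
#' the 3x3 block (the orthogonal polar factor, det +1), with scale and shear
#' removed. Used to initialize the second, rigid registration step from the
#' first-step affine matrix. Computed by the Newton iteration for the polar
#' decomposition, `X <- (X + t(solve(X))) / 2`, which converges quadratically
#' to the orthogonal factor.
#'
#' @param a an [affine_transform()] whose 3x3 block has positive determinant
#'   (a reflection has no rigid rotation factor).
#' @return An [affine_transform()] with orthogonal 3x3 block.
#' @export
rigid_component <- function(a) {
  m <- as_affine(a)$matrix
  A <- m[1:3, 1:3]
  if (det(A) <= 0)
    stop("3x3 block has non-positive determinant; no rigid rotation factor")
  X <- A
  for (i in 1:60) {
    Xn <- (X + t(solve(X))) / 2
    if (max(abs(Xn - X)) < 1e-15) { X <- Xn; break }
    X <- Xn
  }
  out <- diag(4)
  out[1:3, 1:3] <- X
  out[1:3, 4] <- m[1:3, 4]
  affine_transform(out)
}

#' Build a rigid or affine matrix from parameters
#'
#' Parameters act about a center point `c`: translation (mm), rotations about
#' x, y, z (degrees, applied as Rz Ry Rx), then for 12-dof transforms scales
#' (as 1 + s) and shears. Used by the registration optimizer.
#'
#' @param p numeric vector of length 6 (rigid) or 12 (affine):
#'   `(tx, ty, tz, rx, ry, rz[, sx, sy, sz, hxy, hxz, hyz])`.
#' @param center length-3 center of rotation in world mm.
#' @return An [affine_transform()].
#' @export
params_to_affine <- function(p, center = c(0, 0, 0)) {
  stopifnot(length(p) %in% c(6L, 12L))
  r <- p[4:6] * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  A <- Rz %*% Ry %*% Rx
  if (length(p) == 12L) {
    S <- diag(1 + p[7:9])
    H <- diag(3)
    H[1, 2] <- p[10]; H[1, 3] <- p[11]; H[2, 3] <- p[12]
    A <- A %*% S %*% H
  }
  m <- diag(4)
  m[1:3, 1:3] <- A
  m[1:3, 4] <- p[1:3] + center - A %*% center
  affine_transform(m)
}

#' Rigid discrepancy between two transforms
#'
#' Measures how far transform `a` is from transform `b`: the rotation angle of
#' the relative 3x3 factor (degrees) and the displacement of a reference point
#' (mm), typically the volume center. Used to assert transform-recovery
#' accuracy.
#'
#' @param a,b [affine_transform()] objects.
#' @param center length-3 reference point in world mm.
#' @return List with elements `rot_deg` and `trans_mm`.
#' @export
transform_discrepancy <- function(a, b, center = c(0, 0, 0)) {
  d <- as_affine(a)$matrix %*% solve(as_affine(b)$matrix)
  R <- rigid_component(affine_transform(d))$matrix[1:3, 1:3]
  ctheta <- (sum(diag(R)) - 1) / 2
  rot <- acos(min(1, max(-1, ctheta))) * 180 / pi
  p <- apply_transform(d, matrix(center, 1))
  list(rot_deg = rot, trans_mm = sqrt(sum((p - center)^2)))
}
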