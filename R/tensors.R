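# Saupe alignment tensor parameterizations and interconversion.
#
# A tensor is stored as a traceless symmetric 3x3 matrix A (Hz) such that the
# coupling predicted for a unit bond vector v is v' A v. In the tensor's
# principal axis system (PAS) this equals
#   Da * [(3 cos^2 theta - 1) + (3/2) R sin^2 theta cos 2Phi]
# with Da = Azz/2 (the population-scaled magnitude) and rhombicity
# R = (Axx - Ayy) / (3 Da) in [0, 2/3].

#' Build a Saupe matrix from magnitude, rhombicity and orientation
#'
#' @param da population-scaled tensor magnitude (Hz); sign allowed.
#' @param rhombicity dimensionless rhombicity in [0, 2/3].
#' @param euler length-3 numeric (alpha, beta, gamma), radians; intrinsic
#'   z-y-z rotation carrying the principal axis system into the molecular
#'   frame.
#' @return \code{alignment_tensor}: list(saupe, da, rhombicity, euler).
#' @export
alignment_tensor <- function(da, rhombicity = 0, euler = c(0, 0, 0)) {
  if (rhombicity < 0 || rhombicity > 2 / 3 + 1e-12) {
    stop("rhombicity must lie in [0, 2/3]")
  }
  pas <- diag(c(-da * (1 - 1.5 * rhombicity),
                -da * (1 + 1.5 * rhombicity),
                2 * da))
  R <- euler_zyz(euler[1], euler[2], euler[3])
  saupe <- R %*% pas %*% t(R)
  saupe <- (saupe + t(saupe)) / 2
  structure(list(saupe = saupe, da = da, rhombicity = rhombicity,
                 euler = euler),
            class = "alignment_tensor")
}

#' z-y-z Euler rotation matrix
#' @param alpha,beta,gamma angles in radians.
#' @return 3x3 rotation matrix Rz(alpha) Ry(beta) Rz(gamma).
#' @export
euler_zyz <- function(alpha, beta, gamma) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3)
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

#' Recover (Da, rhombicity, Euler angles) from a Saupe matrix
#'
#' Eigen-decomposes the traceless symmetric matrix; the eigenvalue of largest
#' magnitude defines the z axis (Azz = 2 Da) and the remaining two are
#' assigned so the rhombicity is non-negative.
#'
#' @param saupe traceless symmetric 3x3 matrix (Hz).
#' @return \code{alignment_tensor} with the same Saupe matrix.
#' @export
tensor_from_saupe <- function(saupe) {
  if (max(abs(saupe - t(saupe))) > 1e-9) stop("Saupe matrix must be symmetric")
  if (abs(sum(diag(saupe))) > 1e-6 * max(1, max(abs(saupe)))) {
    stop("Saupe matrix must be traceless")
  }
  e <- eigen((saupe + t(saupe)) / 2, symmetric = TRUE)
  iz <- which.max(abs(e$values))
  rest <- setdiff(1:3, iz)
  azz <- e$values[iz]
  da <- azz / 2
  # choose x/y assignment so R = (Axx - Ayy)/(3 Da) >= 0
  v1 <- e$values[rest[1]]; v2 <- e$values[rest[2]]
  if (da == 0) {
    axx <- v1; ayy <- v2; ix <- rest[1]; iy <- rest[2]
  } else if ((v1 - v2) / (3 * da) >= 0) {
    axx <- v1; ayy <- v2; ix <- rest[1]; iy <- rest[2]
  } else {
    axx <- v2; ayy <- v1; ix <- rest[2]; iy <- rest[1]
  }
  rhomb <- if (da == 0) 0 else (axx - ayy) / (3 * da)
  rhomb <- min(max(rhomb, 0), 2 / 3)
  R <- cbind(e$vectors[, ix], e$vectors[, iy], e$vectors[, iz])
  if (det(R) < 0) R[, 1] <- -R[, 1]
  # z-y-z Euler extraction
  beta <- acos(min(max(R[3, 3], -1), 1))
  if (abs(sin(beta)) > 1e-10) {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  } else {
    alpha <- atan2(R[2, 1], R[1, 1])
    gamma <- 0
  }
  out <- alignment_tensor(da, rhomb, c(alpha, beta, gamma))
  out$saupe <- (saupe + t(saupe)) / 2 # keep input exactly
  out
}

#' @export
print.alignment_tensor <- function(x, ...) {
  cat(sprintf(
    "<alignment_tensor> Da = %.4g Hz, rhombicity = %.4f, euler = (%.3f, %.3f, %.3f) rad\n",
    x$da, x$rhombicity, x$euler[1], x$euler[2], x$euler[3]))
  invisible(x)
}

# 5-vector packing: s = (Ayy, Azz, Axy, Axz, Ayz), Axx = -Ayy - Azz.
saupe_to_svec <- function(saupe) {
  c(saupe[2, 2], saupe[3, 3], saupe[1, 2], saupe[1, 3], saupe[2, 3])
}

svec_to_saupe <- function(s) {
  matrix(c(-s[1] - s[2], s[3], s[4],
           s[3], s[1], s[5],
           s[4], s[5], s[2]), 3, 3)
}

#' Direction-cosine design rows for a set of unit bond vectors
#'
#' For a unit vector (x, y, z) the row is
#' (y^2 - x^2, z^2 - x^2, 2xy, 2xz, 2yz); the dot product with the packed
#' Saupe elements (Ayy, Azz, Axy, Axz, Ayz) equals v' A v, the predicted
#' coupling in Hz.
#'
#' @param v \code{nh_vectors} data.frame (resno, x, y, z), unit norm.
#' @return numeric matrix, one row per residue, rownames = resno.
#' @export
direction_cosines <- function(v) {
  norms <- sqrt(v$x^2 + v$y^2 + v$z^2)
  if (any(abs(norms - 1) > 1e-6)) stop("bond vectors must be unit norm")
  m <- cbind(v$y^2 - v$x^2, v$z^2 - v$x^2,
             2 * v$x * v$y, 2 * v$x * v$z, 2 * v$y * v$z)
  rownames(m) <- v$resno
  m
}

#' Draw a random admissible alignment tensor
#'
#' Magnitude uniform over \code{da_range} (random sign), rhombicity uniform
#' on [0, 2/3], orientation uniform over rotations.
#'
#' @param da_range range of |Da| in Hz.
#' @return \code{alignment_tensor}.
#' @export
random_tensor <- function(da_range = c(8, 16)) {
  da <- stats::runif(1, da_range[1], da_range[2]) * sample(c(-1, 1), 1)
  rhomb <- stats::runif(1, 0, 2 / 3)
  alpha <- stats::runif(1, -pi, pi)
  beta <- acos(stats::runif(1, -1, 1))
  gamma <- stats::runif(1, -pi, pi)
  alignment_tensor(da, rhomb, c(alpha, beta, gamma))
}
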