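# Rigid-body geometry: Kabsch superposition, RMSD, plane fits, rounding.

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares rotation + translation mapping `moving` onto `fixed`.
#' Both are n x 3 coordinate matrices with matching row order.
#'
#' @param moving,fixed n x 3 matrices, Angstrom.
#' @return list with `rotation` (3 x 3), `translation` (length 3), and
#'   `rmsd` after superposition. The fitted coordinates are
#'   `moving %*% rotation + translation` (row-vector convention).
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' th <- 0.7
#' R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
#' fit <- kabsch_fit(a %*% R + 2, a)
#' fit$rmsd # ~0
#' @export
kabsch_fit <- function(moving, fixed) {
  stopifnot(is.matrix(moving), is.matrix(fixed),
            ncol(moving) == 3, ncol(fixed) == 3,
            nrow(moving) == nrow(fixed), nrow(moving) >= 1)
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  a <- sweep(moving, 2, cm)
  b <- sweep(fixed, 2, cf)
  h <- crossprod(a, b) # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  s <- diag(c(1, 1, d))
  rot <- sv$u %*% s %*% t(sv$v) # row-vector convention: x' = x %*% rot
  fitted <- a %*% rot
  trans <- cf - drop(cm %*% rot)
  rmsd <- sqrt(mean(rowSums((fitted - b)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 3 matrix.
#' @param transform list with `rotation` and `translation` as returned by
#'   [kabsch_fit()].
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  sweep(coords %*% transform$rotation, 2, transform$translation, `+`)
}

# plain coordinate RMSD, no fitting
coord_rmsd <- function(a, b) {
  sqrt(mean(rowSums((a - b)^2)))
}

# RMS deviation of points from their best-fit plane (ring planarity test)
plane_rms <- function(coords) {
  c0 <- sweep(coords, 2, colMeans(coords))
  sv <- svd(c0)
  # smallest singular value direction = plane normal
  sqrt(mean((c0 %*% sv$v[, 3])^2))
}

plane_normal <- function(coords) {
  c0 <- sweep(coords, 2, colMeans(coords))
  n <- svd(c0)$v[, 3]
  n / sqrt(sum(n^2))
}

# random rotation matrix from a seeded RNG stream (QR of gaussian matrix)
random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr_m <- qr(m)
  q <- qr.Q(qr_m)
  d <- diag(qr.R(qr_m))
  q <- q %*% diag(sign(d))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Round half away from zero
#'
#' Commercial rounding used for occurrence percentages, where R's
#' `round()` rounds half to even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
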