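# Rigid-body superposition, dihedral angles, and quasi-uniform sphere points.

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' paired coordinate sets, using the SVD of the cross-covariance matrix with a
#' reflection correction so that the returned rotation has determinant +1.
#'
#' @param mobile,reference Numeric matrices of equal dimension (n x 3), n >= 3.
#' @return A list with `rotation` (3 x 3, det +1), `translation` (length 3) such
#'   that `mobile %*% rotation + translation` is optimally aligned onto
#'   `reference`, and `rmsd` (Angstrom), the minimum attainable RMSD.
#' @examples
#' pts <- matrix(rnorm(30), 10, 3)
#' kabsch_superpose(pts, pts)$rmsd  # 0
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)) || ncol(mobile) != 3L)
    stop("mobile and reference must be n x 3 matrices of equal size")
  n <- nrow(mobile)
  if (n < 3L)
    stop("degenerate input: need at least 3 points for superposition")
  if (any(!is.finite(mobile)) || any(!is.finite(reference)))
    stop("coordinates must be finite")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  p <- sweep(mobile, 2, cm)
  q <- sweep(reference, 2, cr)
  # collinear (or coincident) point sets leave the rotation under-determined
  for (m in list(p, q)) {
    sv <- svd(m)$d
    if (sv[2] <= 1e-10 * max(sv[1], 1e-12))
      stop("degenerate input: points are collinear")
  }
  h <- crossprod(p, q)
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  aligned <- p %*% rot
  rmsd <- sqrt(mean(rowSums((aligned - q)^2)))
  list(rotation = rot, translation = as.numeric(cr - cm %*% rot), rmsd = rmsd)
}

#' Signed dihedral angle of four points
#'
#' Standard atan2 formulation; the angle is reported in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric length-3 vectors.
#' @return Dihedral angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  ga <- pi * (3 - sqrt(5))
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- ga * i
  cbind(x = r * cos(theta), y = r * sin(theta), z = z)
}

# Rodrigues rotation of points about an axis through `origin`.
rotate_about_axis <- function(points, origin, axis, angle_deg) {
  k <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  p <- sweep(as.matrix(points), 2, origin)
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  rot <- diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
  sweep(p %*% rot, 2, origin, "+")
}

# NeRF-style placement: position a new atom given three predecessors, a bond
# length, a bond angle (deg) at c, and a torsion (deg) about b-c.
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  bc <- (c - b) / sqrt(sum((c - b)^2))
  n <- cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  mat <- cbind(bc, m, n)
  as.numeric(c + mat %*% d2)
}
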