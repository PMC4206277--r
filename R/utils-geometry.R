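# small geometry helpers shared by annotation and generator code

.vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.vnorm <- function(a) sqrt(sum(a * a))

.unit <- function(a) {
  n <- .vnorm(a)
  if (n < 1e-12) stop("cannot normalise zero-length vector")
  a / n
}

#' Dihedral angle of four points
#'
#' Signed torsion angle in degrees (IUPAC convention) of the chain
#' p1-p2-p3-p4.
#'
#' @param p1,p2,p3,p4 numeric xyz vectors.
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .vcross(b1, b2)
  n2 <- .vcross(b2, b3)
  m1 <- .vcross(n1, .unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# place atom D given A-B-C, bond length |CD|, angle B-C-D (deg) and
# dihedral A-B-C-D (deg); natural extension reference frame
.nerf_place <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.vcross(b - a, bc))
  m <- .vcross(n, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph),
          -bond * sin(th) * sin(ph))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# ideal C-beta position from backbone N, CA, C (tetrahedral reconstruction)
.ideal_cb <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- .vcross(b, cc)
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
}

# deterministic, nearly uniform points on the unit sphere (golden spiral)
.sphere_points <- function(n) {
  k <- seq_len(n)
  z <- (2 * k - n - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- k * pi * (3 - sqrt(5))
  cbind(r * cos(th), r * sin(th), z)
}

# cross pairwise distances between row-sets of 3D coordinates
.cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
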