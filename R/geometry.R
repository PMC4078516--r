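# Low-level vector geometry shared by every module. Coordinates are in
# Angstrom, angles in degrees; torsions are reported in (-180, 180].

v_norm <- function(v) sqrt(sum(v * v))

v_unit <- function(v) {
  n <- v_norm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector", call. = FALSE)
  v / n
}

v_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Wrap angles into the canonical reporting range
#'
#' Maps any angle in degrees onto `(-180, 180]`, the range used for every
#' torsion reported by the package (grid phases stated on `[0, 360)` are
#' normalized through this function).
#'
#' @param x numeric vector of angles, degrees.
#' @return numeric vector of the same length, in `(-180, 180]`.
#' @export
#' @examples
#' wrap_angle(c(270, -180, 360, 95.6))
wrap_angle <- function(x) {
  y <- x %% 360
  ifelse(y > 180, y - 360, y)
}

#' Circular distance between two angles
#'
#' @param a,b angles in degrees (recycled).
#' @return absolute circular separation in `[0, 180]` degrees.
#' @export
circular_diff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

#' Signed torsion angle of four points
#'
#' Computes the dihedral a-b-c-d with the IUPAC sign convention: looking from
#' `b` towards `c`, the angle is positive when `d` is rotated clockwise from
#' `a`. The cis (eclipsed) arrangement is 0 degrees, trans is +180.
#'
#' @param a,b,c,d numeric 3-vectors, Angstrom.
#' @return torsion in degrees, in `(-180, 180]`.
#' @export
#' @examples
#' dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0))   # 0 (cis)
#' dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0))  # 180
dihedral_angle <- function(a, b, c, d) {
  b0 <- a - b
  b1 <- c - b
  b2 <- d - c
  n1 <- v_norm(b1)
  if (n1 < 1e-8) stop("undefined dihedral: axis atoms b and c coincide", call. = FALSE)
  b1 <- b1 / n1
  # colinearity guards: |sin| of the two flanking bond angles
  s0 <- v_norm(v_cross(b0, b1)) / max(v_norm(b0), 1e-12)
  s2 <- v_norm(v_cross(b2, b1)) / max(v_norm(b2), 1e-12)
  if (s0 < 1e-8 || s2 < 1e-8) {
    stop("undefined dihedral: colinear reference atoms", call. = FALSE)
  }
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(v_cross(b1, v) * w)
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Bond angle of three points
#'
#' @param p,q,r numeric 3-vectors; the angle has its vertex at `q`.
#' @return angle in degrees, `[0, 180]`.
#' @export
bond_angle <- function(p, q, r) {
  u <- v_unit(p - q)
  v <- v_unit(r - q)
  d <- max(-1, min(1, sum(u * v)))
  acos(d) * 180 / pi
}

# Rodrigues rotation of an n x 3 matrix of points about the axis through
# `origin` with unit direction `axis`, by `angle` degrees (right-hand rule).
rotate_points <- function(points, origin, axis, angle) {
  u <- v_unit(axis)
  th <- angle * pi / 180
  p <- sweep(points, 2L, origin)
  K <- matrix(c(0, u[3L], -u[2L], -u[3L], 0, u[1L], u[2L], -u[1L], 0), 3L, 3L)
  Rm <- diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(p %*% t(Rm), 2L, origin, "+")
}

# NeRF placement: position of atom X given reference atoms r1 (bonded), r2,
# r3, so that |X-r1| = bond, angle(X, r1, r2) = theta and
# dihedral_angle(X, r1, r2, r3) = tau.
nerf_place <- function(r1, r2, r3, bond, theta, tau) {
  bc <- v_unit(r1 - r2)
  n <- v_cross(r2 - r3, bc)
  if (v_norm(n) < 1e-10) {
    stop("degenerate reference frame: colinear reference atoms", call. = FALSE)
  }
  n <- n / v_norm(n)
  m <- v_cross(n, bc)
  th <- theta * pi / 180
  ph <- tau * pi / 180
  r1 + bond * (-cos(th) * bc + sin(th) * cos(ph) * m + sin(th) * sin(ph) * n)
}
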