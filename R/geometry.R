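## Basic vector geometry used throughout. All angles are in degrees unless
## a function name says otherwise; coordinates are in Angstrom.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("g4conform geometry error: cannot normalise a zero vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## wrap an angle in degrees to [0, 360)
wrap360 <- function(x) ((x %% 360) + 360) %% 360

## wrap to (-180, 180]
wrap180 <- function(x) {
  y <- wrap360(x)
  ifelse(y > 180, y - 360, y)
}

## smallest absolute angular difference, degrees
angdiff <- function(a, b) abs(wrap180(a - b))

#' Dihedral (torsion) angle of four points
#'
#' Computes the torsion angle about the p2-p3 bond with the IUPAC sign
#' convention (clockwise rotation of p4 relative to p1 when viewed from p2
#' towards p3 is positive) and reports it on `[0, 360)`.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees on `[0, 360)`.
#' @examples
#' dihedral(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1), c(1, 1, 1)) # cis -> 0
#' @export
dihedral <- function(p1, p2, p3, p4) {
  wrap360(dihedral_signed(p1, p2, p3, p4))
}

## Signed torsion on (-180, 180], IUPAC convention.
dihedral_signed <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9)
    stop("g4conform geometry error: coincident consecutive points in dihedral")
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("g4conform geometry error: collinear points in dihedral")
  ## atan2 form: robust, no acos clipping
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * vunit(b2))
  rad2deg(atan2(y, x))
}

#' Bond angle of three points
#' @param a,b,c Numeric 3-vectors; the angle is measured at `b`.
#' @return Angle in degrees on `[0, 180]`.
#' @export
bond_angle <- function(a, b, c) {
  u <- vunit(a - b)
  v <- vunit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

## Place an atom from internal coordinates (NeRF construction): the new
## atom X is bonded to p3 with the given bond length, makes angle
## p2-p3-X and torsion p1-p2-p3-X (degrees).
place_atom <- function(p1, p2, p3, length, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  d <- c(-length * cos(ang),
         length * sin(ang) * cos(tor),
         length * sin(ang) * sin(tor))
  bc <- vunit(p3 - p2)
  n <- vunit(vcross(p2 - p1, bc))
  m <- vcross(n, bc)  ## bc, m, n orthonormal
  p3 + d[1] * bc + d[2] * m + d[3] * n
}

## Random proper rotation matrix (uses the current RNG stream).
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- vnorm(q)
    if (n > 1e-6) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

## Apply rigid motion to an n x 3 coordinate matrix.
apply_rigid <- function(xyz, rot, trans = c(0, 0, 0)) {
  sweep(xyz %*% t(rot), 2, -trans)
}

## Circular mean of angles in degrees, result on [0, 360).
circular_mean <- function(deg) {
  deg <- deg[is.finite(deg)]
  if (!length(deg)) return(NA_real_)
  wrap360(rad2deg(atan2(mean(sin(deg2rad(deg))), mean(cos(deg2rad(deg))))))
}
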