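# Small vector-geometry helpers shared across modules. Coordinates are plain
# numeric length-3 vectors or n x 3 matrices, units Angstrom throughout.

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Signed dihedral angle of four points
#'
#' Returns the torsion angle a-b-c-d in degrees in (-180, 180], following the
#' right-handed IUPAC sign convention (cis = 0, trans = 180).
#'
#' @param a,b,c,d numeric length-3 coordinate vectors (Angstrom).
#' @return numeric scalar, degrees.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  if (vnorm(vcross(b1, b2)) < 1e-9 || vnorm(vcross(b2, b3)) < 1e-9)
    stop("undefined dihedral: three of the four points are collinear")
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

# Angle at vertex b (degrees).
point_angle <- function(a, b, c) {
  u <- vunit(a - b)
  v <- vunit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

# Place atom D given three prior atoms so that |D-c| = bond,
# angle(b, c, D) = angle (deg) and torsion(a, b, c, D) = torsion (deg).
# Standard internal-to-Cartesian (NeRF) construction.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Least-squares plane through rows of an n x 3 matrix. Returns list(center,
# normal) with unit normal; orientation of the normal is arbitrary.
fit_plane <- function(xyz) {
  if (nrow(xyz) < 3) stop("need at least 3 points to fit a plane")
  ctr <- colMeans(xyz)
  s <- svd(sweep(xyz, 2, ctr))
  list(center = ctr, normal = s$v[, 3])
}

# Random rigid transform (rotation + translation) used by property tests.
random_rigid_transform <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
  list(R = R, t = stats::rnorm(3, sd = 10))
}

# Apply a rigid transform to an n x 3 coordinate matrix.
apply_rigid <- function(xyz, R, t) {
  sweep(xyz %*% t(R), 2, t, `+`)
}
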