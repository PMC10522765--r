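# Small 3D geometry helpers shared by the helical-geometry module and the
# synthetic builders.  Angles are degrees externally, radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation about an arbitrary unit axis (Rodrigues), angle in degrees.
rot_axis <- function(axis, angle_deg) {
  u <- unit3(axis)
  th <- deg2rad(angle_deg)
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  ct * diag(3) + st * ux + (1 - ct) * outer(u, u)
}

rot_z <- function(angle_deg) rot_axis(c(0, 0, 1), angle_deg)
rot_y <- function(angle_deg) rot_axis(c(0, 1, 0), angle_deg)
rot_x <- function(angle_deg) rot_axis(c(1, 0, 0), angle_deg)

# Signed angle (deg) from a to b about unit axis n, in (-180, 180].
signed_angle <- function(a, b, n) {
  n <- unit3(n)
  a <- a - sum(a * n) * n
  b <- b - sum(b * n) * n
  ang <- atan2(sum(cross3(a, b) * n), sum(a * b))
  rad2deg(ang)
}

#' Signed dihedral angle of four points
#'
#' Standard convention: looking along the B-C bond, the angle from the A-B-C
#' plane to the B-C-D plane, positive clockwise, in (-180, 180].  Cis = 0,
#' trans = 180.
#'
#' @param a,b,c,d Numeric length-3 coordinates.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

# NeRF-style atom placement: position atom D bonded to C with bond length,
# angle B-C-D (deg) and dihedral A-B-C-D (deg).
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- deg2rad(angle_deg)
  ph <- -deg2rad(torsion_deg)
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d_local <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# Circular mean and SD (degrees) for angular series.
circular_mean <- function(x_deg) {
  x <- deg2rad(x_deg[!is.na(x_deg)])
  if (length(x) == 0) return(NA_real_)
  rad2deg(atan2(mean(sin(x)), mean(cos(x))))
}

circular_sd <- function(x_deg) {
  x <- deg2rad(x_deg[!is.na(x_deg)])
  if (length(x) == 0) return(NA_real_)
  R <- sqrt(mean(sin(x))^2 + mean(cos(x))^2)
  R <- min(max(R, 1e-12), 1)
  rad2deg(sqrt(-2 * log(R)))
}
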