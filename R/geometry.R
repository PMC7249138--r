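# Low-level 3D geometry: torsions, internal-to-Cartesian placement,
# rotations. Coordinates are plain numeric length-3 vectors in Angstrom.

#' @keywords internal
vnorm <- function(v) sqrt(sum(v * v))

#' @keywords internal
unit <- function(v) v / vnorm(v)

#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle of four points
#'
#' IUPAC sign convention: looking from `b` to `c`, the angle is positive
#' when the far bond rotates clockwise from the near bond.
#'
#' @param a,b,c,d Numeric xyz vectors (Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(unit(b2), n1)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

#' @keywords internal
bond_angle <- function(a, b, c) {
  v1 <- unit(a - b); v2 <- unit(c - b)
  acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
}

# NeRF placement: position atom D given the three preceding reference
# atoms A-B-C, the bond length C-D, the bond angle B-C-D and the torsion
# A-B-C-D. Inverse of dihedral_angle/bond_angle by construction.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  theta <- angle_deg * pi / 180
  chi <- torsion_deg * pi / 180
  d2 <- bond * c(-cos(theta), sin(theta) * cos(chi), sin(theta) * sin(chi))
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  M <- cbind(bc, cross3(n, bc), n)
  as.numeric(c + M %*% d2)
}

# Preserve the caller's RNG state while running seeded generator code.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Uniform random rotation matrix (quaternion method).
#' @keywords internal
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# Rotation taking unit vector `from` onto unit vector `to`.
#' @keywords internal
rotation_between <- function(from, to) {
  f <- unit(from); t <- unit(to)
  v <- cross3(f, t)
  cth <- sum(f * t)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) {
    # pick any axis perpendicular to f
    axis <- unit(cross3(f, if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    K <- matrix(c(0, -axis[3], axis[2],
                  axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, -v[3], v[2],
                v[3], 0, -v[1],
                -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * (1 / (1 + cth))
}
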