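# Small 3D geometry kernel shared by hydrogen placement, secondary-structure
# assignment and the toy-structure generator.  All lengths in Angstrom,
# all angles in degrees.

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Angle at a vertex
#'
#' Angle in degrees between the rays `v -> a` and `v -> b`.
#'
#' @param a,v,b numeric 3-vectors; `v` is the vertex.
#' @return angle in degrees in \[0, 180\].
#' @keywords internal
vertex_angle <- function(a, v, b) {
  u1 <- unit_vec(a - v)
  u2 <- unit_vec(b - v)
  d <- sum(u1 * u2)
  d <- max(-1, min(1, d))
  acos(d) * 180 / pi
}

dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit_vec(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

#' Place an atom from internal coordinates
#'
#' Standard Z-matrix (NeRF) construction: returns the position `d` such
#' that |c-d| = `bond`, the angle b-c-d equals `angle` and the dihedral
#' a-b-c-d equals `dihedral`.
#'
#' @param a,b,c numeric 3-vectors of the three reference atoms.
#' @param bond bond length c-d, Angstrom.
#' @param angle angle b-c-d, degrees.
#' @param dihedral torsion a-b-c-d, degrees.
#' @return numeric 3-vector.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unit_vec(c - b)
  n <- unit_vec(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# Any unit vector perpendicular to u.
perp_vec <- function(u) {
  ref <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit_vec(cross3(u, ref))
}
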