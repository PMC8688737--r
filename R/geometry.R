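# Rigid-body geometry: tetrahedron construction, quaternions, minimum-image
# separations and the tetrahedron-tetrahedron overlap test.

#' Body-frame vertices of a regular tetrahedron
#'
#' The tetrahedron is realised as alternating corners of the cube
#' \eqn{[-a, a]^3} with \eqn{a = \sqrt{3}/6 \cdot \sigma}, so that the
#' circumscribed sphere has diameter `sigma` and the centroid sits at the
#' origin.
#'
#' @param sigma Diameter of the circumscribed sphere (the length unit of the
#'   hard-tetrahedron model).
#' @return A 4 x 3 numeric matrix of vertex coordinates.
#' @export
#' @examples
#' v <- tetra_vertices(1)
#' sqrt(rowSums(v^2))  # all 0.5: vertices on the circumsphere
tetra_vertices <- function(sigma = 1) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (sigma <= 0) stop("sigma must be positive")
  a <- sqrt(3) / 6 * sigma
  matrix(a * c(
    +1, +1, +1,
    +1, -1, -1,
    -1, +1, -1,
    -1, -1, +1
  ), nrow = 4, byrow = TRUE)
}

#' Volume of a regular tetrahedron
#'
#' @inheritParams tetra_vertices
#' @return \eqn{(\sqrt{3}/27)\,\sigma^3}.
#' @export
tetra_volume <- function(sigma = 1) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (sigma <= 0) stop("sigma must be positive")
  sqrt(3) / 27 * sigma^3
}

#' Convex-body shape factor of the regular tetrahedron
#'
#' Nonsphericity parameter \eqn{\alpha = R S / (3V)} built from the mean
#' curvature radius \eqn{R = 3h(\pi - \arccos(1/3))/(4\pi)}, the surface area
#' \eqn{S = \sqrt{3} h^2} and the volume \eqn{V = h^3/(6\sqrt{2})} of a
#' regular tetrahedron with edge length \eqn{h}.  The value is scale
#' invariant; a sphere has \eqn{\alpha = 1}.
#'
#' @param h Edge length (any positive value; the result does not depend on it).
#' @return The dimensionless shape factor, about 2.2346.
#' @export
tetra_shape_factor <- function(h = 1) {
  stopifnot(h > 0)
  R <- 3 * h * (pi - acos(1 / 3)) / (4 * pi)
  S <- sqrt(3) * h^2
  V <- h^3 / (6 * sqrt(2))
  R * S / (3 * V)
}

#' Hard-tetrahedron model geometry
#'
#' Bundles the body-frame vertices, the dipole axis and the characteristic
#' distances of the hard-tetrahedron fluid.  The dipole axis points from the
#' center to the midpoint of the edge joining vertices 1 and 2 (the "charged"
#' edge); with the vertex convention used here that is the +x direction.
#' Vertices 1 and 2 are the charged-edge ends ("V1" sites), vertices 3 and 4
#' the remaining ones ("V3" sites).
#'
#' @param sigma Circumsphere diameter (length unit, default 1).
#' @return An object of class `ht_geometry`.
#' @export
ht_geometry <- function(sigma = 1) {
  v <- tetra_vertices(sigma)
  axis <- (v[1, ] + v[2, ]) / 2
  axis <- axis / sqrt(sum(axis^2))
  structure(list(
    sigma = sigma,
    body_vertices = v,
    body_dipole_axis = axis,
    insphere_contact = sigma / 3
  ), class = "ht_geometry")
}

#' Primitive-model geometry (TIP4P-descended)
#'
#' Hard sphere of diameter `sigma` (the length unit) with two positive
#' H-like sites `P1`, `P2` on the sphere surface along the parent-model O-H
#' directions, and one negative M-like site `N` on their bisector a short
#' distance from the center.  Unlike sites (P-N) attract through a square
#' well of range `r_sw`; like sites (P-P, N-N) repel as hard spheres of
#' diameters `d_pp`, `d_nn`.  The dipole axis is the O-to-N (bisector)
#' direction, here +z.
#'
#' The parent TIP4P geometry fixes the H-O-H angle (104.52 degrees) and the
#' M-site offset (0.15 Angstrom on a 2.653 Angstrom sphere).  The site
#' diameters and well range are not fixed by the parent geometry; the
#' defaults below are package choices (see the methods vignette) and can be
#' overridden here or in a run configuration.
#'
#' @param sigma Hard-sphere diameter in reduced units (default 1).
#' @param hoh_angle_deg Angle subtended by the two P-site directions, degrees.
#' @param n_offset Distance of the N site from the center, sigma units.
#' @param d_pp,d_nn Hard-core diameters for like-site pairs, sigma units.
#' @param r_sw Square-well range for unlike (P-N) site pairs, sigma units;
#'   must be below `sigma` so that bonding requires near-contact molecules.
#' @return An object of class `pm_geometry` with a `body_sites` matrix whose
#'   rows are O, P1, P2, N.
#' @export
pm_geometry <- function(sigma = 1, hoh_angle_deg = 104.52,
                        n_offset = 0.15 / 2.653,
                        d_pp = 0.45, d_nn = 0.45, r_sw = 0.55) {
  stopifnot(sigma > 0, d_pp > 0, d_nn > 0, r_sw > 0, n_offset > 0)
  if (r_sw >= sigma) {
    stop("r_sw must be smaller than sigma (bonding only near contact)")
  }
  th <- hoh_angle_deg * pi / 180 / 2
  sites <- rbind(
    O  = c(0, 0, 0),
    P1 = sigma / 2 * c(sin(th), 0, cos(th)),
    P2 = sigma / 2 * c(-sin(th), 0, cos(th)),
    N  = c(0, 0, n_offset * sigma)
  )
  structure(list(
    sigma_OO = sigma,
    body_sites = sites,
    body_dipole_axis = c(0, 0, 1),
    hoh_angle_deg = hoh_angle_deg,
    n_offset = n_offset,
    d_pp = d_pp, d_nn = d_nn, r_sw = r_sw
  ), class = "pm_geometry")
}

#' Rigid-body pose
#'
#' @param r Center position (length-3 numeric).
#' @param q Orientation as a unit quaternion `(w, x, y, z)`; normalised on
#'   construction.  Default: identity.
#' @return An object of class `pose`.
#' @export
pose <- function(r = c(0, 0, 0), q = c(1, 0, 0, 0)) {
  stopifnot(length(r) == 3L, length(q) == 4L, all(is.finite(r)),
            all(is.finite(q)))
  n <- sqrt(sum(q^2))
  if (n < 1e-8) stop("quaternion norm too small")
  structure(list(r = as.numeric(r), q = as.numeric(q) / n), class = "pose")
}

#' Quaternion from rotation axis and angle
#'
#' @param axis Rotation axis (normalised internally).
#' @param angle Rotation angle in radians.
#' @return Unit quaternion `(w, x, y, z)`.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Uniform random unit quaternions
#'
#' Marsaglia-style draw from the uniform (Haar) distribution on SO(3),
#' using R's random number stream.
#'
#' @param n Number of quaternions.
#' @return An `n x 4` matrix of unit quaternions.
#' @export
quat_random <- function(n = 1) {
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
  cbind(
    sqrt(1 - u1) * sin(2 * pi * u2),
    sqrt(1 - u1) * cos(2 * pi * u2),
    sqrt(u1) * sin(2 * pi * u3),
    sqrt(u1) * cos(2 * pi * u3)
  )
}

#' Rotate vectors by a unit quaternion
#'
#' @param q Unit quaternion `(w, x, y, z)`.
#' @param v A length-3 vector or an `n x 3` matrix of row vectors.
#' @return Rotated vector(s), same shape as `v`.
#' @export
quat_rotate <- function(q, v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L, ncol = 3L)
  w <- q[1]; qv <- q[2:4]
  t_ <- 2 * t(apply(v, 1L, function(x) pracma_cross(qv, x)))
  out <- v + w * t_ + t(apply(t_, 1L, function(x) pracma_cross(qv, x)))
  if (nrow(out) == 1L) out[1L, ] else out
}

# plain cross product (avoids pulling in a package for one primitive)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Lab-frame interaction sites of a primitive-model molecule
#'
#' Rotates the body-frame sites (O, P1, P2, N and, if `l0 > 0`, the two
#' dipole charge sites `QP`, `QM` at \eqn{\pm l_0/2} along the dipole axis)
#' into the lab frame and translates them to the molecule center.
#'
#' @param p A [pose()].
#' @param geom A [pm_geometry()].
#' @param l0 Charge separation for the two-charge dipole representation
#'   (sigma units); 0 omits the charge rows.
#' @return Matrix of lab-frame site coordinates with named rows.
#' @export
pm_sites <- function(p, geom, l0 = 0) {
  stopifnot(inherits(p, "pose"), inherits(geom, "pm_geometry"))
  body <- geom$body_sites
  if (l0 > 0) {
    body <- rbind(body,
                  QP = geom$body_dipole_axis * (+l0 / 2),
                  QM = geom$body_dipole_axis * (-l0 / 2))
  }
  lab <- quat_rotate(p$q, body)
  lab <- sweep(lab, 2L, p$r, "+")
  rownames(lab) <- rownames(body)
  lab
}

#' Minimum-image separation vector
#'
#' Separation `b - a` wrapped into the primary periodic image of a cubic box,
#' each component in `(-box/2, box/2]`.
#'
#' @param a,b Length-3 position vectors.
#' @param box Cubic box edge length.
#' @return Length-3 separation vector.
#' @export
minimum_image <- function(a, b, box) {
  stopifnot(box > 0)
  d <- b - a
  d <- d - box * round(d / box)
  d[d <= -box / 2] <- d[d <= -box / 2] + box
  d
}

#' Tetrahedron-tetrahedron overlap test
#'
#' Decides whether two solid regular tetrahedra intersect, using the
#' center-separation bounds (always overlapping below the insphere-contact
#' distance \eqn{\sigma/3}, never above \eqn{\sigma}) and, in between, a
#' separating-axis test over the 8 face normals and 36 edge-edge cross
#' products.  Degenerate (near-zero) cross-product axes are skipped.
#'
#' @param pose_a,pose_b [pose()] objects.
#' @param geom A [ht_geometry()].
#' @param box Cubic box edge for the minimum-image convention; `Inf` for an
#'   open system.
#' @return `TRUE` if the bodies overlap.
#' @export
sat_overlap <- function(pose_a, pose_b, geom = ht_geometry(), box = Inf) {
  stopifnot(inherits(pose_a, "pose"), inherits(pose_b, "pose"),
            inherits(geom, "ht_geometry"))
  d <- if (is.finite(box)) minimum_image(pose_a$r, pose_b$r, box) else
    pose_b$r - pose_a$r
  dn <- sqrt(sum(d^2))
  if (dn < geom$sigma / 3) return(TRUE)
  if (dn > geom$sigma) return(FALSE)
  cpp_sat_overlap(pose_a$r, pose_a$q, pose_a$r + d, pose_b$q,
                  geom$body_vertices, -1)
}
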