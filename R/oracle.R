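# Slow reference method for tetrahedron overlap: dense point sampling with
# half-space containment checks.  Deliberately independent of the
# separating-axis implementation; used for validation.

#' Tetrahedron overlap by point-containment sampling
#'
#' Reference implementation of the overlap test: a barycentric grid of
#' points filling tetrahedron A is tested for containment in tetrahedron B
#' via the four half-space inequalities of B's faces, and vice versa.  It
#' can only miss intersections thinner than the grid resolution, and never
#' reports a false overlap (interior containment is checked strictly).
#'
#' @param pose_a,pose_b [pose()] objects.
#' @param geom A [ht_geometry()].
#' @param box Periodic box edge (`Inf` for open space).
#' @param resolution Barycentric subdivisions per edge; the grid has
#'   `choose(resolution + 3, 3)` points.
#' @return `TRUE` if a grid point of either body lies strictly inside the
#'   other.
#' @export
tetra_overlap_sampling <- function(pose_a, pose_b, geom = ht_geometry(),
                                   box = Inf, resolution = 12L) {
  d <- if (is.finite(box)) minimum_image(pose_a$r, pose_b$r, box) else
    pose_b$r - pose_a$r
  va <- quat_rotate(pose_a$q, geom$body_vertices)
  vb <- sweep(quat_rotate(pose_b$q, geom$body_vertices), 2L, d, "+")
  pts_a <- barycentric_grid(va, resolution)
  pts_b <- barycentric_grid(vb, resolution)
  any(points_in_tetra(pts_a, vb)) || any(points_in_tetra(pts_b, va))
}

# all points (i v1 + j v2 + k v3 + l v4)/n with i+j+k+l = n
barycentric_grid <- function(verts, n) {
  idx <- expand.grid(i = 0:n, j = 0:n, k = 0:n)
  idx <- idx[idx$i + idx$j + idx$k <= n, , drop = FALSE]
  l <- n - idx$i - idx$j - idx$k
  w <- cbind(idx$i, idx$j, idx$k, l) / n
  w %*% verts
}

# strict containment via same-side-as-opposite-vertex tests on all 4 faces
points_in_tetra <- function(pts, verts) {
  inside <- rep(TRUE, nrow(pts))
  faces <- list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  opp <- c(4, 3, 2, 1)
  for (f in seq_along(faces)) {
    v <- verts[faces[[f]], , drop = FALSE]
    nrm <- pracma_cross(v[2, ] - v[1, ], v[3, ] - v[1, ])
    d0 <- sum(nrm * v[1, ])
    s_opp <- sum(nrm * verts[opp[f], ]) - d0
    s_pts <- pts %*% nrm - d0
    inside <- inside & (s_pts * s_opp > 0)
    if (!any(inside)) break
  }
  inside
}
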