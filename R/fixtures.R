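# Deterministic micro-fixtures: tiny hand-constructed two-body cases whose
# expected values are computed at generation time by the slow reference
# routes (point-containment sampling, closed forms, site-geometry
# construction), each carrying a provenance tag.

#' Generate the worked micro-fixtures used across the test suite
#'
#' Produces named two-body cases: tetrahedron pairs at center separations
#' 0.30 (inside the insphere-contact bound), 0.50 (verdict from the
#' point-containment oracle) and 1.01 (beyond the circumsphere), a bonded
#' primitive-model dimer with exactly one P-N square-well contact, and an
#' aligned point-dipole pair.  Expected values are computed by the reference
#' routes at generation time, never by the production code paths.
#'
#' @param seed Integer seed; the fixture set is a pure function of it.
#' @return An object of class `fixture_set`: a named list of fixtures, each
#'   with `poses` (or vectors), `expected`, and a `provenance` tag.
#' @export
generate_fixtures <- function(seed = 1L) {
  set.seed(seed)
  geom_ht <- ht_geometry()
  fx <- list()

  q1 <- quat_random(1)[1L, ]
  q2 <- quat_random(1)[1L, ]
  fx$tetra_R030 <- list(
    poses = list(pose(c(0, 0, 0), q1), pose(c(0.30, 0, 0), q2)),
    expected = TRUE,
    provenance = "insphere-contact bound: centers closer than sigma/3 always overlap")

  q3 <- quat_random(1)[1L, ]
  q4 <- quat_random(1)[1L, ]
  p50 <- list(pose(c(0, 0, 0), q3), pose(c(0.50, 0, 0), q4))
  fx$tetra_R050 <- list(
    poses = p50,
    expected = tetra_overlap_sampling(p50[[1L]], p50[[2L]], geom_ht,
                                      resolution = 16L),
    provenance = "point-containment sampling oracle, resolution 16")

  fx$tetra_R101 <- list(
    poses = list(pose(c(0, 0, 0), quat_random(1)[1L, ]),
                 pose(c(1.01, 0, 0), quat_random(1)[1L, ])),
    expected = FALSE,
    provenance = "circumsphere bound: centers beyond sigma never overlap")

  # bonded PM dimer: rejection-sample an acceptor orientation giving exactly
  # one P-N contact and no hard overlap at near-contact center separation
  geom_pm <- pm_geometry()
  state <- thermo_state(beta_eps = 8, eta = 0.3, n = 2)
  pa <- pose(c(0, 0, 0), quat_from_axis_angle(c(0, 1, 0),
                                              -geom_pm$hoh_angle_deg / 2 * pi / 180))
  dimer <- NULL
  for (i in 1:10000) {
    pb <- pose(c(0, 0, 1.02), quat_random(1)[1L, ])
    e <- pm_pair_energy(pm_sites(pa, geom_pm), pm_sites(pb, geom_pm),
                        geom_pm, state)
    if (is.finite(e) && e == -state$beta_eps) { dimer <- pb; break }
  }
  if (is.null(dimer)) stop("fixture generation failed to find a bonded dimer")
  fx$pm_dimer_bonded <- list(
    poses = list(pa, dimer),
    beta_eps = state$beta_eps,
    expected = -state$beta_eps,
    provenance = "square-well depth: exactly one unlike-site pair inside the well")

  fx$dd_aligned <- list(
    e1 = c(0, 0, 1), e2 = c(0, 0, 1), r12 = c(0, 0, 1), lambda = 1,
    expected = -2,
    provenance = "closed form: head-to-tail point dipoles, -2 lambda / R^3")

  structure(fx, class = "fixture_set")
}

#' Write a fixture set as plain text
#'
#' One block per fixture with its poses, expected value and provenance tag.
#'
#' @param fx A [generate_fixtures()] result.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_fixtures <- function(fx, path) {
  lines <- character()
  for (nm in names(fx)) {
    f <- fx[[nm]]
    lines <- c(lines, sprintf("[%s]", nm))
    if (!is.null(f$poses)) {
      for (k in seq_along(f$poses)) {
        p <- f$poses[[k]]
        lines <- c(lines,
                   sprintf("pose%d = %s | %s", k,
                           paste(fmt(p$r), collapse = " "),
                           paste(fmt(p$q), collapse = " ")))
      }
    }
    for (key in setdiff(names(f), c("poses", "expected", "provenance"))) {
      lines <- c(lines, sprintf("%s = %s", key,
                                paste(fmt(as.numeric(f[[key]])), collapse = " ")))
    }
    lines <- c(lines, sprintf("expected = %s", format(f$expected)),
               sprintf("provenance = %s", f$provenance), "")
  }
  writeLines(lines, path)
  invisible(path)
}
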