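# Pair-energy terms: square-well bonding, point and two-charge dipoles with
# reaction field, the short-range screening switch, and their composition
# into the total reduced pair energy.  Energies are beta*u throughout; a hard
# overlap is reported as +Inf.

#' Cubic smoothstep switch function
#'
#' \eqn{S = 0} below `r_lo`, 1 above `r_hi`, and the cubic
#' \eqn{(r - R')^2 (3R'' - R' - 2r)/(R'' - R')^3} in between, which is
#' continuous with a continuous first derivative at both bounds.  Used to
#' screen the dipole-dipole interaction at short range.
#'
#' @param r Distance(s), sigma units.
#' @param r_lo,r_hi Lower and upper switch bounds, `r_lo < r_hi`.
#' @return Value(s) in `[0, 1]`.
#' @export
switch_function <- function(r, r_lo, r_hi) {
  if (!(r_lo < r_hi)) stop("r_lo must be smaller than r_hi")
  w <- r_hi - r_lo
  s <- (r - r_lo)^2 * (3 * r_hi - r_lo - 2 * r) / w^3
  s[r <= r_lo] <- 0
  s[r >= r_hi] <- 1
  s
}

#' Dipole interaction specification
#'
#' @param lambda Reduced dipole strength \eqn{\lambda = \mu^2/(k_B T
#'   \sigma^3)} (dimensionless).
#' @param mode One of `"none"`, `"screened"`, `"full"`.  With `"screened"`
#'   the dipole-dipole energy is multiplied by
#'   [switch_function()] of the center-center distance; with `"full"` it acts
#'   over the whole range up to the cutoff; `"none"` switches it off and
#'   ignores `lambda`.
#' @param l0 Charge separation of the two-charge dipole representation,
#'   sigma units (small compared to 1).
#' @param r_lo,r_hi Switch bounds, sigma units.  Defaults correspond to the
#'   4--6 Angstrom screening window on a 2.653 Angstrom core.
#' @param r_c Reaction-field cutoff, sigma units; `NULL` means "half the box
#'   edge", resolved when a run is set up.
#' @param eps_r Dielectric constant of the reaction-field continuum; `Inf`
#'   (the default) gives the conducting-boundary coefficient 1/2.
#' @return An object of class `dipole_spec`.
#' @export
dipole_spec <- function(lambda = 0, mode = c("none", "screened", "full"),
                        l0 = 0.01, r_lo = 4 / 2.653, r_hi = 6 / 2.653,
                        r_c = NULL, eps_r = Inf) {
  mode <- match.arg(mode)
  stopifnot(lambda >= 0, l0 > 0, l0 < 1)
  if (!(r_lo < r_hi)) stop("r_lo must be smaller than r_hi")
  # in small boxes the cutoff can sit inside the switch ramp; the screened
  # interaction is then simply truncated before the switch saturates, but a
  # cutoff at or below the lower bound would make it identically zero
  if (!is.null(r_c) && mode == "screened" && r_c <= r_lo) {
    stop("r_c at or below r_lo: the screened interaction would vanish")
  }
  structure(list(lambda = lambda, mode = mode, l0 = l0,
                 r_lo = r_lo, r_hi = r_hi, r_c = r_c, eps_r = eps_r),
            class = "dipole_spec")
}

#' Thermodynamic state of a run
#'
#' @param beta_eps Reduced square-well depth \eqn{\beta\epsilon_{HB}}
#'   (primitive model only; 0 otherwise).
#' @param eta Packing fraction, in (0, 0.74).
#' @param n Particle count, at least 2.
#' @return An object of class `thermo_state`.
#' @export
thermo_state <- function(beta_eps = 0, eta = 0.35, n = 216) {
  stopifnot(beta_eps >= 0)
  if (!(eta > 0 && eta < 0.74)) stop("eta must lie in (0, 0.74)")
  if (n < 2) stop("need at least 2 particles")
  structure(list(beta_eps = beta_eps, eta = eta, n = as.integer(n)),
            class = "thermo_state")
}

#' Primitive-model reference pair energy from lab-frame sites
#'
#' Hard-core checks on the O-O distance and on like-site pairs (P-P, N-N),
#' plus a square-well count over unlike (P-N) pairs: the reduced energy is
#' \eqn{-\beta\epsilon_{HB}} per P-N pair closer than the well range.
#'
#' @param sites_a,sites_b Site matrices from [pm_sites()].
#' @param geom A [pm_geometry()].
#' @param state A [thermo_state()] supplying `beta_eps`.
#' @param box Periodic box edge for minimum-image distances; `Inf` for an
#'   open pair.
#' @return Reduced energy (a non-positive multiple of `beta_eps`), or `Inf`
#'   on hard overlap.
#' @export
pm_pair_energy <- function(sites_a, sites_b, geom, state, box = Inf) {
  dist_ab <- function(i, j) {
    d <- sites_b[j, ] - sites_a[i, ]
    if (is.finite(box)) d <- d - box * round(d / box)
    sqrt(sum(d^2))
  }
  if (dist_ab("O", "O") < geom$sigma_OO) return(Inf)
  for (i in c("P1", "P2")) for (j in c("P1", "P2")) {
    if (dist_ab(i, j) < geom$d_pp) return(Inf)
  }
  if (dist_ab("N", "N") < geom$d_nn) return(Inf)
  nb <- 0L
  for (i in c("P1", "P2")) if (dist_ab(i, "N") < geom$r_sw) nb <- nb + 1L
  for (j in c("P1", "P2")) if (dist_ab("N", j) < geom$r_sw) nb <- nb + 1L
  -state$beta_eps * nb
}

#' Point dipole-dipole energy
#'
#' Reduced energy of two point dipoles in the standard convention,
#' \eqn{\beta u = -(\lambda/R^3)\,[3(\hat e_1\cdot\hat R)(\hat e_2\cdot\hat R)
#' - \hat e_1\cdot\hat e_2]}, attractive (\eqn{-2\lambda/R^3}) for the
#' head-to-tail aligned pair.
#'
#' @param e1,e2 Unit dipole direction vectors.
#' @param r12 Center separation vector (not normalised).
#' @param lambda Reduced dipole strength.
#' @return Reduced energy.
#' @export
dd_point_energy <- function(e1, e2, r12, lambda) {
  rn <- sqrt(sum(r12^2))
  if (rn == 0) stop("zero separation")
  rh <- r12 / rn
  -lambda / rn^3 * (3 * sum(e1 * rh) * sum(e2 * rh) - sum(e1 * e2))
}

#' Two-charge dipole-dipole energy with reaction field
#'
#' Reduced electrostatic energy of two molecules each carrying unit charges
#' \eqn{\pm 1} a distance \eqn{l_0} apart:
#' \deqn{\beta u = \epsilon \sum_{i,j} q_i q_j \left[\frac{1}{r_{ij}} +
#'   \frac{\varepsilon_r - 1}{2\varepsilon_r + 1}\,
#'   \frac{r_{ij}^2}{r_c^3}\right]}
#' for center separations up to the cutoff \eqn{r_c}, zero beyond, with
#' \eqn{\epsilon = \lambda/l_0^2}.  With \eqn{\varepsilon_r = \infty} the
#' reaction-field coefficient is exactly 1/2.
#'
#' @param charges_a,charges_b 2 x 3 matrices of lab-frame charge positions,
#'   first row the +1 charge, second row the -1 charge.
#' @param spec A [dipole_spec()]; its `r_c` must be set.
#' @return Reduced energy.
#' @export
dd_charges_rf_energy <- function(charges_a, charges_b, spec) {
  r_c <- spec$r_c
  if (is.null(r_c)) stop("dipole_spec has no cutoff r_c set")
  ca <- colMeans(charges_a)
  cb <- colMeans(charges_b)
  if (sqrt(sum((cb - ca)^2)) > r_c) return(0)
  coef <- if (is.infinite(spec$eps_r)) 0.5 else
    (spec$eps_r - 1) / (2 * spec$eps_r + 1)
  epsq <- spec$lambda / spec$l0^2
  qs <- c(1, -1)
  e <- 0
  for (i in 1:2) for (j in 1:2) {
    r <- sqrt(sum((charges_b[j, ] - charges_a[i, ])^2))
    if (r == 0) stop("coincident charge sites on different molecules")
    e <- e + qs[i] * qs[j] * (1 / r + coef * r^2 / r_c^3)
  }
  epsq * e
}

#' Reduced dipole strength from physical parameters
#'
#' \eqn{\lambda = \mu^2 / (4\pi\varepsilon_0 k_B T \sigma^3)} evaluated in
#' SI units (equivalently \eqn{\mu^2/(k_B T \sigma^3)} in the Gaussian
#' convention).
#'
#' @param mu_debye Dipole moment in debye.
#' @param T_kelvin Temperature in kelvin.
#' @param sigma_angstrom Molecular diameter in Angstrom.
#' @return Dimensionless reduced dipole strength.
#' @export
#' @examples
#' lambda_from_physical(1.85, 298, 3)  # about 3 for the gas-phase moment
lambda_from_physical <- function(mu_debye, T_kelvin, sigma_angstrom) {
  stopifnot(mu_debye > 0, T_kelvin > 0, sigma_angstrom > 0)
  debye <- 3.33564e-30        # C m
  k_B <- 1.380649e-23         # J / K
  four_pi_eps0 <- 1.11265006e-10  # C^2 / (J m)
  mu <- mu_debye * debye
  sigma <- sigma_angstrom * 1e-10
  mu^2 / (four_pi_eps0 * k_B * T_kelvin * sigma^3)
}

#' Total reduced pair energy of two molecules
#'
#' Composes the model's reference part (primitive-model site energies, the
#' hard-tetrahedron overlap test, a bare hard sphere, or nothing for the
#' ideal model) with the two-charge dipole-dipole term.  In `"screened"`
#' dipole mode the dipole term is multiplied by the switch function of the
#' center-center distance; in `"full"` mode by 1; in `"none"` it is absent.
#'
#' @param pose_a,pose_b [pose()] objects.
#' @param geometry A [pm_geometry()] or [ht_geometry()], or one of the
#'   strings `"hs"` (plain hard spheres of diameter 1) / `"ideal"` (no
#'   interactions).
#' @param dipole A [dipole_spec()].
#' @param state A [thermo_state()].
#' @param box Cubic box edge (used for minimum images and the default
#'   reaction-field cutoff `box/2`); `Inf` turns periodicity off and requires
#'   an explicit `r_c` whenever dipoles are on.
#' @return Reduced energy with attributes `esw` and `edd` (the square-well
#'   and dipolar parts), or `Inf` on hard overlap.
#' @export
total_pair_energy <- function(pose_a, pose_b, geometry,
                              dipole = dipole_spec(),
                              state = thermo_state(), box = Inf) {
  cm <- as_cmodel(geometry, dipole, state, box)
  e <- cpp_pair_energy(cm, pose_a$r, pose_a$q, pose_b$r, pose_b$q)
  if (e[["overlap"]] > 0) return(Inf)
  structure(e[["esw"]] + e[["edd"]], esw = e[["esw"]], edd = e[["edd"]])
}

# --- internal: translate R-side model objects into the C++ parameter list --

.model_code <- c(ideal = 0L, hs = 1L, pm = 2L, ht = 3L)

# geometry: pm_geometry / ht_geometry object or "hs"/"ideal"
as_cmodel <- function(geometry, dipole, state, box) {
  if (inherits(geometry, "pm_geometry")) {
    type <- .model_code[["pm"]]
  } else if (inherits(geometry, "ht_geometry")) {
    type <- .model_code[["ht"]]
  } else if (is.character(geometry) && geometry %in% c("hs", "ideal")) {
    type <- .model_code[[geometry]]
  } else stop("unknown geometry/model")

  use_dip <- dipole$mode != "none" && dipole$lambda > 0
  dmode <- switch(dipole$mode, none = 0L, screened = 1L, full = 2L)
  if (!use_dip) dmode <- 0L
  r_c <- dipole$r_c
  if (use_dip && is.null(r_c)) {
    if (!is.finite(box)) stop("dipolar interactions need a finite box or an explicit r_c")
    r_c <- box / 2
  }
  if (is.null(r_c)) r_c <- 0

  sites <- matrix(numeric(0), 0, 3)
  dpp2 <- dnn2 <- rsw2 <- site_range2 <- 0
  iqp <- iqm <- -1L
  if (type == .model_code[["pm"]]) {
    sites <- geometry$body_sites[c("P1", "P2", "N"), , drop = FALSE]
    dpp2 <- geometry$d_pp^2
    dnn2 <- geometry$d_nn^2
    rsw2 <- geometry$r_sw^2
    no <- geometry$n_offset * geometry$sigma_OO
    site_range <- max(geometry$sigma_OO + geometry$d_pp,
                      geometry$d_nn + 2 * no,
                      geometry$sigma_OO / 2 + no + geometry$r_sw)
    site_range2 <- site_range^2
    if (use_dip) {
      sites <- rbind(sites,
                     geometry$body_dipole_axis * (+dipole$l0 / 2),
                     geometry$body_dipole_axis * (-dipole$l0 / 2))
      iqp <- 3L; iqm <- 4L
    }
  } else if (type == .model_code[["ht"]]) {
    sites <- geometry$body_vertices
    if (use_dip) {
      sites <- rbind(sites,
                     geometry$body_dipole_axis * (+dipole$l0 / 2),
                     geometry$body_dipole_axis * (-dipole$l0 / 2))
      iqp <- 4L; iqm <- 5L
    }
  } else if (use_dip) {
    # dipolar hard spheres / ideal dipoles: charges along body +z
    sites <- rbind(c(0, 0, +dipole$l0 / 2), c(0, 0, -dipole$l0 / 2))
    iqp <- 0L; iqm <- 1L
  }

  if (use_dip && is.finite(box) && r_c > box / 2 + 1e-12) {
    stop("reaction-field cutoff exceeds half the box edge")
  }

  list(
    type = as.integer(type), box = as.double(box),
    sites = sites,
    dpp2 = dpp2, dnn2 = dnn2, rsw2 = rsw2,
    beta_eps = as.double(state$beta_eps),
    site_range2 = site_range2,
    dmode = dmode,
    epsq = if (use_dip) dipole$lambda / dipole$l0^2 else 0,
    rf_coef = if (use_dip) {
      if (is.infinite(dipole$eps_r)) 0.5 else
        (dipole$eps_r - 1) / (2 * dipole$eps_r + 1)
    } else 0,
    rc = as.double(r_c), rlo = as.double(dipole$r_lo),
    rhi = as.double(dipole$r_hi),
    iqp = iqp, iqm = iqm
  )
}
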