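test_that("switch function hits its endpoints with zero slope and rises monotonically", {
  r_lo <- 4 / 2.653
  r_hi <- 6 / 2.653
  expect_identical(switch_function(r_lo, r_lo, r_hi), 0)
  expect_identical(switch_function(r_hi, r_lo, r_hi), 1)
  expect_equal(switch_function((r_lo + r_hi) / 2, r_lo, r_hi), 0.5,
               tolerance = 1e-14)
  # numeric derivative vanishes at both bounds (smoothstep C1 continuity)
  h <- 1e-6
  d_lo <- (switch_function(r_lo + h, r_lo, r_hi) -
           switch_function(r_lo - h, r_lo, r_hi)) / (2 * h)
  d_hi <- (switch_function(r_hi + h, r_lo, r_hi) -
           switch_function(r_hi - h, r_lo, r_hi)) / (2 * h)
  expect_lt(abs(d_lo), 1e-5)
  expect_lt(abs(d_hi), 1e-5)
  grid <- seq(r_lo - 1, r_hi + 1, length.out = 1000)
  s <- switch_function(grid, r_lo, r_hi)
  expect_true(all(diff(s) >= -1e-15))
  expect_true(all(s >= 0 & s <= 1))
  expect_error(switch_function(1, 2, 2), "smaller")
})

test_that("primitive-model pair energies follow the square-well rules", {
  geom <- pm_geometry()
  state <- thermo_state(beta_eps = 8, eta = 0.3, n = 2)
  pa <- pose()
  # molecules far beyond all ranges: zero
  pb <- pose(c(3, 0, 0))
  expect_identical(
    pm_pair_energy(pm_sites(pa, geom), pm_sites(pb, geom), geom, state), 0)
  # O-O closer than the hard diameter: overlap regardless of orientation
  set.seed(11)
  for (i in 1:20) {
    pb <- pose(c(0.99, 0, 0), quat_random(1)[1, ])
    expect_identical(
      pm_pair_energy(pm_sites(pa, geom), pm_sites(pb, geom), geom, state), Inf)
  }
  # the shipped bonded dimer fixture: exactly one P-N contact, energy -8
  fx <- generate_fixtures(1)$pm_dimer_bonded
  sa <- pm_sites(fx$poses[[1]], geom)
  sb <- pm_sites(fx$poses[[2]], geom)
  expect_identical(pm_pair_energy(sa, sb, geom, state), fx$expected)
  expect_identical(fx$expected, -8)
  # energies are always integer multiples of -beta_eps
  for (i in 1:200) {
    pb <- pose(runif(3, -1.6, 1.6), quat_random(1)[1, ])
    e <- pm_pair_energy(pm_sites(pa, geom), pm_sites(pb, geom), geom, state)
    if (is.finite(e)) {
      expect_equal(e %% state$beta_eps, 0)
      expect_lte(e, 0)
    }
  }
})

test_that("point dipole energy matches the closed forms", {
  # head-to-tail aligned pair: the -2 lambda / R^3 minimum
  expect_equal(dd_point_energy(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1), 1), -2)
  fx <- generate_fixtures(1)$dd_aligned
  expect_equal(dd_point_energy(fx$e1, fx$e2, fx$r12, fx$lambda), fx$expected)
  # antiparallel side-by-side: -lambda / R^3
  expect_equal(dd_point_energy(c(0, 0, 1), c(0, 0, -1), c(1, 0, 0), 1), -1)
  # mutually perpendicular: zero
  expect_equal(dd_point_energy(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), 1), 0)
  # R^-3 decay and linearity in lambda
  e1 <- dd_point_energy(c(0, 0, 1), c(0, 0, 1), c(0, 0, 2), 1)
  expect_equal(e1, -2 / 8)
  expect_equal(dd_point_energy(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1), 3.5), -7)
  expect_error(dd_point_energy(c(0, 0, 1), c(0, 0, 1), c(0, 0, 0), 1), "zero")
})

test_that("two-charge dipole converges to the point dipole at O(l0^2)", {
  set.seed(12)
  # random far-apart pair; huge r_c makes the reaction-field term negligible
  charges <- function(center, axis, l0) {
    rbind(center + axis * l0 / 2, center - axis * l0 / 2)
  }
  errs <- matrix(0, 10, 3)
  l0s <- c(1e-2, 1e-3, 1e-4)
  for (i in 1:10) {
    e1 <- rnorm(3); e1 <- e1 / sqrt(sum(e1^2))
    e2 <- rnorm(3); e2 <- e2 / sqrt(sum(e2^2))
    r12 <- rnorm(3); r12 <- r12 / sqrt(sum(r12^2)) * runif(1, 2, 4)
    ref <- dd_point_energy(e1, e2, r12, lambda = 1)
    for (k in seq_along(l0s)) {
      spec <- dipole_spec(lambda = 1, mode = "full", l0 = l0s[k], r_c = 1e8)
      e <- dd_charges_rf_energy(charges(c(0, 0, 0), e1, l0s[k]),
                                charges(r12, e2, l0s[k]), spec)
      errs[i, k] <- abs(e - ref)
    }
    # l0 = 0.001 agrees with the point dipole to a relative 1e-4
    expect_lt(errs[i, 2] / abs(ref), 1e-4)
  }
  # quadratic convergence: shrinking l0 tenfold cuts the error ~100x
  ratio <- mean(errs[, 1] / errs[, 2])
  expect_gt(ratio, 50)
  expect_lt(ratio, 200)
})

test_that("reaction field has coefficient 1/2 at eps_r = Inf and vanishes beyond r_c", {
  e1 <- c(0, 0, 1)
  ca <- rbind(c(0, 0, 0.005), c(0, 0, -0.005))
  cb <- rbind(c(2, 0, 0.005), c(2, 0, -0.005))
  e_inf <- dd_charges_rf_energy(ca, cb, dipole_spec(lambda = 1, mode = "full",
                                                    l0 = 0.01, r_c = 3))
  # finite eps_r converges to the conducting-boundary value
  for (eps_r in c(1e3, 1e5, 1e7)) {
    e_fin <- dd_charges_rf_energy(
      ca, cb, dipole_spec(lambda = 1, mode = "full", l0 = 0.01, r_c = 3,
                          eps_r = eps_r))
    expect_equal(e_fin, e_inf, tolerance = 10 / eps_r)
  }
  # explicit coefficient check against the hand-assembled sum
  spec <- dipole_spec(lambda = 1, mode = "full", l0 = 0.01, r_c = 3)
  qs <- c(1, -1)
  acc <- 0
  for (i in 1:2) for (j in 1:2) {
    r <- sqrt(sum((cb[j, ] - ca[i, ])^2))
    acc <- acc + qs[i] * qs[j] * (1 / r + 0.5 * r^2 / 3^3)
  }
  expect_equal(e_inf, acc / 0.01^2, tolerance = 1e-12)
  # beyond the cutoff the interaction is exactly zero
  cb_far <- cb + matrix(rep(c(2, 0, 0), each = 2), 2)
  expect_identical(
    dd_charges_rf_energy(ca, cb_far,
                         dipole_spec(lambda = 1, mode = "full", l0 = 0.01,
                                     r_c = 3)), 0)
  expect_error(dd_charges_rf_energy(ca, ca, spec), "coincident")
})

test_that("reduced dipole strength from physical constants", {
  lam_gas <- lambda_from_physical(1.85, 298, 3)
  lam_liq <- lambda_from_physical(2.9, 298, 3)
  expect_equal(round(lam_gas), 3)
  expect_equal(lam_gas, 3.08, tolerance = 0.01)
  expect_equal(lam_liq, 7.57, tolerance = 0.01)
  # lambda scales as mu^2 and 1/(T sigma^3)
  expect_equal(lambda_from_physical(3.7, 298, 3), 4 * lam_gas,
               tolerance = 1e-12)
  expect_equal(lambda_from_physical(1.85, 149, 6),
               lam_gas * (298 / 149) / 8, tolerance = 1e-12)
  expect_error(lambda_from_physical(-1, 298, 3))
})

test_that("total pair energy is symmetric under particle exchange", {
  state <- thermo_state(beta_eps = 8, eta = 0.3, n = 2)
  specs <- list(dipole_spec(mode = "none"),
                dipole_spec(lambda = 3, mode = "screened", r_c = 4),
                dipole_spec(lambda = 7, mode = "full", r_c = 4))
  set.seed(13)
  for (geom in list(pm_geometry(), ht_geometry())) {
    for (sp in specs) {
      for (i in 1:40) {
        pa <- pose(runif(3, 0, 3), quat_random(1)[1, ])
        pb <- pose(runif(3, 0, 3), quat_random(1)[1, ])
        ea <- total_pair_energy(pa, pb, geom, sp, state, box = 8)
        eb <- total_pair_energy(pb, pa, geom, sp, state, box = 8)
        if (is.infinite(ea)) {
          expect_identical(eb, Inf)
        } else {
          expect_equal(as.numeric(ea), as.numeric(eb), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("dipole modes compose as switch x dipole term", {
  geom <- pm_geometry()
  state <- thermo_state(beta_eps = 8, eta = 0.3, n = 2)
  r_lo <- 4 / 2.653
  r_hi <- 6 / 2.653
  mk <- function(mode) dipole_spec(lambda = 7, mode = mode, l0 = 0.01,
                                   r_lo = r_lo, r_hi = r_hi, r_c = 4)
  set.seed(14)
  for (i in 1:200) {
    d <- runif(1, 1.01, 4.2)
    pb <- pose(c(d, 0, 0), quat_random(1)[1, ])
    e_full <- total_pair_energy(pose(), pb, geom, mk("full"), state, box = 10)
    e_scr <- total_pair_energy(pose(), pb, geom, mk("screened"), state,
                               box = 10)
    e_none <- total_pair_energy(pose(), pb, geom, mk("none"), state, box = 10)
    if (is.infinite(e_full)) next
    # mode none: no dipolar part at all
    expect_identical(attr(e_none, "edd"), 0)
    expect_equal(attr(e_none, "esw"), attr(e_full, "esw"))
    # screened = switch(center distance) x full, bin by bin
    expect_equal(attr(e_scr, "edd"),
                 switch_function(d, r_lo, r_hi) * attr(e_full, "edd"),
                 tolerance = 1e-10)
    if (d < r_lo) expect_identical(attr(e_scr, "edd"), 0)
    if (d > r_hi) expect_equal(as.numeric(e_scr), as.numeric(e_full),
                               tolerance = 1e-12)
  }
})

test_that("the compiled total energy matches the R-level composition", {
  geom <- pm_geometry()
  state <- thermo_state(beta_eps = 8, eta = 0.3, n = 2)
  spec <- dipole_spec(lambda = 7, mode = "screened", l0 = 0.01, r_c = 4)
  set.seed(15)
  n_checked <- 0
  for (i in 1:300) {
    d <- runif(1, 0.9, 4.2)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    pa <- pose(c(0, 0, 0), quat_random(1)[1, ])
    pb <- pose(d * u, quat_random(1)[1, ])
    e_cpp <- total_pair_energy(pa, pb, geom, spec, state, box = Inf)
    sa <- pm_sites(pa, geom, l0 = spec$l0)
    sb <- pm_sites(pb, geom, l0 = spec$l0)
    e_sw <- pm_pair_energy(sa[1:4, ], sb[1:4, ], geom, state, box = Inf)
    if (is.infinite(e_sw)) {
      expect_identical(e_cpp, Inf)
      next
    }
    e_dd <- dd_charges_rf_energy(sa[c("QP", "QM"), ], sb[c("QP", "QM"), ],
                                 spec) *
      switch_function(d, spec$r_lo, spec$r_hi)
    expect_equal(attr(e_cpp, "esw"), e_sw, tolerance = 1e-8)
    # the dipolar part is a near-cancelling sum scaled by lambda / l0^2, so
    # compare absolutely at the cancellation noise floor
    expect_lt(abs(attr(e_cpp, "edd") - e_dd), 1e-9)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 100)
})

test_that("hard tetrahedra contribute 0 or overlap, never a finite attraction", {
  geom <- ht_geometry()
  state <- thermo_state(beta_eps = 0, eta = 0.3, n = 2)
  set.seed(16)
  for (i in 1:100) {
    d <- runif(1, 0.2, 1.2)
    pb <- pose(c(d, 0, 0), quat_random(1)[1, ])
    e <- total_pair_energy(pose(), pb, geom, dipole_spec(mode = "none"),
                           state, box = 6)
    ov <- sat_overlap(pose(), pb, geom)
    if (ov) expect_identical(e, Inf) else expect_equal(as.numeric(e), 0)
  }
})
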