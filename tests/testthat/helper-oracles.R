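# Shared helpers: random poses, independent oracles and memoised reference
# runs (computed once per test session, reused across files).

random_poses <- function(n, r_range = c(0, 1), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  d <- runif(n, r_range[1], r_range[2])
  list(qa = quat_random(n), qb = quat_random(n), dir = u, dist = d)
}

# deterministic volume of a tetrahedron from its vertices (oracle for
# tetra_volume and for rotation invariance)
det_volume <- function(verts) {
  abs(det(rbind(verts[2, ] - verts[1, ],
                verts[3, ] - verts[1, ],
                verts[4, ] - verts[1, ]))) / 6
}

# Monte Carlo integration oracle for the two-particle primitive model in a
# periodic box: probability that a configuration drawn from the Boltzmann
# distribution is bonded (energy < 0).  Independent of the sweep engine.
pm_two_body_bonded_oracle <- function(geom, state, box, n_draw = 4e5,
                                      seed = 991) {
  set.seed(seed)
  pa <- pose(c(0, 0, 0), c(1, 0, 0, 0))
  qa <- quat_random(n_draw)
  qb <- quat_random(n_draw)
  pos <- matrix(runif(3 * n_draw, -box / 2, box / 2), ncol = 3)
  w <- numeric(n_draw)
  bonded <- logical(n_draw)
  for (i in seq_len(n_draw)) {
    e <- total_pair_energy(pose(c(0, 0, 0), qa[i, ]),
                           pose(pos[i, ], qb[i, ]),
                           geom, dipole_spec(mode = "none"), state, box = box)
    if (is.infinite(e)) {
      w[i] <- 0
    } else {
      w[i] <- exp(-e)
      bonded[i] <- e < 0
    }
  }
  p <- sum(w * bonded) / sum(w)
  # delta-method standard error of the weighted ratio
  m <- sum(w) / n_draw
  v <- sum((w * (bonded - p))^2) / n_draw
  list(p = p, se = sqrt(v / n_draw) / m)
}

# block-averaged mean and standard error of a (correlated) scalar trace
block_se <- function(x, n_blocks = 20) {
  blk <- cut(seq_along(x), breaks = n_blocks, labels = FALSE)
  bm <- vapply(split(x, blk), mean, numeric(1))
  list(mean = mean(bm), se = sd(bm) / sqrt(length(bm)))
}

# ---- memoised reference simulations (shared across test files) -----------

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, maker) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- maker()
  .run_cache[[key]]
}

# hard-sphere fluid at liquid packing: used for g(r), contact value,
# coordination-number and first-minimum checks
hs_reference_run <- function() {
  cached_run("hs035", function() {
    cfg <- run_config(model = "hs", eta = 0.35, n = 216, n_equil = 500,
                      n_prod = 3000, sample_every = 5, seed = 101,
                      pairs = "C-C")
    run_simulation(cfg)
  })
}

# ideal-gas run: uncorrelated limit for the g(r) estimator
ideal_reference_run <- function() {
  cached_run("ideal", function() {
    # sparse sampling: back-to-back snapshots of the random walk are highly
    # correlated, which makes the per-bin block errors unreliable
    cfg <- run_config(model = "ideal", eta = 0.35, n = 128, n_equil = 50,
                      n_prod = 4000, sample_every = 10, seed = 202,
                      pairs = "C-C")
    run_simulation(cfg)
  })
}

# primitive-model desk-scale runs at the published state point
# (beta*eps = 8, eta = 0.35, N = 216), one per dipole mode.  Same protocol
# as scripts/acceptance.R: a long no-dipole run first, then the dipolar
# runs continue from its equilibrated final configuration.
pm_reference_run <- function(mode) {
  cached_run(paste0("pm_", mode), function() {
    if (mode == "none") {
      cfg <- run_config(model = "pm", eta = 0.35, n = 216, beta_eps = 8,
                        dipole_mode = "none", n_equil = 50000,
                        n_prod = 50000, sample_every = 25, pairs = "O-O",
                        seed = 501)
      suppressWarnings(run_simulation(cfg))
    } else {
      base <- pm_reference_run("none")
      cfg <- run_config(model = "pm", eta = 0.35, n = 216, beta_eps = 8,
                        lambda = 7, dipole_mode = mode, n_equil = 40000,
                        n_prod = 40000, sample_every = 25, pairs = "O-O",
                        seed = switch(mode, screened = 502, full = 503))
      suppressWarnings(run_simulation(cfg, init = base$final))
    }
  })
}
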