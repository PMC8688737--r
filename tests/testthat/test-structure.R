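test_that("pair histogram counts land in the right bins", {
  box <- 10
  pos <- rbind(c(1, 1, 1), c(1 + 1.234, 1, 1))
  quat <- rbind(c(1, 0, 0, 0), c(1, 0, 0, 0))
  conf <- configuration(pos, quat, box, "hs")
  h <- accumulate_pair_histogram(conf, "C-C", bin_width = 0.02)
  expect_equal(sum(h$counts), 2)  # ordered pairs: (1,2) and (2,1)
  bin <- findInterval(1.234, h$breaks, left.open = TRUE)
  expect_equal(h$counts[bin], 2)
  expect_equal(sum(h$counts[-bin]), 0)
  # periodic wrap: particles near opposite faces are close
  conf2 <- configuration(rbind(c(0.1, 5, 5), c(9.9, 5, 5)), quat, box, "hs")
  h2 <- accumulate_pair_histogram(conf2, "C-C", bin_width = 0.02)
  bin2 <- findInterval(0.2, h2$breaks, left.open = TRUE)
  expect_equal(h2$counts[bin2], 2)
  expect_error(accumulate_pair_histogram(conf, "C-C", r_max = box), "half")
})

test_that("histogram totals and symmetry on a 5-particle fixture", {
  set.seed(41)
  n <- 5
  box <- 30
  # all pairwise distances within r_max = box/2: cluster in a 3-sigma ball
  pos <- matrix(10 + runif(n * 3, 0, 2.5), n)
  conf <- configuration(pos, quat_random(n), box, "pm")
  h <- accumulate_pair_histogram(conf, "O-O", bin_width = 0.05)
  expect_equal(sum(h$counts), n * (n - 1))
  # cross-molecule label exchange: O-P counts equal P-O counts bin by bin
  hop <- accumulate_pair_histogram(conf, "O-P", bin_width = 0.05)
  hpo <- accumulate_pair_histogram(conf, "P-O", bin_width = 0.05)
  expect_identical(hop$counts, hpo$counts)
  expect_equal(sum(hop$counts), n * (n - 1) * 2)
})

test_that("uncorrelated uniform centers normalise to g = 1", {
  set.seed(42)
  n <- 200
  box <- 8
  counts <- NULL
  n_samp <- 40
  h <- NULL
  for (s in seq_len(n_samp)) {
    conf <- configuration(matrix(runif(n * 3, 0, box), n),
                          quat_random(n), box, "hs")
    hs <- accumulate_pair_histogram(conf, "C-C", bin_width = 0.1)
    counts <- if (is.null(counts)) hs$counts else counts + hs$counts
    h <- hs
  }
  h$counts <- counts
  h$n_samples <- n_samp
  g <- normalize_g(h)
  # drop the innermost bins (tiny shell volumes, noisy)
  keep <- g$r > 0.5
  expect_equal(mean(g$g[keep]), 1, tolerance = 0.01)
  expect_lt(max(abs(g$g[keep] - 1)), 0.15)
  h$counts <- 0 * h$counts
  expect_error(normalize_g(h), "empty")
})

test_that("hard spheres vanish below contact and match Carnahan-Starling at it", {
  run <- hs_reference_run()
  g <- run$g[["C-C"]]
  expect_true(all(g$g[g$r < 1] == 0))
  eta <- 0.35
  cs_contact <- (1 - eta / 2) / (1 - eta)^3
  contact <- g$g[which(g$r > 1)[1:2]]
  expect_equal(max(contact), cs_contact, tolerance = 0.1)
})

test_that("first-minimum detection recovers the damped-cosine extremum", {
  r <- seq(0.5, 3, by = 0.005)
  g <- data.frame(r = r, g = 1 + exp(-r) * cos(2 * pi * r))
  # closed form: extrema at tan(2 pi r) = -1/(2 pi); first max near 0.975,
  # first min near 1.475
  r_min_true <- 1.4749
  expect_equal(find_first_minimum(g), r_min_true, tolerance = 0.006)
  # flat g: no interior minimum
  expect_error(find_first_minimum(data.frame(r = r, g = rep(1, length(r)))),
               "minimum")
  # monotone g: no interior minimum
  expect_error(find_first_minimum(data.frame(r = r, g = r)), "minimum")
})

test_that("hard-sphere first minimum sits near 1.6 contact distances", {
  run <- hs_reference_run()
  expect_gt(run$r_min, 1.4)
  expect_lt(run$r_min, 1.8)
})

test_that("coordination number: closed form and counting oracle", {
  # g = 1 exactly: N_C = (4 pi / 3) rho R^3
  r <- seq(0.01, 3, by = 0.02)
  g1 <- structure(data.frame(r = r, g = rep(1, length(r)), se = NA),
                  class = c("correlation_function", "data.frame"))
  rho <- 0.8
  expect_equal(coordination_number(g1, r_min = 2, rho = rho),
               4 * pi / 3 * rho * 8, tolerance = 1e-3)
  expect_error(coordination_number(g1, r_min = 5, rho = rho), "range")

  # quadrature on a single snapshot vs direct neighbor counting
  run <- hs_reference_run()
  conf <- run$final
  h <- accumulate_pair_histogram(conf, "C-C", bin_width = run$config$bin_width)
  gsnap <- normalize_g(h)
  r_min <- run$r_min
  n <- nrow(conf$pos)
  # quadrature with the partner density (N-1)/V counts neighbors per particle
  nc_quad <- coordination_number(gsnap, r_min, rho = (n - 1) / conf$box^3)
  # counting oracle: average neighbors within r_min over the same snapshot
  cnt <- 0
  for (i in seq_len(n)) {
    d <- sweep(conf$pos[-i, , drop = FALSE], 2, conf$pos[i, ], "-")
    d <- d - conf$box * round(d / conf$box)
    cnt <- cnt + sum(sqrt(rowSums(d^2)) <= r_min)
  }
  nc_count <- cnt / n
  expect_equal(nc_quad, nc_count, tolerance = 0.02)
})

test_that("energy table reports block statistics per run", {
  run <- hs_reference_run()
  tab <- energy_table(list(hs = run))
  expect_equal(nrow(tab), 1)
  expect_identical(tab$model, "hs")
  expect_equal(tab$e_total, tab$e_sw + tab$e_dd)
  expect_true(tab$se_reliable)
  expect_gte(tab$n_blocks, 10)
  # hard spheres have zero reduced energy throughout
  expect_identical(tab$e_total, 0)
  expect_error(energy_table(list()), "no runs")
  expect_error(energy_summary(numeric(0), numeric(0), 10, 0), "zero-length")
  # fewer than 10 blocks is flagged unreliable
  short <- run
  short$summary <- energy_summary(rnorm(24), rnorm(24), 10, beta_eps = 2,
                                  n_blocks = 4)
  tab2 <- energy_table(list(short = short))
  expect_false(tab2$se_reliable)
  # well-depth scaling divides by beta_eps
  expect_equal(tab2$e_total_well, tab2$e_total / 2)
})
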