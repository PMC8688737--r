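# Structural observables: site-site pair histograms, normalised correlation
# functions g(r), first-minimum detection, coordination numbers and the
# block-averaged energy decomposition table.

#' Accumulate a site-site pair distance histogram
#'
#' Bins the minimum-image distances between site group `a` of every molecule
#' and site group `b` of every *other* molecule (ordered pairs) of a single
#' configuration.  Available site labels: `C` (center) for every model;
#' `O`, `P`, `N` for the primitive model; `V`, `V1` (charged-edge vertices),
#' `V3` (the other two) for tetrahedra.
#'
#' @param config A [configuration()].
#' @param pair Pair label such as `"C-C"`, `"O-P"`, `"V1-V3"`.
#' @param bin_width Bin width in sigma units.
#' @param r_max Maximum sampled radius; defaults to (and must not exceed)
#'   half the box edge.
#' @return An object of class `pair_histogram` (counts per bin plus the
#'   metadata needed for normalisation).
#' @export
accumulate_pair_histogram <- function(config, pair = "C-C", bin_width = 0.02,
                                      r_max = NULL) {
  stopifnot(inherits(config, "configuration"), bin_width > 0)
  if (is.null(r_max)) r_max <- config$box / 2
  if (r_max > config$box / 2 + 1e-12) {
    stop("r_max must not exceed half the box edge")
  }
  sp <- site_positions(config, pair)
  n <- nrow(config$pos)
  breaks <- seq(0, r_max, by = bin_width)
  nbins <- length(breaks) - 1L
  counts <- numeric(nbins)
  for (i in seq_len(n)) {
    ai <- sp$a[sp$a_mol == i, , drop = FALSE]
    bj <- sp$b[sp$b_mol != i, , drop = FALSE]
    for (k in seq_len(nrow(ai))) {
      d <- sweep(bj, 2L, ai[k, ], "-")
      d <- d - config$box * round(d / config$box)
      r <- sqrt(rowSums(d^2))
      h <- findInterval(r[r < r_max], breaks, left.open = TRUE)
      h <- h[h >= 1L & h <= nbins]
      counts <- counts + tabulate(h, nbins)
    }
  }
  new_pair_histogram(counts, breaks, pair, n_samples = 1L, n = n,
                     box = config$box, n_a = sp$n_a, n_b = sp$n_b)
}

new_pair_histogram <- function(counts, breaks, pair, n_samples, n, box,
                               n_a, n_b, block_counts = NULL,
                               block_samples = NULL) {
  structure(list(counts = counts, breaks = breaks, pair = pair,
                 n_samples = n_samples, n = n, box = box,
                 n_a = n_a, n_b = n_b,
                 block_counts = block_counts, block_samples = block_samples),
            class = "pair_histogram")
}

# lab-frame coordinates of the two site groups of a pair label
site_positions <- function(config, pair) {
  tag <- config$model
  ab <- strsplit(pair, "-", fixed = TRUE)[[1L]]
  if (length(ab) != 2L) stop("pair label must be of the form 'A-B'")
  body <- switch(tag,
    pm = {
      g <- config$geometry
      list(C = matrix(0, 1, 3), O = matrix(0, 1, 3),
           P = g$body_sites[c("P1", "P2"), , drop = FALSE],
           N = g$body_sites["N", , drop = FALSE])
    },
    ht = {
      g <- config$geometry
      list(C = matrix(0, 1, 3), V = g$body_vertices,
           V1 = g$body_vertices[1:2, , drop = FALSE],
           V3 = g$body_vertices[3:4, , drop = FALSE])
    },
    list(C = matrix(0, 1, 3)))
  if (!all(ab %in% names(body))) {
    stop(sprintf("unknown site pair '%s' for model '%s'", pair, tag))
  }
  n <- nrow(config$pos)
  lab_group <- function(sites) {
    ns <- nrow(sites)
    out <- matrix(0, n * ns, 3L)
    mol <- integer(n * ns)
    for (i in seq_len(n)) {
      rot <- quat_rotate(config$quat[i, ], sites)
      if (is.null(dim(rot))) rot <- matrix(rot, 1L, 3L)
      idx <- ((i - 1L) * ns + 1L):(i * ns)
      out[idx, ] <- sweep(rot, 2L, config$pos[i, ], "+")
      mol[idx] <- i
    }
    list(x = out, mol = mol, ns = ns)
  }
  A <- lab_group(body[[ab[1L]]])
  B <- lab_group(body[[ab[2L]]])
  list(a = A$x, a_mol = A$mol, n_a = A$ns,
       b = B$x, b_mol = B$mol, n_b = B$ns)
}

#' Normalise a pair histogram into a correlation function
#'
#' Standard site-site radial distribution estimator: counts divided by the
#' ideal-gas expectation
#' `n_samples * N * n_a * n_b * (N-1)/V * (4 pi / 3)(r_out^3 - r_in^3)`,
#' so that an uncorrelated system gives `g = 1` in every bin.  When the
#' histogram carries block-resolved counts, per-bin standard errors over the
#' blocks are attached.
#'
#' @param hist A `pair_histogram`.
#' @param rho Optional number-density override (molecules per volume of the
#'   partner species); by default `(N-1)/V`.
#' @return A data frame of class `correlation_function` with columns `r`
#'   (bin centers), `g` and `se` (NA without block data), and attributes
#'   `pair`, `rho`, `n`, `box`.
#' @export
normalize_g <- function(hist, rho = NULL) {
  stopifnot(inherits(hist, "pair_histogram"))
  if (hist$n_samples < 1 || sum(hist$counts) == 0) {
    stop("empty histogram: nothing to normalise")
  }
  v <- hist$box^3
  if (is.null(rho)) rho <- (hist$n - 1) / v
  br <- hist$breaks
  shell <- 4 * pi / 3 * (br[-1L]^3 - br[-length(br)]^3)
  denom <- hist$n_samples * hist$n * hist$n_a * hist$n_b * rho * shell
  g <- hist$counts / denom
  se <- rep(NA_real_, length(g))
  if (!is.null(hist$block_counts)) {
    bs <- hist$block_samples
    keep <- bs > 0
    gb <- sweep(hist$block_counts[, keep, drop = FALSE], 2L, bs[keep], "/")
    gb <- gb / (hist$n * hist$n_a * hist$n_b * rho * shell)
    k <- sum(keep)
    if (k >= 2L) se <- apply(gb, 1L, sd) / sqrt(k)
  }
  out <- data.frame(r = (br[-1L] + br[-length(br)]) / 2, g = g, se = se)
  structure(out, class = c("correlation_function", "data.frame"),
            pair = hist$pair, rho = rho, n = hist$n, box = hist$box)
}

#' Location of the first minimum of g(r)
#'
#' Finds the first local minimum after the first local maximum of a
#' moving-average smoothed copy of `g(r)`; ties are broken toward smaller
#' `r`.  Errors when the curve is monotone (no interior minimum).
#'
#' @param g A `correlation_function` (or data frame with columns `r`, `g`).
#' @param smooth_window Moving-average window in bins (odd; default 5).
#' @return The radius of the first minimum.
#' @export
find_first_minimum <- function(g, smooth_window = 5L) {
  r <- g$r
  y <- g$g
  w <- max(1L, as.integer(smooth_window))
  if (w %% 2L == 0L) w <- w + 1L
  if (w > 1L) {
    s <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2L))
    pad <- w %/% 2L
    s[seq_len(pad)] <- s[pad + 1L]
    s[(length(s) - pad + 1L):length(s)] <- s[length(s) - pad]
  } else s <- y
  n <- length(s)
  peak <- NA_integer_
  for (i in 2:(n - 1L)) {
    if (s[i] > s[i - 1L] && s[i] >= s[i + 1L]) { peak <- i; break }
  }
  if (is.na(peak)) stop("no interior minimum: g has no peak")
  for (i in (peak + 1L):(n - 1L)) {
    if (s[i] <= s[i - 1L] && s[i] < s[i + 1L]) return(r[i])
  }
  stop("no interior minimum found after the first peak")
}

#' First-shell coordination number
#'
#' Trapezoidal quadrature of \eqn{4\pi\rho \int_0^{R_{min}} g(r) r^2 dr}
#' over the sampled bins of the center-center correlation function.
#'
#' @param g A `correlation_function` for the center-center pair.
#' @param rho Number density `N/V`; defaults to the density stored with `g`.
#' @param r_min Integration limit (first minimum of `g`); must lie within
#'   the sampled range.
#' @return The mean number of neighbor centers within `r_min`.
#' @export
coordination_number <- function(g, r_min, rho = NULL) {
  if (is.null(rho)) {
    n <- attr(g, "n"); box <- attr(g, "box")
    if (is.null(n) || is.null(box)) stop("rho not given and not stored in g")
    rho <- n / box^3
  }
  if (r_min > max(g$r) + 1e-12) stop("r_min beyond the sampled range")
  keep <- g$r <= r_min
  r <- c(0, g$r[keep])
  y <- c(0, g$g[keep] * g$r[keep]^2)
  # close the integral at r_min itself (linear interpolation of g there),
  # not at the last grid point below it
  if (max(r) < r_min && any(!keep)) {
    gmin <- approx(g$r, g$g, xout = r_min)$y
    r <- c(r, r_min)
    y <- c(y, gmin * r_min^2)
  }
  4 * pi * rho * sum(diff(r) * (y[-1L] + y[-length(y)]) / 2)
}

#' Block-averaged reduced energy table
#'
#' One row per completed run: per-particle reduced energies split into
#' square-well and dipole-dipole parts with block-average standard errors.
#' Energies are reported both in thermal units (\eqn{\beta E / N}) and,
#' for square-well models, in units of the well depth
#' (\eqn{\beta E / (N \beta\epsilon_{HB})}).
#'
#' @param runs A named list of results from [run_simulation()].
#' @return A data frame with one row per run.
#' @export
energy_table <- function(runs) {
  if (!length(runs)) stop("no runs given")
  rows <- lapply(names(runs), function(nm) {
    run <- runs[[nm]]
    s <- run$summary
    if (is.null(s)) stop(sprintf("run '%s' has no production summary", nm))
    data.frame(
      run = nm, model = run$config$model, mode = run$config$dipole$mode,
      lambda = run$config$dipole$lambda, eta = run$config$state$eta,
      beta_eps = run$config$state$beta_eps,
      e_sw = s$e_sw, e_dd = s$e_dd, e_total = s$e_total, se = s$se,
      e_total_well = s$e_total_well, se_well = s$se_well,
      n_blocks = s$n_blocks, se_reliable = s$n_blocks >= 10L,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# per-particle block statistics from per-sweep production traces
energy_summary <- function(esw_trace, edd_trace, n, beta_eps,
                           n_blocks = 20L) {
  ns <- length(esw_trace)
  if (ns < 1L) stop("zero-length production trace")
  blk <- cut(seq_len(ns), breaks = min(n_blocks, ns), labels = FALSE)
  tot <- (esw_trace + edd_trace) / n
  bm <- vapply(split(tot, blk), mean, numeric(1))
  k <- length(bm)
  se <- if (k >= 2L) sd(bm) / sqrt(k) else NA_real_
  out <- list(
    e_sw = mean(esw_trace) / n, e_dd = mean(edd_trace) / n,
    e_total = mean(tot), se = se, n_blocks = k)
  if (beta_eps > 0) {
    out$e_total_well <- out$e_total / beta_eps
    out$se_well <- se / beta_eps
  } else {
    out$e_total_well <- NA_real_
    out$se_well <- NA_real_
  }
  out
}
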