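# NVT Metropolis Monte Carlo: initial configuration construction, sweep
# driver, equilibration monitoring and configuration audits.

#' Box edge length from packing fraction
#'
#' `box = (N v_mol / eta)^(1/3)` with the molecular hard-core volume
#' `v_mol = pi/6` for the primitive model / hard spheres (diameter 1) and
#' `sqrt(3)/27` for hard tetrahedra (circumsphere diameter 1).
#'
#' @param eta Packing fraction in (0, 0.74).
#' @param n Particle count.
#' @param model `"pm"`, `"hs"`, `"ideal"` or `"ht"`, or a geometry object.
#' @return Cubic box edge length in sigma units.
#' @export
density_to_box <- function(eta, n, model = "hs") {
  if (!(eta > 0 && eta < 0.74)) stop("eta must lie in (0, 0.74)")
  (n * molecular_volume(model) / eta)^(1 / 3)
}

molecular_volume <- function(model) {
  tag <- model_tag(model)
  if (tag == "ht") sqrt(3) / 27 else pi / 6
}

model_tag <- function(model) {
  if (inherits(model, "pm_geometry")) return("pm")
  if (inherits(model, "ht_geometry")) return("ht")
  if (is.character(model) && model %in% c("pm", "ht", "hs", "ideal"))
    return(model)
  stop("unknown model")
}

# geometry object for a model tag (default parameters)
default_geometry <- function(model) {
  if (inherits(model, "pm_geometry") || inherits(model, "ht_geometry"))
    return(model)
  switch(model, pm = pm_geometry(), ht = ht_geometry(), model)
}

#' Particle configuration in a periodic cubic box
#'
#' @param pos `N x 3` matrix of center positions in `[0, box)`.
#' @param quat `N x 4` matrix of unit quaternions.
#' @param box Cubic box edge length.
#' @param geometry Geometry object or model string (see
#'   [total_pair_energy()]).
#' @return An object of class `configuration`.
#' @export
configuration <- function(pos, quat, box, geometry) {
  stopifnot(is.matrix(pos), ncol(pos) == 3L, is.matrix(quat),
            ncol(quat) == 4L, nrow(pos) == nrow(quat), box > 0)
  structure(list(pos = pos, quat = quat, box = box,
                 geometry = default_geometry(geometry),
                 model = model_tag(geometry)),
            class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("<configuration> %s, N = %d, box = %.4f (eta = %.4f)\n",
              x$model, nrow(x$pos), x$box,
              nrow(x$pos) * molecular_volume(x$geometry) / x$box^3))
  invisible(x)
}

#' Build an overlap-free starting configuration
#'
#' Places molecules on an FCC-derived lattice at a dilute density with
#' uniformly random orientations, then compresses stepwise to the target
#' packing fraction while relaxing hard overlaps with Monte Carlo moves that
#' never increase a particle's overlap count.
#'
#' @param n Particle count.
#' @param eta Target packing fraction.
#' @param model Model string or geometry object.
#' @param seed Integer seed (drives R's RNG; the whole construction is
#'   deterministic given the seed).
#' @param max_cycles,relax_sweeps Budget for the compression loop.
#' @return A [configuration()] that passes the full pairwise overlap audit.
#'   If the target density cannot be reached within the budget, an error
#'   reporting the achieved packing fraction is raised.
#' @export
build_initial_config <- function(n, eta, model = "hs", seed = 1,
                                 max_cycles = 2000, relax_sweeps = 300) {
  geom <- default_geometry(model)
  tag <- model_tag(model)
  set.seed(seed)
  box_target <- density_to_box(eta, n, geom)

  if (tag == "ideal") {
    pos <- matrix(runif(3 * n, 0, box_target), ncol = 3L)
    quat <- quat_random(n)
    return(configuration(pos, quat, box_target, geom))
  }

  # FCC start.  Preferred: directly at the target box, which is overlap-free
  # for hard spheres whenever the nearest-neighbor spacing clears the center
  # core (eta below close packing); for the primitive model only the
  # orientation-dependent site cores can then still clash and the relax
  # phase of cpp_compress clears those without any box change.  When even
  # the orientation-independent core cannot fit on the target lattice
  # (tetrahedra: the circumsphere bound; extreme site geometries: reach
  # sigma + d_pp), fall back to a dilute lattice beyond the full interaction
  # range and compress stepwise.
  range <- if (tag == "pm") {
    no <- geom$n_offset * geom$sigma_OO
    max(geom$sigma_OO + geom$d_pp, geom$d_nn + 2 * no)
  } else 1
  core <- if (tag == "pm") geom$sigma_OO else 1
  fcc_sites <- function(m, cell) {
    base <- rbind(c(0, 0, 0), c(.5, .5, 0), c(.5, 0, .5), c(0, .5, .5))
    g <- expand.grid(x = seq_len(m) - 1L, y = seq_len(m) - 1L,
                     z = seq_len(m) - 1L)
    do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
      sweep(base, 2L, as.numeric(g[i, ]), "+") * cell
    }))
  }
  m <- ceiling((n / 4)^(1 / 3))
  ms <- ceiling(n^(1 / 3))
  if (box_target / (m * sqrt(2)) > 1.02 * core) {
    # FCC directly at the target box clears the center core
    box0 <- box_target
    sites <- fcc_sites(m, box0 / m)
  } else if (box_target / ms > 1.02 * core) {
    # FCC is over-provisioned for this n; simple cubic still fits
    box0 <- box_target
    g <- as.matrix(expand.grid(x = seq_len(ms) - 1L, y = seq_len(ms) - 1L,
                               z = seq_len(ms) - 1L))
    sites <- (g + 0.5) * (box0 / ms)
  } else {
    # even the orientation-independent core cannot fit at the target:
    # dilute FCC beyond the full interaction range, then compress
    box0 <- max(box_target, 1.25 * range * sqrt(2) * m)
    sites <- fcc_sites(m, box0 / m)
  }
  pos <- sites[sample.int(nrow(sites), n), , drop = FALSE]
  quat <- quat_random(n)

  cm <- as_cmodel(geom, dipole_spec(mode = "none"),
                  thermo_state(beta_eps = 0, eta = eta, n = n), box0)
  # relaxes any site overlaps of the start state (and decorrelates a few
  # sweeps); when box0 > box_target it also compresses stepwise
  res <- cpp_compress(cm, pos, quat, box0, box_target, 0.99,
                      max_cycles, relax_sweeps,
                      0.25, pi / 4)
  if (!res$reached) {
    eta_ach <- n * molecular_volume(geom) / res$box^3
    stop(sprintf(
      "compression stalled: reached eta = %.4f of target %.4f", eta_ach, eta))
  }
  pos <- res$pos
  quat <- res$quat
  cfg <- configuration(pos, quat, box_target, geom)
  aud <- config_audit(cfg)
  if (aud$n_overlap > 0L) stop("internal error: initial configuration overlaps")
  cfg
}

#' Full pairwise audit of a configuration
#'
#' O(N^2) recomputation of the total reduced energy and hard-overlap count,
#' used as the reference for the incremental bookkeeping of the sweep loop.
#'
#' @param config A [configuration()].
#' @param dipole A [dipole_spec()].
#' @param state A [thermo_state()].
#' @return List with `n_overlap`, `esw`, `edd` and `ok` (no overlaps).
#' @export
config_audit <- function(config, dipole = dipole_spec(),
                         state = thermo_state(beta_eps = 0, eta = 0.3,
                                              n = nrow(config$pos))) {
  cm <- as_cmodel(config$geometry, dipole, state, config$box)
  r <- cpp_config_energy(cm, config$pos, config$quat)
  list(n_overlap = r$n_overlap, esw = r$esw, edd = r$edd,
       ok = r$n_overlap == 0L)
}

#' Run Metropolis sweeps on a configuration
#'
#' One sweep is `N` trial moves; each trial picks a random particle and
#' proposes a joint translation (uniform in a cube of side `2 d_trans`) and
#' rotation (axis uniform on the sphere, angle uniform in `[0, d_rot]`),
#' accepted with probability `min(1, exp(-delta beta u))`.  Trials creating
#' hard overlaps are rejected.  The running energy is updated incrementally
#' and revalidated against a full recomputation every `revalidate_every`
#' sweeps (drift beyond 1e-8 aborts).
#'
#' @param config A [configuration()].
#' @param n_sweeps Number of sweeps.
#' @param dipole,state Interaction specification, as in
#'   [total_pair_energy()].
#' @param d_trans,d_rot Maximum translation (sigma) and rotation (radians).
#' @param tune Auto-tune amplitudes toward 30--50\% acceptance (use during
#'   equilibration only; tuning breaks detailed balance).
#' @param sample_every Sweeps between structure samples (0 disables).
#' @param pairs Character vector of site-pair labels to histogram, e.g.
#'   `"C-C"`, `"O-O"`, `"O-P"`, `"V1-V3"`.
#' @param bin_width Histogram bin width, sigma units.
#' @param n_blocks Number of equal blocks for statistical errors.
#' @param revalidate_every Sweeps between full-energy revalidations.
#' @return List with the updated `config`, per-sweep reduced-energy traces
#'   `esw_trace` / `edd_trace`, acceptance trace, possibly histograms, and
#'   final move amplitudes.
#' @export
metropolis_sweep <- function(config, n_sweeps, dipole = dipole_spec(),
                             state = thermo_state(beta_eps = 0, eta = 0.3,
                                                  n = nrow(config$pos)),
                             d_trans = 0.15, d_rot = 0.4, tune = FALSE,
                             sample_every = 0L, pairs = character(),
                             bin_width = 0.02, n_blocks = 20L,
                             revalidate_every = 1000L) {
  cm <- as_cmodel(config$geometry, dipole, state, config$box)
  hs <- hist_groups(config$geometry, pairs, cm)
  nbins <- max(1L, floor((config$box / 2) / bin_width))
  res <- cpp_mc_run(cm, config$pos, config$quat, as.integer(n_sweeps),
                    d_trans, d_rot, as.integer(sample_every), hs,
                    bin_width, nbins, as.integer(n_blocks), tune, 100L,
                    as.integer(revalidate_every))
  out <- list(
    config = configuration(res$pos, res$quat, config$box, config$geometry),
    esw_trace = res$esw_trace, edd_trace = res$edd_trace,
    acc_trace = res$acc_trace, acceptance = mean(res$acc_trace),
    d_trans = res$d_trans, d_rot = res$d_rot,
    E_sw = res$E_sw, E_dd = res$E_dd)
  if (length(pairs)) {
    out$hist <- res$hist
    out$hist_pairs <- pairs
    out$block_samples <- res$block_samples
    out$n_samples <- res$n_samples
    out$bin_width <- bin_width
  }
  out
}

# site index groups for histogramming: -1 denotes the molecular center
hist_groups <- function(geometry, pairs, cm) {
  if (!length(pairs)) return(list())
  tag <- model_tag(geometry)
  groups <- switch(tag,
    pm = list(O = -1L, C = -1L, P = c(0L, 1L), N = 2L),
    ht = list(C = -1L, V = 0:3, V1 = c(0L, 1L), V3 = c(2L, 3L)),
    list(C = -1L))
  lapply(pairs, function(p) {
    ab <- strsplit(p, "-", fixed = TRUE)[[1L]]
    if (length(ab) != 2L || !all(ab %in% names(groups))) {
      stop(sprintf("unknown site pair '%s' for model '%s'", p, tag))
    }
    list(a = groups[[ab[1L]]], b = groups[[ab[2L]]], name = p)
  })
}

#' Equilibration check on an energy trace
#'
#' The final `window` points are split in half; the trace is declared
#' equilibrated when the two half-window means differ by less than twice
#' their pooled standard error (batch means absorb autocorrelation).  The
#' same test slid from the start of the trace yields a suggested production
#' start.
#'
#' @param trace Numeric vector of per-sweep energies.
#' @param window Window length (default: half the trace, at least 40).
#' @param n_batches Batches per half-window for the standard errors.
#' @return List with `equilibrated`, `suggested_start` (NA when no window
#'   passes) and a `diagnostic` message.
#' @export
monitor_equilibration <- function(trace, window = NULL, n_batches = 8L) {
  n <- length(trace)
  if (is.null(window)) window <- max(40L, floor(n / 2))
  window <- as.integer(window)
  if (n < window) {
    return(list(equilibrated = FALSE, suggested_start = NA_integer_,
                diagnostic = sprintf("trace (%d) shorter than window (%d)",
                                     n, window)))
  }
  half_test <- function(x) {
    h <- length(x) %/% 2L
    a <- x[seq_len(h)]
    b <- x[(h + 1L):(2L * h)]
    bm <- function(y) {
      k <- max(2L, min(n_batches, length(y) %/% 4L))
      means <- vapply(split(y, cut(seq_along(y), k, labels = FALSE)),
                      mean, numeric(1))
      sd(means) / sqrt(k)
    }
    se <- sqrt(bm(a)^2 + bm(b)^2)
    abs(mean(a) - mean(b)) <= 2 * se
  }
  starts <- unique(c(seq(1L, n - window + 1L, by = max(1L, window %/% 2L)),
                     n - window + 1L))
  pass <- vapply(starts, function(s) half_test(trace[s:(s + window - 1L)]),
                 logical(1))
  list(
    equilibrated = pass[length(pass)],
    suggested_start = if (any(pass)) starts[which(pass)[1L]] else NA_integer_,
    diagnostic = if (pass[length(pass)]) "stationary within 2 SE"
                 else "half-window means differ by more than 2 SE")
}
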