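# End-to-end simulation driver: initial configuration, tuned equilibration,
# production sampling, and the derived structural/energetic observables.

#' Run a full NVT Monte Carlo simulation
#'
#' Builds an overlap-free starting configuration, equilibrates with
#' amplitude auto-tuning (30--50\% target acceptance; amplitudes are frozen
#' afterwards so production obeys detailed balance), monitors the energy
#' trace for stationarity, then runs production with periodic structure
#' sampling.  Everything is driven by R's RNG seeded once from
#' `cfg$seed`, so results are fully reproducible.
#'
#' @param cfg A [run_config()].
#' @param init Optional starting [configuration()] (e.g. a snapshot read
#'   with [read_snapshot()]); when given, the lattice construction is
#'   skipped but the RNG is still seeded from `cfg$seed`.
#' @param verbose Print progress lines.
#' @return An object of class `mc_run` with the final configuration,
#'   energy traces, correlation functions (with per-bin block standard
#'   errors), the first-minimum location `r_min` and coordination number
#'   `n_c` of the center-center function, and a block-averaged energy
#'   `summary`.
#' @export
run_simulation <- function(cfg, init = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  if (is.null(init)) {
    init <- build_initial_config(cfg$n, cfg$eta, cfg$geometry, seed = cfg$seed)
  } else {
    stopifnot(inherits(init, "configuration"))
    set.seed(cfg$seed)
  }
  if (verbose) {
    message(sprintf("[%s] N=%d eta=%.3f box=%.3f lambda=%g mode=%s",
                    cfg$model, cfg$n, cfg$eta, cfg$box, cfg$lambda,
                    cfg$dipole$mode))
  }
  conf <- init
  dt <- cfg$d_trans
  dr <- cfg$d_rot
  equil <- NULL
  monitor <- NULL
  if (cfg$n_equil > 0) {
    eq <- metropolis_sweep(conf, cfg$n_equil, cfg$dipole, cfg$state,
                           dt, dr, tune = TRUE,
                           revalidate_every = cfg$revalidate_every)
    conf <- eq$config
    dt <- eq$d_trans
    dr <- eq$d_rot
    monitor <- monitor_equilibration(eq$esw_trace + eq$edd_trace)
    if (!isTRUE(monitor$equilibrated)) {
      warning("energy trace not stationary at the end of equilibration: ",
              monitor$diagnostic)
    }
    equil <- list(esw_trace = eq$esw_trace, edd_trace = eq$edd_trace,
                  acceptance = eq$acceptance)
    if (verbose) {
      message(sprintf("  equilibration: %d sweeps, acc %.2f, d_trans %.3f, d_rot %.3f",
                      cfg$n_equil, eq$acceptance, dt, dr))
    }
  }

  pr <- metropolis_sweep(conf, cfg$n_prod, cfg$dipole, cfg$state, dt, dr,
                         tune = FALSE, sample_every = cfg$sample_every,
                         pairs = cfg$pairs, bin_width = cfg$bin_width,
                         n_blocks = cfg$n_blocks,
                         revalidate_every = cfg$revalidate_every)
  conf <- pr$config
  aud <- config_audit(conf, cfg$dipole, cfg$state)
  if (!aud$ok) stop("post-run audit found hard overlaps")

  # histograms -> correlation functions
  cm <- as_cmodel(cfg$geometry, cfg$dipole, cfg$state, cfg$box)
  groups <- hist_groups(cfg$geometry, cfg$pairs, cm)
  nbins <- dim(pr$hist)[1L]
  breaks <- seq(0, by = cfg$bin_width, length.out = nbins + 1L)
  hists <- list()
  g <- list()
  for (s in seq_along(cfg$pairs)) {
    bc <- matrix(pr$hist[, s, ], nrow = nbins)
    h <- new_pair_histogram(
      counts = rowSums(bc), breaks = breaks, pair = cfg$pairs[s],
      n_samples = pr$n_samples, n = cfg$n, box = cfg$box,
      n_a = length(groups[[s]]$a), n_b = length(groups[[s]]$b),
      block_counts = bc, block_samples = pr$block_samples)
    hists[[cfg$pairs[s]]] <- h
    g[[cfg$pairs[s]]] <- normalize_g(h)
  }

  summary <- energy_summary(pr$esw_trace, pr$edd_trace, cfg$n,
                            cfg$state$beta_eps, cfg$n_blocks)
  cc <- intersect(c("C-C", "O-O"), cfg$pairs)
  r_min <- NA_real_
  n_c <- NA_real_
  if (length(cc)) {
    gcc <- g[[cc[1L]]]
    r_min <- tryCatch(find_first_minimum(gcc), error = function(e) NA_real_)
    if (is.finite(r_min)) {
      n_c <- coordination_number(gcc, r_min, rho = cfg$n / cfg$box^3)
    }
  }
  if (verbose) {
    message(sprintf(
      "  production: %d sweeps, acc %.2f, beta E/N = %.4f +- %.4f, N_C = %.3f",
      cfg$n_prod, pr$acceptance, summary$e_total, summary$se, n_c))
  }
  structure(list(
    config = cfg, final = conf,
    equil = equil, monitor = monitor,
    prod = list(esw_trace = pr$esw_trace, edd_trace = pr$edd_trace,
                acc_trace = pr$acc_trace),
    acceptance = pr$acceptance, d_trans = dt, d_rot = dr,
    hist = hists, g = g, summary = summary, r_min = r_min, n_c = n_c,
    audit = aud, elapsed = proc.time()[["elapsed"]] - t0
  ), class = "mc_run")
}

#' @export
print.mc_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<mc_run> %s N=%d eta=%.3f mode=%s lambda=%g\n",
              x$config$model, x$config$n, x$config$eta,
              x$config$dipole$mode, x$config$dipole$lambda))
  cat(sprintf("  beta E/N = %.4f +- %.4f (sw %.4f, dd %.4f)\n",
              s$e_total, s$se, s$e_sw, s$e_dd))
  if (is.finite(s$e_total_well)) {
    cat(sprintf("  E/N in well-depth units = %.4f +- %.4f\n",
                s$e_total_well, s$se_well))
  }
  if (is.finite(x$n_c)) {
    cat(sprintf("  R_min = %.3f, N_C = %.3f\n", x$r_min, x$n_c))
  }
  cat(sprintf("  acceptance %.3f, %.1f s elapsed\n", x$acceptance, x$elapsed))
  invisible(x)
}
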