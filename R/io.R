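# Snapshot and result-file handling.  Snapshots are extended-XYZ-style plain
# text; all numeric tables are TSV.  Output formatting is fixed so that
# re-running a write on the same inputs is byte-identical.

fmt <- function(x) sprintf("%.17g", x)

#' Write a configuration snapshot
#'
#' Extended-XYZ-style text: first line the particle count, second line
#' `key=value` metadata (box edge, model tag, sweep index), then one line
#' per particle with the center coordinates and the orientation quaternion.
#' The full double precision is kept (`%.17g`), so write -> read -> write
#' round-trips bit-exactly.
#'
#' @param config A [configuration()].
#' @param path Output file path.
#' @param sweep Sweep index recorded in the comment line.
#' @return The path, invisibly.
#' @export
write_snapshot <- function(config, path, sweep = 0L) {
  stopifnot(inherits(config, "configuration"))
  n <- nrow(config$pos)
  lines <- c(
    as.character(n),
    sprintf("box=%s model=%s sweep=%d columns=x_y_z_qw_qx_qy_qz",
            fmt(config$box), config$model, as.integer(sweep)),
    vapply(seq_len(n), function(i) {
      paste(c(fmt(config$pos[i, ]), fmt(config$quat[i, ])), collapse = " ")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a configuration snapshot
#'
#' @param path Snapshot file written by [write_snapshot()].
#' @param geometry Optional geometry object; by default the model tag from
#'   the comment line selects the default geometry (note that non-default
#'   primitive-model site parameters are not stored in snapshots and must be
#'   re-supplied here).
#' @return A [configuration()].
#' @export
read_snapshot <- function(path, geometry = NULL) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(lines[1L])
  meta <- strsplit(strsplit(lines[2L], " ", fixed = TRUE)[[1L]], "=",
                   fixed = TRUE)
  meta <- setNames(
    vapply(meta, `[`, character(1), 2L),
    vapply(meta, `[`, character(1), 1L))
  box <- as.numeric(meta[["box"]])
  tag <- meta[["model"]]
  rows <- do.call(rbind, lapply(lines[3:(2L + n)], function(ln) {
    as.numeric(strsplit(ln, " ", fixed = TRUE)[[1L]])
  }))
  if (is.null(geometry)) geometry <- tag
  configuration(rows[, 1:3, drop = FALSE], rows[, 4:7, drop = FALSE],
                box, geometry)
}

#' Write the result files of a run
#'
#' Emits, under `out_dir`: the final snapshot (`snapshot.xyz`), the
#' per-sweep production energy trace (`energy_trace.tsv`: sweep, square-well
#' and dipolar reduced energy, acceptance), one `g_<pair>.tsv` per sampled
#' correlation function (columns r, g, se), a one-row `summary.tsv`, and an
#' echo of the fully-resolved configuration (`config.cfg`).
#'
#' @param run An `mc_run` from [run_simulation()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_results <- function(run, out_dir) {
  stopifnot(inherits(run, "mc_run"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir)
  }
  paths <- character()
  p <- file.path(out_dir, "snapshot.xyz")
  write_snapshot(run$final, p, sweep = run$config$n_equil + run$config$n_prod)
  paths <- c(paths, p)

  tr <- run$prod
  p <- file.path(out_dir, "energy_trace.tsv")
  writeLines(c("sweep\tesw\tedd\tacceptance",
               sprintf("%d\t%s\t%s\t%s", seq_along(tr$esw_trace),
                       fmt(tr$esw_trace), fmt(tr$edd_trace),
                       fmt(tr$acc_trace))), p)
  paths <- c(paths, p)

  for (pair in names(run$g)) {
    gdf <- run$g[[pair]]
    p <- file.path(out_dir, sprintf("g_%s.tsv", gsub("-", "", pair)))
    writeLines(c("r\tg\tse",
                 sprintf("%s\t%s\t%s", fmt(gdf$r), fmt(gdf$g),
                         ifelse(is.na(gdf$se), "NA", fmt(gdf$se)))), p)
    paths <- c(paths, p)
  }

  s <- run$summary
  p <- file.path(out_dir, "summary.tsv")
  writeLines(c(
    paste(c("model", "mode", "lambda", "eta", "beta_eps", "n", "e_sw", "e_dd",
            "e_total", "se", "e_total_well", "se_well", "r_min", "n_c",
            "acceptance"), collapse = "\t"),
    paste(c(run$config$model, run$config$dipole$mode,
            fmt(run$config$dipole$lambda), fmt(run$config$eta),
            fmt(run$config$state$beta_eps), as.character(run$config$n),
            fmt(s$e_sw), fmt(s$e_dd), fmt(s$e_total), fmt(s$se),
            fmt(s$e_total_well), fmt(s$se_well), fmt(run$r_min),
            fmt(run$n_c), fmt(run$acceptance)), collapse = "\t")), p)
  paths <- c(paths, p)

  p <- file.path(out_dir, "config.cfg")
  writeLines(config_echo(run$config), p)
  paths <- c(paths, p)
  invisible(paths)
}

# fully-resolved key=value echo of a run_config
config_echo <- function(cfg) {
  keys <- names(config_schema())
  vapply(keys, function(k) {
    v <- cfg[[k]]
    if (length(v) > 1L) v <- paste(v, collapse = ",")
    if (is.numeric(v)) v <- ifelse(is.na(v), "NA", sprintf("%.17g", v))
    sprintf("%s = %s", k, as.character(v))
  }, character(1))
}
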