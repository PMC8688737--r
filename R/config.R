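# Run configuration: schema-validated key-value configs, named presets, and
# the constructor that assembles geometry / dipole / state objects for a run.

# schema: name -> list(type, default (may be quote for model-dependent), check)
config_schema <- function() {
  list(
    model        = list(type = "character", default = "hs",
                        check = function(x) x %in% c("pm", "ht", "hs", "ideal")),
    eta          = list(type = "numeric", default = 0.35,
                        check = function(x) x > 0 && x < 0.74),
    lambda       = list(type = "numeric", default = 0,
                        check = function(x) x >= 0),
    dipole_mode  = list(type = "character", default = "none",
                        check = function(x) x %in% c("none", "screened", "full")),
    beta_eps     = list(type = "numeric", default = 0,
                        check = function(x) x >= 0),
    n            = list(type = "integer", default = 216L,
                        check = function(x) x >= 2),
    n_equil      = list(type = "integer", default = 20000L,
                        check = function(x) x >= 0),
    n_prod       = list(type = "integer", default = 50000L,
                        check = function(x) x >= 1),
    sample_every = list(type = "integer", default = 25L,
                        check = function(x) x >= 1),
    d_trans      = list(type = "numeric", default = 0.12,
                        check = function(x) x > 0),
    d_rot        = list(type = "numeric", default = 0.35,
                        check = function(x) x > 0),
    seed         = list(type = "integer", default = 42L,
                        check = function(x) is.finite(x)),
    r_lo         = list(type = "numeric", default = 4 / 2.653,
                        check = function(x) x > 0),
    r_hi         = list(type = "numeric", default = 6 / 2.653,
                        check = function(x) x > 0),
    r_c          = list(type = "numeric", default = NA_real_,  # NA = box/2
                        check = function(x) is.na(x) || x > 0),
    l0           = list(type = "numeric", default = NA_real_,  # NA = by model
                        check = function(x) is.na(x) || (x > 0 && x < 1)),
    eps_r        = list(type = "numeric", default = Inf,
                        check = function(x) x > 0),
    switch_scale = list(type = "character", default = "sigma",
                        check = function(x) x %in% c("sigma", "contact")),
    bin_width    = list(type = "numeric", default = 0.02,
                        check = function(x) x > 0),
    pairs        = list(type = "character", default = NA_character_,
                        check = function(x) TRUE),
    d_pp         = list(type = "numeric", default = 0.45,
                        check = function(x) x > 0),
    d_nn         = list(type = "numeric", default = 0.45,
                        check = function(x) x > 0),
    r_sw         = list(type = "numeric", default = 0.55,
                        check = function(x) x > 0 && x < 1),
    hoh_angle_deg = list(type = "numeric", default = 104.52,
                         check = function(x) x > 0 && x < 180),
    n_offset     = list(type = "numeric", default = 0.15 / 2.653,
                        check = function(x) x > 0 && x < 0.5),
    n_blocks     = list(type = "integer", default = 20L,
                        check = function(x) x >= 2),
    revalidate_every = list(type = "integer", default = 1000L,
                            check = function(x) x >= 0),
    out_dir      = list(type = "character", default = NA_character_,
                        check = function(x) TRUE)
  )
}

#' Assemble a validated run configuration
#'
#' Accepts any subset of the configuration keys (see the schema in
#' `load_config()`'s documentation or any preset file) and fills the rest
#' with defaults.  All validation failures are reported together.
#'
#' @param ... Configuration values by key, e.g. `model = "pm"`, `eta = 0.35`.
#' @param quiet Suppress the echo of defaulted physics parameters.
#' @return An object of class `run_config` holding the resolved geometry,
#'   dipole specification, thermodynamic state, box size and run parameters.
#' @export
run_config <- function(..., quiet = TRUE) {
  vals <- list(...)
  if (!is.null(vals$pairs)) vals$pairs <- paste(vals$pairs, collapse = ",")
  schema <- config_schema()
  unknown <- setdiff(names(vals), names(schema))
  problems <- character()
  if (length(unknown)) {
    problems <- c(problems, sprintf("unknown key '%s'", unknown))
  }
  out <- list()
  defaulted <- character()
  for (key in names(schema)) {
    sc <- schema[[key]]
    if (key %in% names(vals)) {
      v <- vals[[key]]
      v <- switch(sc$type,
                  integer = suppressWarnings(as.integer(v)),
                  numeric = suppressWarnings(as.numeric(v)),
                  as.character(v))
      if (length(v) != 1L || (sc$type != "character" && is.na(v) &&
                              !identical(key, "r_c") && !identical(key, "l0"))) {
        problems <- c(problems, sprintf("field '%s': invalid value", key))
        v <- sc$default
      } else if (!isTRUE(sc$check(v))) {
        problems <- c(problems,
                      sprintf("field '%s': value %s fails validation", key,
                              format(v)))
      }
      out[[key]] <- v
    } else {
      out[[key]] <- sc$default
      defaulted <- c(defaulted, key)
    }
  }
  if (length(problems)) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }

  # model-dependent defaults
  if (is.na(out$l0)) out$l0 <- if (out$model == "ht") 0.001 else 0.01
  if (is.na(out$pairs)) {
    out$pairs <- if (out$model == "pm") "O-O" else "C-C"
  } else {
    out$pairs <- strsplit(out$pairs, ",", fixed = TRUE)[[1L]]
  }
  r_lo <- out$r_lo
  r_hi <- out$r_hi
  if (out$model == "ht" && out$switch_scale == "contact") {
    r_lo <- r_lo / 3
    r_hi <- r_hi / 3
  }

  geometry <- switch(out$model,
    pm = pm_geometry(hoh_angle_deg = out$hoh_angle_deg,
                     n_offset = out$n_offset, d_pp = out$d_pp,
                     d_nn = out$d_nn, r_sw = out$r_sw),
    ht = ht_geometry(),
    out$model)
  box <- density_to_box(out$eta, out$n, geometry)
  r_c <- if (is.na(out$r_c)) box / 2 else out$r_c
  dip <- dipole_spec(lambda = out$lambda, mode = out$dipole_mode,
                     l0 = out$l0, r_lo = r_lo, r_hi = r_hi, r_c = r_c,
                     eps_r = out$eps_r)
  state <- thermo_state(beta_eps = out$beta_eps, eta = out$eta, n = out$n)

  cfg <- structure(c(out, list(
    geometry = geometry, dipole = dip, state = state, box = box,
    defaulted = defaulted)), class = "run_config")
  if (!quiet && length(defaulted)) {
    phys <- intersect(defaulted, c("eta", "lambda", "dipole_mode", "beta_eps",
                                   "r_lo", "r_hi", "r_c", "l0", "eps_r",
                                   "d_pp", "d_nn", "r_sw", "hoh_angle_deg",
                                   "n_offset"))
    if (length(phys)) {
      message("defaulted physics parameters: ", paste(phys, collapse = ", "))
    }
  }
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (key in names(config_schema())) {
    v <- x[[key]]
    cat(sprintf("  %-16s %s%s\n", key, paste(format(v), collapse = ","),
                if (key %in% x$defaulted) "   (default)" else ""))
  }
  cat(sprintf("  %-16s %.6f\n", "box", x$box))
  invisible(x)
}

#' Load a run configuration from a key-value file
#'
#' The file format is plain text, one `key = value` pair per line; blank
#' lines and lines starting with `#` are ignored.  Unknown keys are
#' rejected; all schema violations are reported at once.  An empty file
#' yields the all-defaults configuration.  The `hs` model is the primitive
#' model with every site interaction switched off, i.e. pure hard spheres.
#'
#' @param path Path to the configuration file, or the name of a shipped
#'   preset (see [preset_names()]).
#' @param quiet Suppress the echo of defaulted physics parameters.
#' @return A [run_config()].
#' @export
load_config <- function(path, quiet = TRUE) {
  if (!file.exists(path)) {
    preset <- system.file("presets", paste0(path, ".cfg"),
                          package = "hardwater")
    if (nzchar(preset)) path <- preset else stop("config file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vals <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    vals[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  if (!is.null(vals$eps_r) && tolower(vals$eps_r) %in% c("inf", "infinity")) {
    vals$eps_r <- Inf
  }
  do.call(run_config, c(vals, list(quiet = quiet)))
}

#' Names of the shipped preset configurations
#'
#' Presets cover the published state points of both models: the primitive
#' model at `beta_eps = 8`, `eta = 0.35` with `lambda` 0/3/7 in all dipole
#' modes, the hard-sphere comparison fluid, and the hard-tetrahedron fluid
#' at `eta` 0.35 / 0.425 with `lambda = 1`.
#'
#' @return Character vector of preset names usable with [load_config()].
#' @export
preset_names <- function() {
  sub("\\.cfg$", "", dir(system.file("presets", package = "hardwater"),
                         pattern = "\\.cfg$"))
}
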