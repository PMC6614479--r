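#' Model and experiment configuration
#'
#' A `lac_config` bundles everything a run needs: the fixed biochemical
#' constants of the lac-operon model, the cost-function coefficients, the
#' allowed ranges of the five mutable regulatory parameters, the mutation
#' kernel, solver settings, and experiment defaults. All concentrations and
#' rates are in consistent arbitrary units; fitness is reported in benefit
#' units (lactose metabolized per unit time).
#'
#' The five mutable parameters, in their canonical order, are:
#' \describe{
#'   \item{bas1}{basal activity of the lac promoter (conc/time).}
#'   \item{bas2}{basal activity of the lacI promoter (conc/time).}
#'   \item{Ky}{numerator of the maximal lac-promoter activity (conc^2/time);
#'     `Ky/Kmy` is the activity at zero free LacI.}
#'   \item{Kmy}{half-saturation constant of promoter activity in free LacI
#'     (conc).}
#'   \item{Kt}{translational capacity of LacY relative to LacZ
#'     (dimensionless).}
#' }
#'
#' The packaged numeric defaults are not taken from any published table; they
#' were chosen so that the model is well-posed over the whole mutable box
#' (intracellular lactose reaches a finite steady state everywhere) and has a
#' nontrivial fitness maximum. See the methods vignette for the rationale
#' behind each value.
#'
#' @param fixed Named list of fixed constants: `kd1`, `kd2`, `kd3`
#'   (degradation rates of LacZ, LacY, LacI, 1/time), `K` (half-saturation of
#'   LacI-lactose binding, conc), `k1`, `k2` (lactose influx rate per LacY and
#'   its half-saturation), `k3`, `k4` (lactose metabolism rate per LacZ and
#'   its half-saturation), `lac_out` (extracellular lactose, the environment).
#' @param cost Named list: `alpha` (cost per protein molecule per unit time)
#'   and `alpha_z`, `alpha_y`, `alpha_i` (per-protein cost factors, by default
#'   the product of each protein's length relative to LacZ and its degradation
#'   constant).
#' @param mutable Named list of `c(min, max)` ranges for the five mutable
#'   parameters, in the order `bas1`, `bas2`, `Ky`, `Kmy`, `Kt`.
#' @param kernel Named list: `cv` (std of the normal proposal as a fraction of
#'   the current value), `policy` (`"resample"` or `"clip"` for out-of-range
#'   proposals), `max_attempts` (resample budget before clipping).
#' @param solver Named list: `method` (`"analytic"`, `"root"` or
#'   `"integrate"`), `tol` (relative residual tolerance on the right-hand
#'   side), `t_max` (integration horizon cap).
#' @param experiment Named list of experiment defaults: `fractions` (fitness
#'   levels as fractions of fmax), `n_sets`, `n_mutations`, `n_backgrounds`,
#'   `target_tol` (relative tolerance on achieved fitness), `neutral_epsilon`
#'   (|delta fitness| at or below which a mutation counts as neutral).
#'
#' @return An object of class `lac_config` (a validated named list).
#' @examples
#' cfg <- lac_config()
#' cfg$fixed$lac_out
#' @export
lac_config <- function(fixed = NULL, cost = NULL, mutable = NULL,
                       kernel = NULL, solver = NULL, experiment = NULL) {
  def <- default_config_blocks()
  cfg <- list(
    fixed      = utils::modifyList(def$fixed, fixed %||% list()),
    cost       = utils::modifyList(def$cost, cost %||% list()),
    mutable    = utils::modifyList(def$mutable, mutable %||% list()),
    kernel     = utils::modifyList(def$kernel, kernel %||% list()),
    solver     = utils::modifyList(def$solver, solver %||% list()),
    experiment = utils::modifyList(def$experiment, experiment %||% list())
  )
  validate_lac_config(structure(cfg, class = "lac_config"))
}

# Relative protein lengths (amino acids): LacZ 1023, LacY 417, LacI 360.
default_config_blocks <- function() {
  kd <- 0.02
  list(
    fixed = list(kd1 = kd, kd2 = kd, kd3 = kd, K = 10,
                 k1 = 1, k2 = 10, k3 = 1, k4 = 10, lac_out = 100),
    cost = list(alpha = 20,
                alpha_z = kd,
                alpha_y = 417 / 1023 * kd,
                alpha_i = 360 / 1023 * kd),
    mutable = list(bas1 = c(0, 0.5), bas2 = c(0.001, 2), Ky = c(0, 20),
                   Kmy = c(0.01, 50), Kt = c(0.01, 1)),
    kernel = list(cv = 0.1, policy = "resample", max_attempts = 100L),
    solver = list(method = "analytic", tol = 1e-9, t_max = 1e6),
    experiment = list(fractions = c(0.001, 0.1, 0.5), n_sets = 100L,
                      n_mutations = 10000L, n_backgrounds = 4000L,
                      target_tol = 0.01, neutral_epsilon = 0)
  )
}

#' @rdname lac_config
#' @export
mutable_params <- function() c("bas1", "bas2", "Ky", "Kmy", "Kt")

validate_lac_config <- function(cfg) {
  stopifnot(inherits(cfg, "lac_config"))
  need <- function(block, fields) {
    missing <- setdiff(fields, names(cfg[[block]]))
    if (length(missing)) {
      stop("config block '", block, "' is missing field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  need("fixed", c("kd1", "kd2", "kd3", "K", "k1", "k2", "k3", "k4", "lac_out"))
  need("cost", c("alpha", "alpha_z", "alpha_y", "alpha_i"))
  need("mutable", mutable_params())
  need("kernel", c("cv", "policy", "max_attempts"))
  need("solver", c("method", "tol", "t_max"))
  need("experiment", c("fractions", "n_sets", "n_mutations", "n_backgrounds",
                       "target_tol", "neutral_epsilon"))

  for (nm in names(cfg$fixed)) {
    v <- cfg$fixed[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("fixed parameter '", nm, "' must be a finite nonnegative number",
           call. = FALSE)
    }
  }
  for (nm in c("kd1", "kd2", "kd3")) {
    if (cfg$fixed[[nm]] <= 0) {
      stop("degradation constant '", nm, "' must be strictly positive",
           call. = FALSE)
    }
  }
  for (nm in names(cfg$cost)) {
    v <- cfg$cost[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("cost parameter '", nm, "' must be a finite nonnegative number",
           call. = FALSE)
    }
  }
  for (nm in mutable_params()) {
    rng <- as.numeric(cfg$mutable[[nm]])
    if (length(rng) != 2L || anyNA(rng) || rng[1] < 0 || rng[1] > rng[2]) {
      stop("mutable range for '", nm,
           "' must be c(min, max) with 0 <= min <= max", call. = FALSE)
    }
    cfg$mutable[[nm]] <- rng
  }
  if (!is.numeric(cfg$kernel$cv) || cfg$kernel$cv <= 0) {
    stop("kernel cv must be > 0", call. = FALSE)
  }
  if (!cfg$kernel$policy %in% c("resample", "clip")) {
    stop("kernel policy must be 'resample' or 'clip'", call. = FALSE)
  }
  if (!cfg$solver$method %in% c("analytic", "root", "integrate")) {
    stop("solver method must be 'analytic', 'root' or 'integrate'",
         call. = FALSE)
  }
  if (cfg$solver$tol <= 0) stop("solver tol must be > 0", call. = FALSE)
  ex <- cfg$experiment
  if (any(ex$fractions <= 0) || any(ex$fractions > 1)) {
    stop("experiment fractions must lie in (0, 1]", call. = FALSE)
  }
  if (ex$target_tol <= 0) stop("experiment target_tol must be > 0", call. = FALSE)
  if (ex$neutral_epsilon < 0) {
    stop("experiment neutral_epsilon must be >= 0", call. = FALSE)
  }
  cfg
}

#' Read or write a configuration file
#'
#' Configurations are serialized as YAML with the same six blocks as
#' [lac_config()]. A written file reloads to an identical configuration
#' (numbers are stored at full double precision).
#'
#' @param path Path to a YAML configuration file.
#' @return `read_lac_config()` returns a validated `lac_config`;
#'   `write_lac_config()` returns `path` invisibly.
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' write_lac_config(lac_config(), path)
#' cfg <- read_lac_config(path)
#' @export
read_lac_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), c("fixed", "cost", "mutable", "kernel", "solver",
                               "experiment"))
  if (length(bad)) {
    stop("unknown config block(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  mut <- raw$mutable
  if (!is.null(mut)) {
    mut <- lapply(mut, function(r) {
      if (is.list(r)) c(r$min, r$max) else as.numeric(r)
    })
  }
  lac_config(fixed = raw$fixed, cost = raw$cost, mutable = mut,
             kernel = raw$kernel, solver = raw$solver,
             experiment = raw$experiment)
}

#' @rdname read_lac_config
#' @param config A `lac_config` object.
#' @export
write_lac_config <- function(config, path) {
  config <- validate_lac_config(config)
  out <- unclass(config)
  out$mutable <- lapply(out$mutable, function(r) list(min = r[1], max = r[2]))
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}

#' Path to the packaged default configuration
#'
#' @return Path to the YAML file shipped in `inst/extdata`.
#' @examples
#' cfg <- read_lac_config(default_config_path())
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "lacdfe",
              mustWork = TRUE)
}

#' @export
print.lac_config <- function(x, ...) {
  cat("<lac_config>\n")
  cat("  fixed:     ", paste(sprintf("%s=%g", names(x$fixed), unlist(x$fixed)),
                             collapse = ", "), "\n")
  cat("  cost:      ", paste(sprintf("%s=%g", names(x$cost), unlist(x$cost)),
                             collapse = ", "), "\n")
  for (nm in mutable_params()) {
    cat(sprintf("  mutable %-4s [%g, %g]\n", nm, x$mutable[[nm]][1],
                x$mutable[[nm]][2]))
  }
  cat(sprintf("  kernel:     cv=%g, policy=%s\n", x$kernel$cv,
              x$kernel$policy))
  cat(sprintf("  solver:     method=%s, tol=%g\n", x$solver$method,
              x$solver$tol))
  invisible(x)
}

# Bounds of the mutable box as a 2 x 5 matrix (rows: min, max).
mutable_bounds <- function(config) {
  vapply(config$mutable[mutable_params()], identity, numeric(2))
}
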