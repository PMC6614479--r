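#' Estimate the maximum attainable fitness over the mutable box
#'
#' Runs bounded local optimization (L-BFGS-B) of the model fitness over the
#' five mutable regulatory parameters from a Latin-hypercube set of starting
#' points, with the fixed constants held at their configured values, and
#' reports the best optimum found. The landscape is smooth and
#' five-dimensional, so a modest number of scattered starts locates the
#' global maximum reliably; no global-optimality certificate is attempted.
#'
#' @param config A [lac_config()].
#' @param n_starts Number of Latin-hypercube starting points (default 32).
#' @param seed Integer seed controlling the starting points; the result is
#'   deterministic given the seed.
#' @return A `lac_fmax` object: a list with `fmax` (the best fitness found),
#'   `par` (a one-row tibble of the arg-max parameter set), `n_starts`, and
#'   `starts` (a tibble of all local optima found).
#' @examples
#' cfg <- lac_config()
#' fm <- estimate_fmax(cfg, n_starts = 8, seed = 1)
#' fm$fmax
#' @export
estimate_fmax <- function(config, n_starts = 32L, seed = NULL) {
  bounds <- mutable_bounds(config)
  lower <- bounds[1, ]
  upper <- bounds[2, ]
  span <- upper - lower
  degenerate <- all(span == 0)

  starts_unit <- with_seed_if(seed, {
    if (degenerate) matrix(0, nrow = 1L, ncol = 5L)
    else lhs::randomLHS(n_starts, 5L)
  })
  starts <- sweep(sweep(starts_unit, 2, span, `*`), 2, lower, `+`)
  colnames(starts) <- mutable_params()

  neg_fitness <- function(x) {
    names(x) <- mutable_params()
    f <- fitness_value(x, config)
    if (!is.finite(f)) 1e12 else -f
  }

  opt_one <- function(x0) {
    if (degenerate) {
      return(tibble::tibble(!!!as.list(x0), fitness = -neg_fitness(x0)))
    }
    o <- stats::optim(x0, neg_fitness, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500))
    tibble::tibble(!!!as.list(o$par), fitness = -o$value)
  }
  optima <- purrr::map_dfr(seq_len(nrow(starts)),
                           function(i) opt_one(starts[i, ]))
  if (all(!is.finite(optima$fitness)) || all(optima$fitness <= -1e11)) {
    stop("estimate_fmax: no starting point produced a converged fitness",
         call. = FALSE)
  }
  best <- which.max(optima$fitness)
  structure(
    list(fmax = optima$fitness[best],
         par = optima[best, mutable_params()],
         n_starts = nrow(starts),
         starts = optima),
    class = "lac_fmax"
  )
}

#' @export
print.lac_fmax <- function(x, ...) {
  cat(sprintf("<lac_fmax> fmax = %g (best of %d starts)\n", x$fmax,
              x$n_starts))
  cat("  at:", paste(sprintf("%s=%g", mutable_params(),
                             unlist(x$par)), collapse = ", "), "\n")
  invisible(x)
}

#' Sample parameter sets at a target fraction of fmax
#'
#' Generates `count` distinct parameter sets whose fitness lies within
#' `tolerance` (relative) of `fraction * fmax`, emulating the replicated
#' same-fitness backgrounds of the study design (100 sets per fitness level).
#'
#' Each set starts from a uniform draw in the mutable box. If the draw does
#' not already bracket the target along some coordinate, the sampler makes
#' greedy 1-D uphill moves along randomly ordered coordinates (bounded line
#' maximization) until the target fitness is bracketed, then solves for the
#' exact crossing with 1-D root finding along a single coordinate. This keeps
#' the accepted sets scattered rather than clustered around the optimizer
#' path. Sets closer to `fmax` take more work to find, mirroring the
#' increasing sparsity of high-fitness parameter sets.
#'
#' @param config A [lac_config()].
#' @param fraction Target fitness as a fraction of `fmax`, in (0, 1].
#' @param count Number of distinct sets requested.
#' @param fmax Maximum-fitness estimate (see [estimate_fmax()]). If `NULL`,
#'   it is estimated internally with the same seed.
#' @param tolerance Acceptable relative deviation of achieved fitness from
#'   the target (default `config$experiment$target_tol`, 1%).
#' @param seed Integer seed; collections are reproducible given the seed.
#' @param max_proposals Total proposal budget before giving up with a
#'   shortfall.
#' @return A `lac_param_sets` tibble with columns `set_id`, the five mutable
#'   parameters, `fitness`, `fraction` and `fmax_used`, plus attributes
#'   `shortfall` (sets requested but not found) and `n_proposals`. Zero sets
#'   found is an error; a partial result carries a warning and a positive
#'   `shortfall` attribute.
#' @examples
#' cfg <- lac_config()
#' fm <- estimate_fmax(cfg, n_starts = 8, seed = 1)
#' sets <- sample_at_fitness(cfg, fraction = 0.001, count = 5, fmax = fm$fmax,
#'                           seed = 1)
#' @export
sample_at_fitness <- function(config, fraction, count = 100L, fmax = NULL,
                              tolerance = NULL, seed = NULL,
                              max_proposals = 200L * count) {
  stopifnot(fraction > 0, fraction <= 1, count >= 1)
  tolerance <- tolerance %||% config$experiment$target_tol
  if (is.null(fmax)) fmax <- estimate_fmax(config, seed = seed)$fmax
  target <- fraction * fmax
  if (target > fmax) stop("target fitness exceeds fmax", call. = FALSE)

  bounds <- mutable_bounds(config)
  lower <- bounds[1, ]
  upper <- bounds[2, ]
  nm <- mutable_params()

  accepted <- list()
  n_prop <- 0L

  ok <- function(f) is.finite(f) && abs(f - target) <= tolerance * abs(target)

  with_seed_if(seed, {
    while (length(accepted) < count && n_prop < max_proposals) {
      n_prop <- n_prop + 1L
      p <- stats::runif(5L, lower, upper)
      names(p) <- nm
      p <- refine_to_target(p, target, config, lower, upper, tolerance)
      if (is.null(p)) next
      f <- fitness_value(p, config)
      if (!ok(f)) next
      if (is_duplicate(p, accepted)) next
      accepted[[length(accepted) + 1L]] <- c(p, fitness = f)
    }
  })

  if (length(accepted) == 0L) {
    stop("sample_at_fitness: no parameter set found at fraction ", fraction,
         " within the proposal budget", call. = FALSE)
  }
  shortfall <- as.integer(count - length(accepted))
  if (shortfall > 0L) {
    warning("sample_at_fitness: found only ", length(accepted), " of ",
            count, " requested sets at fraction ", fraction, call. = FALSE)
  }
  out <- dplyr::bind_rows(lapply(accepted, function(x) tibble::as_tibble(as.list(x))))
  out <- dplyr::mutate(out,
                       set_id = dplyr::row_number(),
                       fraction = fraction,
                       fmax_used = fmax,
                       .before = 1)
  out <- dplyr::relocate(out, "set_id", dplyr::all_of(nm), "fitness",
                         "fraction", "fmax_used")
  structure(out, shortfall = shortfall, n_proposals = n_prop,
            class = c("lac_param_sets", class(out)))
}

# Distinctness: a candidate duplicates an accepted set if every mutable
# parameter agrees to 1e-6 relative.
is_duplicate <- function(p, accepted) {
  nm <- mutable_params()
  for (a in accepted) {
    rel <- abs(p[nm] - a[nm]) / pmax(abs(a[nm]), 1e-12)
    if (all(rel <= 1e-6)) return(TRUE)
  }
  FALSE
}

# Move a uniform proposal onto the target-fitness surface: try a 1-D root
# find along each coordinate (random order); if no coordinate brackets the
# target, climb greedily (1-D bounded maximization along random coordinates)
# and retry. Returns NULL on failure.
refine_to_target <- function(p, target, config, lower, upper, tolerance) {
  nm <- mutable_params()
  f_at <- function(p, j, x) {
    q <- p
    q[j] <- x
    fitness_value(q, config)
  }
  try_cross <- function(p) {
    f0 <- fitness_value(p, config)
    if (!is.finite(f0)) return(NULL)
    if (abs(f0 - target) <= tolerance * abs(target)) return(p)
    for (j in sample(nm)) {
      if (upper[[which(nm == j)]] <= lower[[which(nm == j)]]) next
      lo <- lower[[which(nm == j)]]
      hi <- upper[[which(nm == j)]]
      g <- function(x) f_at(p, j, x) - target
      # pick an endpoint on the opposite side of the target from p
      for (end in sample(c(lo, hi))) {
        ge <- g(end)
        g0 <- f0 - target
        if (!is.finite(ge) || ge * g0 > 0) next
        root <- tryCatch(
          stats::uniroot(g, sort(c(p[[j]], end)), tol = 1e-12 * max(1, hi))$root,
          error = function(e) NULL)
        if (is.null(root)) next
        q <- p
        q[j] <- root
        return(q)
      }
    }
    NULL
  }
  res <- try_cross(p)
  if (!is.null(res)) return(res)
  # Greedy uphill: whenever the target becomes reachable along the current
  # coordinate, root-find the crossing immediately (so coordinates are moved
  # to their 1-D optima only when the climb requires it); otherwise move the
  # most promising coordinate to its 1-D maximum and repeat.
  for (pass in 1:10) {
    f0 <- fitness_value(p, config)
    if (!is.finite(f0)) return(NULL)
    best <- NULL
    for (j in sample(nm)) {
      idx <- which(nm == j)
      if (upper[[idx]] <= lower[[idx]]) next
      o <- stats::optimize(function(x) f_at(p, j, x),
                           lower = lower[[idx]], upper = upper[[idx]],
                           maximum = TRUE, tol = 1e-10)
      if (!is.finite(o$objective)) next
      if (o$objective >= target && f0 < target) {
        g <- function(x) f_at(p, j, x) - target
        root <- tryCatch(
          stats::uniroot(g, sort(c(p[[j]], o$maximum)),
                         tol = 1e-12 * max(1, upper[[idx]]))$root,
          error = function(e) NULL)
        if (!is.null(root)) {
          p[j] <- root
          return(p)
        }
      }
      if (is.null(best) || o$objective > best$objective) {
        best <- list(j = j, objective = o$objective, maximum = o$maximum)
      }
    }
    if (is.null(best) || best$objective <= f0 + 1e-12) break
    p[best$j] <- best$maximum
  }
  try_cross(p)
}
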