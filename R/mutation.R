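#' Propose single-parameter mutations
#'
#' Each mutation picks one of the five mutable regulatory parameters
#' uniformly at random and redraws its value from a normal distribution
#' centred on the current value with standard deviation `cv * current value`
#' (a multiplicative kernel, so parameters on different scales experience
#' comparable relative perturbations). When the current value is exactly
#' zero, the standard deviation falls back to `cv * (max - min)` of that
#' parameter's range. Proposals outside the configured range are redrawn up
#' to `max_attempts` times and then clipped (`policy = "resample"`, the
#' default) or clipped immediately (`policy = "clip"`).
#'
#' @param background Named vector or one-row data frame holding the five
#'   mutable parameters of the starting set.
#' @param n Number of independent mutations to propose.
#' @param config A [lac_config()]; `config$kernel` and `config$mutable` are
#'   used.
#' @param seed Optional integer seed.
#' @return A tibble with columns `param_id`, `old_value`, `new_value`.
#' @examples
#' cfg <- lac_config()
#' bg <- c(bas1 = 0.1, bas2 = 0.5, Ky = 5, Kmy = 1, Kt = 0.5)
#' propose_mutations(bg, 5, cfg, seed = 1)
#' @export
propose_mutations <- function(background, n, config, seed = NULL) {
  bg <- as_param_vec(background)
  nm <- mutable_params()
  bounds <- mutable_bounds(config)
  kern <- config$kernel
  if (n == 0L) {
    return(tibble::tibble(param_id = character(), old_value = double(),
                          new_value = double()))
  }
  with_seed_if(seed, {
    idx <- sample.int(5L, n, replace = TRUE)
    old <- bg[nm][idx]
    lo <- bounds[1, idx]
    hi <- bounds[2, idx]
    sd <- kern$cv * abs(old)
    sd[old == 0] <- kern$cv * (hi - lo)[old == 0]
    draw <- function(m, s) stats::rnorm(length(m), m, s)
    new <- draw(old, sd)
    if (kern$policy == "resample") {
      for (i in seq_len(kern$max_attempts)) {
        bad <- which(new < lo | new > hi)
        if (!length(bad)) break
        new[bad] <- draw(old[bad], sd[bad])
      }
    }
    new <- pmin(pmax(new, lo), hi)
    tibble::tibble(param_id = nm[idx], old_value = unname(old),
                   new_value = unname(new))
  })
}

#' Build a distribution of fitness effects on one background
#'
#' Applies `n_mutations` independent single-parameter mutations to
#' `background`, recomputes the steady-state fitness of each mutant, and
#' records the fitness change `delta_fitness = fitness(mutant) -
#' fitness(background)`. The background fitness is computed once and reused.
#' Mutants whose steady state does not converge are excluded and counted in
#' the `n_failed` attribute rather than scored.
#'
#' @inheritParams propose_mutations
#' @param n_mutations Number of mutations (study scale: 10,000).
#' @param neutral_epsilon Threshold below which `|delta_fitness|` counts as
#'   neutral (default `config$experiment$neutral_epsilon`, 0).
#' @return A `lac_dfe` tibble with columns `param_id`, `old_value`,
#'   `new_value`, `fitness`, `delta_fitness`, `effect` (one of
#'   `"beneficial"`, `"deleterious"`, `"neutral"`); attributes `background`
#'   (named parameter vector), `background_fitness`, `neutral_epsilon`,
#'   `n_failed`.
#' @examples
#' cfg <- lac_config()
#' bg <- c(bas1 = 0.1, bas2 = 0.5, Ky = 5, Kmy = 1, Kt = 0.5)
#' dfe <- build_dfe(bg, 200, cfg, seed = 1)
#' classify_dfe(dfe)
#' @export
build_dfe <- function(background, n_mutations, config, seed = NULL,
                      neutral_epsilon = NULL) {
  bg <- as_param_vec(background)
  eps <- neutral_epsilon %||% config$experiment$neutral_epsilon
  f0 <- fitness_value(bg, config)
  if (!is.finite(f0)) {
    stop("background fitness is not computable (steady state did not converge)",
         call. = FALSE)
  }
  muts <- propose_mutations(bg, n_mutations, config, seed = seed)
  if (nrow(muts) == 0L) {
    out <- tibble::tibble(param_id = character(), old_value = double(),
                          new_value = double(), fitness = double(),
                          delta_fitness = double(), effect = character())
    return(new_lac_dfe(out, bg, f0, eps, 0L))
  }
  mutants <- tibble::as_tibble(lapply(as.list(bg), rep, nrow(muts)))
  for (p in unique(muts$param_id)) {
    rows <- muts$param_id == p
    mutants[[p]][rows] <- muts$new_value[rows]
  }
  f <- fitness_vec(mutants, config)
  failed <- !is.finite(f)
  muts$fitness <- f
  muts$delta_fitness <- f - f0
  muts <- muts[!failed, , drop = FALSE]
  muts$effect <- dplyr::case_when(
    muts$delta_fitness > eps ~ "beneficial",
    muts$delta_fitness < -eps ~ "deleterious",
    TRUE ~ "neutral"
  )
  new_lac_dfe(muts, bg, f0, eps, sum(failed))
}

new_lac_dfe <- function(df, background, background_fitness, eps, n_failed) {
  structure(df,
            background = background,
            background_fitness = background_fitness,
            neutral_epsilon = eps,
            n_failed = as.integer(n_failed),
            class = c("lac_dfe", class(tibble::as_tibble(df))))
}

#' Classify a DFE into beneficial, deleterious and neutral fractions
#'
#' A mutation is beneficial when `delta_fitness > neutral_epsilon`,
#' deleterious when `delta_fitness < -neutral_epsilon`, and neutral
#' otherwise. The three fractions sum to one.
#'
#' @param dfe A `lac_dfe` from [build_dfe()].
#' @param neutral_epsilon Optional override of the threshold stored in the
#'   sample.
#' @return A one-row tibble with columns `n`, `fraction_beneficial`,
#'   `fraction_deleterious`, `fraction_neutral`, `mean_beneficial_effect`
#'   (mean fitness gain of beneficial mutations, in fitness units),
#'   `mean_beneficial_s` (the same as a selection coefficient, i.e. divided
#'   by the background fitness; `NA` when the background fitness is unknown
#'   or nonpositive), `mean_deleterious_effect` (mean magnitude of
#'   deleterious effects).
#' @export
classify_dfe <- function(dfe, neutral_epsilon = NULL) {
  if (nrow(dfe) == 0L) stop("cannot classify an empty DFE sample", call. = FALSE)
  eps <- neutral_epsilon %||% attr(dfe, "neutral_epsilon") %||% 0
  d <- dfe$delta_fitness
  ben <- d > eps
  del <- d < -eps
  f0 <- attr(dfe, "background_fitness")
  mean_ben <- if (any(ben)) mean(d[ben]) else NA_real_
  tibble::tibble(
    n = length(d),
    fraction_beneficial = mean(ben),
    fraction_deleterious = mean(del),
    fraction_neutral = mean(!ben & !del),
    mean_beneficial_effect = mean_ben,
    mean_beneficial_s = if (!is.null(f0) && isTRUE(f0 > 0)) mean_ben / f0
                        else NA_real_,
    mean_deleterious_effect = if (any(del)) mean(abs(d[del])) else NA_real_
  )
}
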