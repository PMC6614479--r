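#' Run the DFE experiment across fitness levels
#'
#' For each requested fitness level (fraction of fmax), samples `n_sets`
#' distinct parameter sets at that fitness, builds a DFE of `n_mutations`
#' single mutations on each, classifies the mutations, fits exponentials to
#' the beneficial effects and to the deleterious effect magnitudes, and
#' counts peaks in the deleterious distribution. This reproduces the
#' study design of replicated same-fitness backgrounds at low (0.001 fmax),
#' medium (0.1 fmax) and high (0.5 fmax) starting fitness.
#'
#' Failures in any per-set stage (e.g. too few beneficial mutations to fit)
#' are recorded as `NA` fields in that set's row rather than aborting the
#' run.
#'
#' @param config A [lac_config()].
#' @param fractions Fitness levels as fractions of fmax (default
#'   `config$experiment$fractions`).
#' @param n_sets Parameter sets per level (default
#'   `config$experiment$n_sets`).
#' @param n_mutations Mutations per set (default
#'   `config$experiment$n_mutations`).
#' @param seed Root seed; per-level and per-set sub-seeds are derived
#'   deterministically, so the output table is reproducible.
#' @param fmax Optional precomputed fmax estimate; estimated internally if
#'   `NULL`.
#' @param sets Optional precomputed `lac_param_sets` (a single collection or
#'   list of collections, one per fraction); sampled internally if `NULL`.
#' @return A `lac_dfe_experiment` tibble with one row per (level, set):
#'   `fraction`, `set_id`, the five mutable parameters, `fitness`,
#'   `fraction_beneficial`, `fraction_deleterious`, `fraction_neutral`,
#'   `mean_beneficial_effect`, `mean_beneficial_s`, `lam_beneficial`, `r2_beneficial`,
#'   `lam_deleterious`, `r2_deleterious`, `n_peaks_deleterious`, `bimodal`,
#'   `n_failed`. Attribute `fmax` carries the estimate used.
#' @examples
#' cfg <- lac_config()
#' ex <- dfe_experiment(cfg, fractions = c(0.001, 0.1), n_sets = 2,
#'                      n_mutations = 200, seed = 1)
#' @export
dfe_experiment <- function(config, fractions = NULL, n_sets = NULL,
                           n_mutations = NULL, seed = 1L, fmax = NULL,
                           sets = NULL) {
  ex <- config$experiment
  fractions <- fractions %||% ex$fractions
  n_sets <- n_sets %||% ex$n_sets
  n_mutations <- n_mutations %||% ex$n_mutations
  seeds <- derive_seeds(seed, c("fmax", paste0("level_", seq_along(fractions))))
  if (is.null(fmax)) {
    fmax <- estimate_fmax(config, seed = seeds$fmax)$fmax
  }
  if (!is.null(sets) && inherits(sets, "lac_param_sets")) sets <- list(sets)

  level_rows <- purrr::map2(fractions, seq_along(fractions), function(fr, li) {
    coll <- if (!is.null(sets)) sets[[li]] else {
      sample_at_fitness(config, fraction = fr, count = n_sets, fmax = fmax,
                        seed = seeds[[paste0("level_", li)]])
    }
    set_seeds <- derive_seeds(seeds[[paste0("level_", li)]],
                              paste0("set_", coll$set_id))
    purrr::map_dfr(seq_len(nrow(coll)), function(i) {
      bg <- unlist(coll[i, mutable_params()])
      dfe_summary_row(bg, coll$fitness[i], fr, coll$set_id[i], n_mutations,
                      config, set_seeds[[i]])
    })
  })
  out <- dplyr::bind_rows(level_rows)
  structure(out, fmax = fmax,
            class = c("lac_dfe_experiment", class(tibble::as_tibble(out))))
}

dfe_summary_row <- function(bg, bg_fitness, fraction, set_id, n_mutations,
                            config, seed) {
  base <- tibble::tibble(fraction = fraction, set_id = set_id,
                         !!!as.list(bg), fitness = bg_fitness)
  res <- tryCatch({
    dfe <- build_dfe(bg, n_mutations, config, seed = seed)
    cls <- classify_dfe(dfe)
    ben <- dfe$delta_fitness[dfe$effect == "beneficial"]
    del <- abs(dfe$delta_fitness[dfe$effect == "deleterious"])
    fit_or_na <- function(x) {
      tryCatch(fit_exponential(x), error = function(e) NULL)
    }
    fb <- fit_or_na(ben)
    fd <- fit_or_na(del)
    peaks <- if (length(del) >= 50) detect_bimodality(del)$n_peaks else NA_integer_
    tibble::tibble(
      fraction_beneficial = cls$fraction_beneficial,
      fraction_deleterious = cls$fraction_deleterious,
      fraction_neutral = cls$fraction_neutral,
      mean_beneficial_effect = cls$mean_beneficial_effect,
      mean_beneficial_s = cls$mean_beneficial_s,
      lam_beneficial = fb$lam %||% NA_real_,
      r2_beneficial = fb$r2 %||% NA_real_,
      lam_deleterious = fd$lam %||% NA_real_,
      r2_deleterious = fd$r2 %||% NA_real_,
      n_peaks_deleterious = peaks,
      bimodal = if (is.na(peaks)) NA else peaks >= 2L,
      n_failed = attr(dfe, "n_failed")
    )
  }, error = function(e) {
    tibble::tibble(fraction_beneficial = NA_real_,
                   fraction_deleterious = NA_real_,
                   fraction_neutral = NA_real_,
                   mean_beneficial_effect = NA_real_,
                   mean_beneficial_s = NA_real_,
                   lam_beneficial = NA_real_, r2_beneficial = NA_real_,
                   lam_deleterious = NA_real_, r2_deleterious = NA_real_,
                   n_peaks_deleterious = NA_integer_, bimodal = NA,
                   n_failed = NA_integer_)
  })
  dplyr::bind_cols(base, res)
}
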