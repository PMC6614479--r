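#' Find a beneficial mutation in one parameter
#'
#' Repeatedly draws single-parameter mutations in `param_id` from the normal
#' mutation kernel until one increases fitness, up to `max_draws` proposals.
#' Near a 1-D optimum of that parameter no beneficial mutation may exist
#' within the budget; this raises a condition of class
#' `lacdfe_no_beneficial`.
#'
#' @param background Named vector or one-row data frame of the five mutable
#'   parameters.
#' @param param_id Which mutable parameter to mutate.
#' @param config A [lac_config()].
#' @param seed Optional integer seed.
#' @param max_draws Proposal budget (default 1000).
#' @return A one-row tibble: `param_id`, `old_value`, `new_value`,
#'   `delta_fitness` (> 0).
#' @export
find_beneficial_mutation <- function(background, param_id, config,
                                     seed = NULL, max_draws = 1000L) {
  bg <- as_param_vec(background)
  stopifnot(param_id %in% mutable_params())
  f0 <- fitness_value(bg, config)
  if (!is.finite(f0)) {
    stop("background fitness is not computable", call. = FALSE)
  }
  with_seed_if(seed, {
    for (i in seq_len(max_draws)) {
      m <- propose_one_in(bg, param_id, config)
      q <- bg
      q[param_id] <- m
      f1 <- fitness_value(q, config)
      if (is.finite(f1) && f1 > f0) {
        return(tibble::tibble(param_id = param_id,
                              old_value = unname(bg[param_id]),
                              new_value = m,
                              delta_fitness = f1 - f0))
      }
    }
    rlang::abort(
      paste0("no beneficial mutation found in '", param_id, "' within ",
             max_draws, " draws"),
      class = "lacdfe_no_beneficial")
  })
}

# Kernel draw restricted to one named parameter (same kernel as
# propose_mutations).
propose_one_in <- function(bg, param_id, config) {
  rng <- config$mutable[[param_id]]
  old <- bg[[param_id]]
  sd <- config$kernel$cv * abs(old)
  if (old == 0) sd <- config$kernel$cv * diff(rng)
  new <- stats::rnorm(1, old, sd)
  if (config$kernel$policy == "resample") {
    att <- 0L
    while ((new < rng[1] || new > rng[2]) &&
           att < config$kernel$max_attempts) {
      new <- stats::rnorm(1, old, sd)
      att <- att + 1L
    }
  }
  min(max(new, rng[1]), rng[2])
}

#' Pairwise epistasis scan between beneficial mutations
#'
#' Implements the two-background protocol for a focal beneficial mutation
#' `mu`: on the starting set `P0` (fitness `f0`), applying `mu` gives fitness
#' `f0*` and effect `delta_f = f0* - f0`. For each of `n_backgrounds`
#' backgrounds `PM` — `P0` carrying one other beneficial mutation in a
#' parameter different from the focal one, spread evenly over the four
#' non-focal parameters — re-applying the identical `mu` (same new value,
#' bit for bit) gives `fM*` and `delta_f_star = fM* - fM`. The record stores
#' both effects, their ratio `delta_f / delta_f_star`, and a sign-epistasis
#' flag (the two effects have opposite signs). Benefit and cost changes of
#' the focal mutation on both backgrounds are kept so sign-epistatic records
#' can be traced to their benefit-increasing vs cost-reducing origin.
#'
#' `fitness_fn` may replace the lac model with any function mapping a
#' parameter data frame to a fitness vector (used, for instance, to verify
#' that an additive fitness function yields no epistasis: every ratio
#' exactly 1).
#'
#' @param background Named vector or one-row data frame: the starting set
#'   `P0`.
#' @param focal Either a one-row mutation tibble (from
#'   [find_beneficial_mutation()]) or the name of a mutable parameter, in
#'   which case a beneficial focal mutation is searched for internally.
#' @param n_backgrounds Number of mutated backgrounds (study scale: 4000;
#'   default 200 keeps exploratory runs fast).
#' @param config A [lac_config()].
#' @param seed Integer seed; the scan is reproducible given the seed.
#' @param fitness_fn Optional replacement fitness: `function(params_df) ->
#'   numeric`. Defaults to the lac-model fitness. Benefit/cost columns are
#'   `NA` under a replacement fitness.
#' @param max_draws Per-background search budget for the beneficial
#'   background mutation.
#' @return A `lac_epistasis` tibble, one row per background: `focal_param`,
#'   `focal_old`, `focal_new`, `background_param`, `background_old`,
#'   `background_new`, `f0`, `f0_star`, `delta_f`, `fM`, `fM_star`,
#'   `delta_f_star`, `ratio` (`NA` when `delta_f_star == 0`),
#'   `sign_epistatic`, `focal_dbenefit_P0`, `focal_dcost_P0`,
#'   `focal_dbenefit_PM`, `focal_dcost_PM`. Attribute `n_shortfall` counts
#'   backgrounds where no beneficial mutation was found.
#' @examples
#' cfg <- lac_config()
#' bg <- c(bas1 = 0.05, bas2 = 0.5, Ky = 1, Kmy = 5, Kt = 0.5)
#' sc <- epistasis_scan(bg, "Ky", n_backgrounds = 8, config = cfg, seed = 1)
#' @export
epistasis_scan <- function(background, focal, n_backgrounds = 200L, config,
                           seed = 1L, fitness_fn = NULL, max_draws = 1000L) {
  bg <- as_param_vec(background)
  lac_fit <- is.null(fitness_fn)
  fit_bd <- function(pvec) {
    df <- tibble::as_tibble(as.list(pvec))
    if (lac_fit) {
      fb <- compute_fitness(df, config)
      c(fitness = fb$fitness, benefit = fb$benefit, cost = fb$cost)
    } else {
      c(fitness = fitness_fn(df), benefit = NA_real_, cost = NA_real_)
    }
  }
  seeds <- derive_seeds(seed, c("focal", "backgrounds"))
  if (is.character(focal)) {
    if (!lac_fit) {
      stop("supply an explicit focal mutation when using a custom fitness_fn",
           call. = FALSE)
    }
    focal <- find_beneficial_mutation(bg, focal, config, seed = seeds$focal,
                                      max_draws = max_draws)
  }
  stopifnot(is.data.frame(focal), nrow(focal) == 1L)
  fp <- focal$param_id

  v0 <- fit_bd(bg)
  p0s <- bg
  p0s[fp] <- focal$new_value
  v0s <- fit_bd(p0s)
  delta_f <- v0s[["fitness"]] - v0[["fitness"]]
  if (lac_fit && delta_f <= 0) {
    stop("focal mutation is not beneficial on this background", call. = FALSE)
  }

  others <- setdiff(mutable_params(), fp)
  bg_params <- rep(others, length.out = n_backgrounds)
  shortfall <- 0L

  rows <- with_seed_if(seeds$backgrounds, {
    purrr::map(seq_len(n_backgrounds), function(i) {
      bp <- bg_params[i]
      bm <- tryCatch({
        if (lac_fit) {
          find_beneficial_mutation(bg, bp, config, max_draws = max_draws)
        } else {
          # under a custom fitness, search with the same kernel against it
          f0c <- fitness_fn(tibble::as_tibble(as.list(bg)))
          res <- NULL
          for (k in seq_len(max_draws)) {
            cand <- propose_one_in(bg, bp, config)
            q <- bg
            q[bp] <- cand
            f1c <- fitness_fn(tibble::as_tibble(as.list(q)))
            if (is.finite(f1c) && f1c > f0c) {
              res <- tibble::tibble(param_id = bp, old_value = unname(bg[bp]),
                                    new_value = cand,
                                    delta_fitness = f1c - f0c)
              break
            }
          }
          if (is.null(res)) rlang::abort("none", class = "lacdfe_no_beneficial")
          res
        }
      }, lacdfe_no_beneficial = function(e) NULL)
      if (is.null(bm)) return(NULL)
      pM <- bg
      pM[bp] <- bm$new_value
      vM <- fit_bd(pM)
      pMs <- pM
      pMs[fp] <- focal$new_value
      vMs <- fit_bd(pMs)
      dfs <- vMs[["fitness"]] - vM[["fitness"]]
      tibble::tibble(
        focal_param = fp, focal_old = focal$old_value,
        focal_new = focal$new_value,
        background_param = bp, background_old = unname(bg[bp]),
        background_new = bm$new_value,
        f0 = v0[["fitness"]], f0_star = v0s[["fitness"]], delta_f = delta_f,
        fM = vM[["fitness"]], fM_star = vMs[["fitness"]],
        delta_f_star = dfs,
        ratio = if (dfs == 0) NA_real_ else delta_f / dfs,
        sign_epistatic = (delta_f > 0 && dfs < 0) || (delta_f < 0 && dfs > 0),
        focal_dbenefit_P0 = v0s[["benefit"]] - v0[["benefit"]],
        focal_dcost_P0 = v0s[["cost"]] - v0[["cost"]],
        focal_dbenefit_PM = vMs[["benefit"]] - vM[["benefit"]],
        focal_dcost_PM = vMs[["cost"]] - vM[["cost"]]
      )
    })
  })
  shortfall <- sum(vapply(rows, is.null, logical(1)))
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    stop("epistasis_scan: no beneficial background mutation found for any ",
         "background", call. = FALSE)
  }
  if (shortfall > 0L) {
    warning("epistasis_scan: ", shortfall, " of ", n_backgrounds,
            " backgrounds had no beneficial mutation within budget",
            call. = FALSE)
  }
  structure(out, n_shortfall = as.integer(shortfall),
            class = c("lac_epistasis", class(tibble::as_tibble(out))))
}

#' Order epistasis records by background fitness
#'
#' Sorts the records of an epistasis scan by the fitness `fM` of the mutated
#' background and emits the ranked trend of the ratio `delta_f /
#' delta_f_star`, the quantity whose increase with background fitness is the
#' signature of diminishing-returns epistasis. Records with undefined ratio
#' (`delta_f_star == 0`) are excluded. Sign-epistatic records are counted
#' and carried through.
#'
#' @param records A `lac_epistasis` tibble from [epistasis_scan()].
#' @return A tibble with columns `rank`, `fM`, `ratio`, `sign_epistatic`,
#'   `background_param`; attributes `n_sign_epistatic`, `n_undefined` and
#'   `all_fM_equal` (ordering is by input index when every background
#'   fitness ties).
#' @export
ratio_vs_background_fitness <- function(records) {
  def <- records[!is.na(records$ratio), , drop = FALSE]
  if (nrow(def) < 2L) {
    stop("need >= 2 records with defined ratios", call. = FALSE)
  }
  ties <- length(unique(def$fM)) == 1L
  ord <- if (ties) seq_len(nrow(def)) else order(def$fM)
  out <- tibble::tibble(
    rank = seq_along(ord),
    fM = def$fM[ord],
    ratio = def$ratio[ord],
    sign_epistatic = def$sign_epistatic[ord],
    background_param = def$background_param[ord]
  )
  structure(out,
            n_sign_epistatic = sum(def$sign_epistatic),
            n_undefined = sum(is.na(records$ratio)),
            all_fM_equal = ties)
}
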