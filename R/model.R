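#' Right-hand side of the lac-operon ODE system
#'
#' The dynamic state has three components: LacZ, LacY and intracellular
#' lactose (`lac_in`). Total LacI is decoupled and linear, so it is held at
#' its closed-form steady state `bas2/kd3`, and free LacI is recomputed from
#' the repressor-lactose binding equilibrium at every evaluation:
#' `lacI_free = lacI_tot / (1 + lac_in/K)`.
#'
#' The derivatives are
#' \deqn{d[LacZ]/dt = bas_1 + K^y/(K^y_m + [lacI]) - k_{d1}[LacZ]}
#' \deqn{d[LacY]/dt = (bas_1 + K^y/(K^y_m + [lacI])) K_t - k_{d2}[LacY]}
#' \deqn{d[lac_{in}]/dt = k_1 [LacY] lac_{out}/(k_2 + lac_{out})
#'   - k_3 [LacZ] lac_{in}/(k_4 + lac_{in})}
#'
#' @param state Numeric vector `c(lacZ, lacY, lac_in)`.
#' @param params Named numeric vector or one-row data frame with the five
#'   mutable parameters (`bas1`, `bas2`, `Ky`, `Kmy`, `Kt`).
#' @param config A [lac_config()] supplying the fixed constants.
#' @return Numeric vector of the three time derivatives.
#' @examples
#' cfg <- lac_config()
#' lac_rhs(c(0, 0, 0), c(bas1 = 0.1, bas2 = 0.5, Ky = 5, Kmy = 1, Kt = 0.5), cfg)
#' @export
lac_rhs <- function(state, params, config) {
  p <- as_param_vec(params)
  if (length(state) != 3L || !all(is.finite(state))) {
    stop("state must be a finite numeric vector c(lacZ, lacY, lac_in)",
         call. = FALSE)
  }
  if (!all(is.finite(p))) stop("params must be finite", call. = FALSE)
  fx <- config$fixed
  lacI_tot <- p[["bas2"]] / fx$kd3
  lacI_free <- lacI_tot / (1 + state[3] / fx$K)
  act <- p[["bas1"]] + p[["Ky"]] / (p[["Kmy"]] + lacI_free)
  c(
    act - fx$kd1 * state[1],
    act * p[["Kt"]] - fx$kd2 * state[2],
    fx$k1 * state[2] * fx$lac_out / (fx$k2 + fx$lac_out) -
      fx$k3 * state[1] * state[3] / (fx$k4 + state[3])
  )
}

# Coerce a named vector / one-row data frame / list to the 5 mutable params.
as_param_vec <- function(params) {
  if (is.data.frame(params)) {
    stopifnot(nrow(params) == 1L)
    params <- unlist(params[, mutable_params()])
  }
  p <- unlist(params)[mutable_params()]
  if (anyNA(p)) {
    stop("params must supply all of: ", paste(mutable_params(), collapse = ", "),
         call. = FALSE)
  }
  p
}

# Vectorized steady-state core. The LacY:LacZ ratio is fixed at Kt*kd1/kd2
# for every parameter set, so the lactose balance closes in lac_in alone:
# lac_in/(k4 + lac_in) = r with r = k1' * Kt * kd1 / (kd2 * k3), where
# k1' = k1*lac_out/(k2+lac_out). r >= 1 means influx exceeds the metabolic
# capacity and lac_in diverges (flagged as non-converged).
steady_state_core <- function(bas1, bas2, Ky, Kmy, Kt, fx) {
  lacI_tot <- bas2 / fx$kd3
  influx_per_lacY <- fx$k1 * fx$lac_out / (fx$k2 + fx$lac_out)
  r <- influx_per_lacY * Kt * fx$kd1 / (fx$kd2 * fx$k3)
  lac_in <- ifelse(r < 1, fx$k4 * r / (1 - r), NA_real_)
  no_production <- bas1 == 0 & Ky == 0
  lac_in[no_production] <- 0
  lacI_free <- lacI_tot / (1 + lac_in / fx$K)
  act <- bas1 + Ky / (Kmy + lacI_free)
  lacZ <- act / fx$kd1
  lacY <- act * Kt / fx$kd2
  converged <- is.finite(lac_in)
  lacI_free[!converged] <- NA_real_
  lacZ[!converged] <- NA_real_
  lacY[!converged] <- NA_real_
  tibble::tibble(lacZ = lacZ, lacY = lacY, lacI_tot = lacI_tot,
                 lacI_free = lacI_free, lac_in = lac_in,
                 converged = converged)
}

#' Steady state of the lac-operon model
#'
#' Computes the steady-state concentrations of LacZ, LacY, total and free
#' LacI, and intracellular lactose for each parameter set (row) in `params`.
#' Total LacI is always the closed form `bas2/kd3`.
#'
#' Three solution methods are available. `"analytic"` (the default) uses the
#' model's exact reduction: the steady-state LacY:LacZ ratio equals
#' `Kt*kd1/kd2` independently of expression level, so the lactose balance
#' determines `lac_in` in closed form. `"root"` solves the same balance by
#' bracketing 1-D root finding on the full nonlinear residual, and
#' `"integrate"` integrates the stiff ODE from `(0, 0, 0)` with
#' [deSolve::lsoda()] until the relative right-hand-side norm drops below
#' `config$solver$tol`. The three routes agree to solver tolerance and are
#' cross-checked in the package tests.
#'
#' When lactose influx exceeds the maximum metabolic capacity, intracellular
#' lactose has no finite steady state; such rows are returned with
#' `converged = FALSE` and `NA` concentrations. The packaged default ranges
#' exclude this regime.
#'
#' @param params Data frame with columns `bas1`, `bas2`, `Ky`, `Kmy`, `Kt`
#'   (one row per parameter set), or a named vector for a single set.
#' @param config A [lac_config()].
#' @param method Overrides `config$solver$method`.
#' @return A tibble with one row per parameter set and columns `lacZ`,
#'   `lacY`, `lacI_tot`, `lacI_free`, `lac_in`, `converged`.
#' @examples
#' cfg <- lac_config()
#' steady_state(data.frame(bas1 = 0.1, bas2 = 0.5, Ky = 5, Kmy = 1, Kt = 0.5), cfg)
#' @export
steady_state <- function(params, config, method = NULL) {
  method <- method %||% config$solver$method
  df <- as_param_df(params)
  switch(method,
    analytic = steady_state_core(df$bas1, df$bas2, df$Ky, df$Kmy, df$Kt,
                                 config$fixed),
    root = purrr::map_dfr(seq_len(nrow(df)),
                          function(i) steady_state_root(df[i, ], config)),
    integrate = purrr::map_dfr(seq_len(nrow(df)),
                               function(i) steady_state_integrate(df[i, ], config)),
    stop("unknown steady-state method: ", method, call. = FALSE)
  )
}

as_param_df <- function(params) {
  if (!is.data.frame(params)) {
    params <- tibble::as_tibble(as.list(as_param_vec(params)))
  }
  missing <- setdiff(mutable_params(), names(params))
  if (length(missing)) {
    stop("params is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  params
}

# 1-D bracketing root finder on the lactose balance. g(L) >= 0 at L = 0;
# expand the upper bracket geometrically and give up (non-converged) if the
# balance never changes sign.
steady_state_root <- function(p, config) {
  fx <- config$fixed
  p <- as_param_vec(p)
  lacI_tot <- p[["bas2"]] / fx$kd3
  act_at <- function(L) {
    p[["bas1"]] + p[["Ky"]] / (p[["Kmy"]] + lacI_tot / (1 + L / fx$K))
  }
  g <- function(L) {
    act <- act_at(L)
    fx$k1 * (act * p[["Kt"]] / fx$kd2) * fx$lac_out / (fx$k2 + fx$lac_out) -
      fx$k3 * (act / fx$kd1) * L / (fx$k4 + L)
  }
  finish <- function(L, converged = TRUE) {
    act <- act_at(L)
    tibble::tibble(
      lacZ = if (converged) act / fx$kd1 else NA_real_,
      lacY = if (converged) act * p[["Kt"]] / fx$kd2 else NA_real_,
      lacI_tot = lacI_tot,
      lacI_free = if (converged) lacI_tot / (1 + L / fx$K) else NA_real_,
      lac_in = if (converged) L else NA_real_,
      converged = converged
    )
  }
  if (act_at(0) == 0 || g(0) <= 0) return(finish(0))
  upper <- fx$k4
  for (i in 1:80) {
    if (g(upper) < 0) break
    upper <- upper * 2
    if (upper > 1e18) return(finish(NA_real_, converged = FALSE))
  }
  if (g(upper) >= 0) return(finish(NA_real_, converged = FALSE))
  root <- stats::uniroot(g, c(0, upper), tol = 1e-13 * max(1, upper))$root
  finish(root)
}

# Stiff time integration from the empty state, doubling the horizon until
# the relative rhs norm is below tolerance.
steady_state_integrate <- function(p, config) {
  fx <- config$fixed
  pv <- as_param_vec(p)
  deriv <- function(t, y, parms) list(lac_rhs(y, pv, config))
  y <- c(lacZ = 0, lacY = 0, lac_in = 0)
  t_end <- 50 / min(fx$kd1, fx$kd2)
  converged <- FALSE
  repeat {
    sol <- deSolve::lsoda(y, c(0, t_end), deriv, parms = NULL,
                          rtol = 1e-12, atol = 1e-12)
    y <- sol[nrow(sol), -1]
    res <- lac_rhs(y, pv, config)
    if (sqrt(sum(res^2)) / (1 + sqrt(sum(y^2))) < config$solver$tol) {
      converged <- TRUE
      break
    }
    t_end <- t_end * 4
    if (t_end > config$solver$t_max) break
  }
  lacI_tot <- pv[["bas2"]] / fx$kd3
  tibble::tibble(
    lacZ = if (converged) unname(y[1]) else NA_real_,
    lacY = if (converged) unname(y[2]) else NA_real_,
    lacI_tot = lacI_tot,
    lacI_free = if (converged) unname(lacI_tot / (1 + y[3] / fx$K)) else NA_real_,
    lac_in = if (converged) unname(y[3]) else NA_real_,
    converged = converged
  )
}

#' Benefit, cost and fitness of the lac system
#'
#' Benefit is the lactose metabolized per unit time at steady state,
#' `k3*lacZ*lac_in/(k4 + lac_in)`. Cost is the protein-production expenditure
#' `alpha*(alpha_z*lacZ + alpha_y*lacY + alpha_i*lacI_tot)`; the LacI term
#' uses total LacI because every repressor molecule, free or lactose-bound,
#' must be produced. Fitness is benefit minus cost and may be negative.
#'
#' @param ss A steady-state tibble from [steady_state()].
#' @param config A [lac_config()].
#' @return `compute_benefit()` and `compute_cost()` return numeric vectors;
#'   `compute_fitness()` returns a tibble with columns `benefit`, `cost`,
#'   `fitness`, `converged`.
#' @examples
#' cfg <- lac_config()
#' p <- data.frame(bas1 = 0.1, bas2 = 0.5, Ky = 5, Kmy = 1, Kt = 0.5)
#' compute_fitness(p, cfg)
#' @export
compute_benefit <- function(ss, config) {
  fx <- config$fixed
  if (any(fx$k4 + ss$lac_in == 0, na.rm = TRUE)) {
    stop("degenerate half-saturation: k4 + lac_in = 0", call. = FALSE)
  }
  fx$k3 * ss$lacZ * ss$lac_in / (fx$k4 + ss$lac_in)
}

#' @rdname compute_benefit
#' @export
compute_cost <- function(ss, config) {
  co <- config$cost
  co$alpha * (co$alpha_z * ss$lacZ + co$alpha_y * ss$lacY +
                co$alpha_i * ss$lacI_tot)
}

#' @rdname compute_benefit
#' @param params Data frame of parameter sets (columns `bas1`, `bas2`, `Ky`,
#'   `Kmy`, `Kt`), or a named vector for a single set.
#' @param method Steady-state method override, see [steady_state()].
#' @export
compute_fitness <- function(params, config, method = NULL) {
  ss <- steady_state(params, config, method = method)
  benefit <- compute_benefit(ss, config)
  cost <- compute_cost(ss, config)
  tibble::tibble(benefit = benefit, cost = cost, fitness = benefit - cost,
                 converged = ss$converged)
}

# Fast scalar fitness for optimizers / root finders: named numeric in,
# single fitness value out (NA when non-converged). Pure scalar arithmetic;
# mirrors steady_state_core + benefit - cost.
fitness_value <- function(pvec, config) {
  fx <- config$fixed
  co <- config$cost
  lacI_tot <- pvec[["bas2"]] / fx$kd3
  r <- fx$k1 * fx$lac_out / (fx$k2 + fx$lac_out) * pvec[["Kt"]] * fx$kd1 /
    (fx$kd2 * fx$k3)
  if (pvec[["bas1"]] == 0 && pvec[["Ky"]] == 0) {
    lac_in <- 0
  } else if (r < 1) {
    lac_in <- fx$k4 * r / (1 - r)
  } else {
    return(NA_real_)
  }
  lacI_free <- lacI_tot / (1 + lac_in / fx$K)
  act <- pvec[["bas1"]] + pvec[["Ky"]] / (pvec[["Kmy"]] + lacI_free)
  lacZ <- act / fx$kd1
  lacY <- act * pvec[["Kt"]] / fx$kd2
  fx$k3 * lacZ * lac_in / (fx$k4 + lac_in) -
    co$alpha * (co$alpha_z * lacZ + co$alpha_y * lacY + co$alpha_i * lacI_tot)
}

# Vectorized fitness over a params data frame (analytic method).
fitness_vec <- function(df, config) {
  ss <- steady_state_core(df$bas1, df$bas2, df$Ky, df$Kmy, df$Kt,
                          config$fixed)
  compute_benefit(ss, config) - compute_cost(ss, config)
}
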