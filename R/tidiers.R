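#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods for lacdfe result objects
#'
#' Broom-style accessors: `tidy()` returns per-component rows, `glance()` a
#' one-row summary.
#'
#' @param x A `lac_expfit`, `lac_fmax`, `lac_dfe` or `lac_bimodality`
#'   object.
#' @param ... Unused.
#' @return A tibble.
#' @name lacdfe-tidiers
NULL

#' @rdname lacdfe-tidiers
#' @method tidy lac_expfit
#' @export
tidy.lac_expfit <- function(x, ...) {
  tibble::tibble(term = "lambda", estimate = x$lam)
}

#' @rdname lacdfe-tidiers
#' @method glance lac_expfit
#' @export
glance.lac_expfit <- function(x, ...) {
  tibble::tibble(lam = x$lam, r2 = x$r2, n_bins = x$n_bins,
                 sign_ok = x$sign_ok, n = x$n)
}

#' @rdname lacdfe-tidiers
#' @method tidy lac_fmax
#' @export
tidy.lac_fmax <- function(x, ...) {
  tibble::tibble(term = mutable_params(),
                 estimate = unlist(x$par[mutable_params()]))
}

#' @rdname lacdfe-tidiers
#' @method glance lac_fmax
#' @export
glance.lac_fmax <- function(x, ...) {
  tibble::tibble(fmax = x$fmax, n_starts = x$n_starts)
}

#' @rdname lacdfe-tidiers
#' @method glance lac_dfe
#' @export
glance.lac_dfe <- function(x, ...) {
  cls <- classify_dfe(x)
  dplyr::bind_cols(
    tibble::tibble(background_fitness = attr(x, "background_fitness"),
                   n_failed = attr(x, "n_failed")),
    cls
  )
}

#' @rdname lacdfe-tidiers
#' @method glance lac_bimodality
#' @export
glance.lac_bimodality <- function(x, ...) {
  tibble::tibble(n_peaks = x$n_peaks)
}
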