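#' Tidy a cutoff power-law fit
#'
#' @param x A `plcut_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @method tidy plcut_fit
#' @export
tidy.plcut_fit <- function(x, ...) {
  tibble(term = c("alpha", "beta"),
         estimate = c(x$alpha, x$beta),
         std.error = c(x$stderr_alpha, x$stderr_beta))
}

#' @rdname tidy.plcut_fit
#' @method glance plcut_fit
#' @export
glance.plcut_fit <- function(x, ...) {
  tibble(logLik = x$loglik, nobs = x$n, a0 = x$a0,
         beta_boundary = x$boundary)
}

#' Tidy a maximum-entropy solution
#'
#' @param x A `maxent_solution`.
#' @param ... Unused.
#' @return Tibble with `term` / `estimate` rows for `alpha`, `beta`, `K`,
#'   and `lambda`.
#' @method tidy maxent_solution
#' @export
tidy.maxent_solution <- function(x, ...) {
  tibble(term = c("alpha", "beta", "K", "lambda"),
         estimate = c(x$alpha, x$beta, x$K, x$lambda))
}

#' @rdname tidy.maxent_solution
#' @method glance maxent_solution
#' @export
glance.maxent_solution <- function(x, ...) {
  tibble(a0 = x$a0, implied_C = x$implied_C, implied_E = x$implied_E,
         residual = x$residual)
}

#' Tidy a fluctuation-scaling fit
#'
#' @param x An `omega_fit`.
#' @param ... Unused.
#' @return The per-bin table (`center`, `sd`, `n_pairs`).
#' @method tidy omega_fit
#' @export
tidy.omega_fit <- function(x, ...) {
  x$bins
}

#' @rdname tidy.omega_fit
#' @method glance omega_fit
#' @export
glance.omega_fit <- function(x, ...) {
  tibble(omega = x$omega, std.error = x$stderr, intercept = x$intercept,
         r.squared = x$r2, n_bins = x$n_bins, n_pairs = x$n_pairs)
}
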