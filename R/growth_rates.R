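#' Conditional (individual) growth-rate density
#'
#' For an urn of size `n`, the one-iteration growth rate `g = n'/n` is
#' Gaussian with mean 1 and variance `c/n`: absolute fluctuations scale as
#' `sqrt(n)`, so relative fluctuations shrink as `n^-0.5`.
#'
#' @param g Growth rate(s).
#' @param n Conditioning size (> 0).
#' @param c Per-ball variance coefficient (> 0).
#' @return Density value(s).
#' @export
individual_growth_pdf <- function(g, n, c) {
  stopifnot(n > 0, c > 0)
  dnorm(g, mean = 1, sd = sqrt(c / n))
}

#' Per-ball variance coefficient implied by the process parameters
#'
#' The conditional variance of the one-iteration size change is `c * n`
#' with `c = 2q / (1 + q)^2` for the grow-and-shrink dynamics (case I,
#' binomial growth at `q` thinned at `q/(1+q)`) and `c = q (1 - q)` for the
#' growth of a surviving urn (case II).
#'
#' @param q Attraction probability.
#' @param mode `"shrink_only"` or `"exit_only"`.
#' @return The coefficient `c`.
#' @export
growth_variance_coefficient <- function(q,
                                        mode = c("shrink_only",
                                                 "exit_only")) {
  mode <- match.arg(mode)
  switch(mode,
         shrink_only = 2 * q / (1 + q)^2,
         exit_only = q * (1 - q))
}

#' Closed-form aggregate growth-rate curve
#'
#' Pooling the size-conditional Gaussians over a cutoff-free power law with
#' `alpha = 0.5` gives, up to normalization, the upper incomplete Gamma
#' function of order zero (the exponential integral):
#' `G(g) propto Gamma(0, n0 (g - 1)^2 / (2c))`.  The curve diverges
#' logarithmically at `g = 1`.
#'
#' @param g Growth rate(s); the value at `g = 1` is `Inf`.
#' @param n0 Lower bound of the mixing density (minimum size).
#' @param c Per-ball variance coefficient (the form printed with
#'   `0.5 * n0 * (g-1)^2` corresponds to `c = 1`).
#' @return Unnormalized density value(s).
#' @export
closed_form_aggregate <- function(g, n0 = 1, c = 1) {
  stopifnot(n0 > 0, c > 0)
  x <- n0 * (g - 1)^2 / (2 * c)
  out <- rep(Inf, length(x))
  ok <- x > 0
  out[ok] <- vapply(x[ok], pracma::expint, numeric(1))
  out
}

#' Aggregate (pooled) growth-rate density
#'
#' Numerical mixture `integral G(g | n) rho(n) dn` of the conditional
#' Gaussians over the cutoff power-law size density with parameters
#' `(alpha, beta, n0)`.  Because both factors are normalized the mixture is
#' a normalized density in `g`.
#'
#' @param g Growth rate(s).
#' @param alpha,beta,n0 Parameters of the mixing size density.
#' @param c Per-ball variance coefficient of the conditional Gaussians.
#' @return Density value(s).
#' @export
aggregate_growth_pdf <- function(g, alpha, beta = 0, n0 = 1, c = 1) {
  K <- normalization_K(alpha, beta, n0)
  vapply(g, function(gi) {
    f <- function(n) {
      dnorm(gi, 1, sqrt(c / n)) * K * exp(-(alpha + 1) * log(n) - beta * n)
    }
    val <- tryCatch(
      integrate(f, n0, Inf, rel.tol = 1e-9, subdivisions = 500L)$value,
      error = function(e) NA_real_)
    if (is.na(val)) {
      stop_domain("growth-rate mixture quadrature failed at g = ", gi)
    }
    val
  }, numeric(1))
}

# normalized closed-form density and cdf on a grid wide enough that the
# truncated mass is >= 1 - 1e-6
closed_form_grid <- function(n0 = 1, c = 1, n_grid = 4001) {
  # tail mass of Gamma(0, s x^2): integrand ~ exp(-s x^2)/ (s x^2); choose
  # half-width w where the unnormalized tail is negligible
  s <- n0 / (2 * c)
  w <- sqrt(30 / s)
  x <- seq(1 - w, 1 + w, length.out = n_grid)
  y <- closed_form_aggregate(x, n0, c)
  y[!is.finite(y)] <- max(y[is.finite(y)])  # midpoint: log singularity
  dx <- diff(x)
  mass <- sum((y[-1] + y[-length(y)]) / 2 * dx)
  dens <- y / mass
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * dx))
  cdf <- cdf / cdf[length(cdf)]
  list(g = x, density = dens, cdf = approxfun(x, cdf, yleft = 0, yright = 1))
}

#' Normalized closed-form aggregate growth-rate distribution
#'
#' Numerically normalized version of [closed_form_aggregate()], returning
#' the density and a distribution function usable with [stats::ks.test()].
#'
#' @inheritParams closed_form_aggregate
#' @return List with `density` tibble (`g`, `density`) and `cdf`
#'   (a function).
#' @export
closed_form_normalized <- function(n0 = 1, c = 1) {
  grid <- closed_form_grid(n0, c)
  list(density = tibble(g = grid$g, density = grid$density),
       cdf = grid$cdf)
}

#' Extract empirical growth rates from a run
#'
#' Growth rates `g = n_after / n_before` for urns that persisted through an
#' iteration (urns that exited or were replaced between the two snapshots
#' are excluded: their `g` would be an artifact of the re-entry
#' convention).
#'
#' @param run An `urn_run` with collected pairs.
#' @return Tibble with columns `t`, `n_before`, and `g`.
#' @export
empirical_growth_rates <- function(run) {
  stopifnot(inherits(run, "urn_run"))
  if (nrow(run$pairs) == 0) {
    stop_domain("run has no recorded pairs; rerun with collect_pairs = TRUE")
  }
  dplyr::transmute(run$pairs, t = .data$t, n_before = .data$n_before,
                   g = .data$n_after / .data$n_before)
}
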