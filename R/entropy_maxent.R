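#' Exact Shannon entropy of a binomial distribution
#'
#' Direct sum `-sum(p_k log p_k)` (natural log, `0 log 0 = 0`) over the
#' binomial with `n` trials and success probability `q`.  Used for the exact
#' small-size entropies that correct the entropy constraint at size 1.
#'
#' @param n Number of trials (intended for small `n`, <= a few hundred).
#' @param q Success probability in \[0, 1\].
#' @return Entropy in nats.
#' @examples
#' binomial_entropy_exact(1, 0.5)  # log(2)
#' @export
binomial_entropy_exact <- function(n, q) {
  stopifnot(n >= 1, q >= 0, q <= 1)
  p <- dbinom(0:n, n, q)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Ratio of exact binomial entropies at sizes 1 and 2
#'
#' `s(1, q) / s(2, q)`, which stays close to 0.6 over a wide range of `q`.
#' This ratio transfers the large-`n` entropy approximation down to size 1,
#' where the Gaussian approximation would give 0.
#'
#' @param q Success probability in (0, 1).
#' @return The entropy ratio, in (0, 1).
#' @export
small_n_entropy_ratio <- function(q) {
  if (q <= 0 || q >= 1) stop_domain("ratio undefined for q in {0, 1}")
  binomial_entropy_exact(1, q) / binomial_entropy_exact(2, q)
}

#' Large-n entropy of one urn's size-change distribution
#'
#' Gaussian differential entropy `0.5 * log(2 * pi * e * sigma^2(n))` with
#' the mode-specific variance `sigma^2(n) = q (1 + q) n` (case I,
#' grow-and-shrink) or `sigma^2(n) = q (1 - q) n` (case II, growth of a
#' surviving urn).  Only differences of these entropies matter downstream:
#' the additive constant cancels when the constraint is reduced to the mean
#' log-size.
#'
#' @param n Urn size (>= 1).
#' @param q Attraction probability.
#' @param mode `"shrink_only"` (case I) or `"exit_only"` (case II).
#' @return Entropy in nats.
#' @export
per_urn_entropy <- function(n, q, mode = c("shrink_only", "exit_only")) {
  mode <- match.arg(mode)
  stopifnot(all(n >= 1))
  sigma2 <- switch(mode,
                   shrink_only = q * (1 + q) * n,
                   exit_only = q * (1 - q) * n)
  0.5 * log(2 * pi * exp(1) * sigma2)
}

#' Entropy constraint C: mean log size
#'
#' `C = mean(log(n_i))`, the log of the geometric mean of the sizes -- the
#' constant-free form of the per-urn entropy sum that constrains the
#' maximum-entropy size distribution.
#'
#' @param sizes Vector of sizes (all >= 1), or distinct sizes when `count`
#'   is given.
#' @param count Optional weights (counts or probabilities) matching `sizes`.
#' @return `C` in nats.
#' @examples
#' compute_C(c(1, 2, 4, 8))  # 6 log(2) / 4
#' @export
compute_C <- function(sizes, count = NULL) {
  if (length(sizes) == 0) stop_domain("`sizes` is empty")
  if (any(sizes < 1)) stop_domain("all sizes must be >= 1")
  if (is.null(count)) mean(log(sizes))
  else sum(count * log(sizes)) / sum(count)
}

#' Corrected entropy constraint accounting for size-1 urns
#'
#' The large-`n` approximation behind [compute_C()] assigns entropy
#' `log(1) = 0` to urns of size 1, underestimating their true (binomial)
#' entropy.  With turnover, size-1 urns are plentiful, so their contribution
#' is restored by substituting `small_n_entropy_ratio(q) * s2` for each
#' size-1 term, where `s2` is the constant-free entropy at size 2
#' (`log(2)` by default, the same scale as the other terms).
#'
#' @inheritParams compute_C
#' @param q Attraction probability used for the exact small-size entropies.
#' @param s2_scale Constant-free entropy at size 2: `"full"` (default,
#'   `log(2)`, the same scale as the `log(n)` terms of `C`) or `"half"`
#'   (`0.5 * log(2)`, the half-log Gaussian-approximation scale).
#' @return Corrected `C` in nats; always >= [compute_C()] on the same data.
#' @export
compute_C_corrected <- function(sizes, q, count = NULL,
                                s2_scale = c("full", "half")) {
  s2_scale <- match.arg(s2_scale)
  if (length(sizes) == 0) stop_domain("`sizes` is empty")
  if (any(sizes < 1)) stop_domain("all sizes must be >= 1")
  s2 <- if (s2_scale == "half") 0.5 * log(2) else log(2)
  s1 <- small_n_entropy_ratio(q) * s2
  terms <- ifelse(sizes < 2, s1, log(sizes))
  if (is.null(count)) mean(terms) else sum(count * terms) / sum(count)
}

#' Power-law exponent from the entropy constraint
#'
#' In the cutoff-free case (`beta = 0`) the maximum-entropy density
#' `K n^-(alpha+1)` on `[a0, Inf)` has mean log-size `log(a0) + 1/alpha`,
#' so `alpha = 1 / (C - log(a0))`; for `a0 = 1` simply `alpha = 1/C`.
#'
#' @param C Entropy constraint (mean log size), must exceed `log(a0)`.
#' @param a0 Minimum size (default 1).
#' @return The tail exponent `alpha` (the density exponent is
#'   `lambda = alpha + 1`).
#' @export
alpha_from_C <- function(C, a0 = 1) {
  if (C <= log(a0)) {
    stop_domain("infeasible constraint: C must exceed log(a0)")
  }
  1 / (C - log(a0))
}

#' Upper incomplete gamma function for general (possibly negative) order
#'
#' `Gamma(s, x) = integral_x^Inf t^(s-1) e^(-t) dt`, extended to `s <= 0` by
#' the downward recurrence `Gamma(s, x) = (Gamma(s+1, x) - x^s e^(-x)) / s`
#' with `Gamma(0, x) = E1(x)`.  These are the special functions in which the
#' moment constraints of the cutoff power law are expressible.
#'
#' @param s Order (any real with `s > -50`).
#' @param x Argument (> 0).
#' @return `Gamma(s, x)`.
#' @export
upper_incomplete_gamma <- function(s, x) {
  stopifnot(x > 0, s > -50)
  if (s > 0) {
    pracma::incgam(x, s)
  } else if (s == 0) {
    pracma::expint(x)
  } else {
    (upper_incomplete_gamma(s + 1, x) - x^s * exp(-x)) / s
  }
}

# Moments of the continuous density K n^-(alpha+1) e^(-beta n) on [a0, Inf):
# returns Z (normalizing integral of the unnormalized density), Elog = E[ln n],
# En = E[n].  Incomplete-gamma closed forms for Z and En; Elog by central
# difference of log Z in alpha (the integrand has no elementary primitive).
plcut_cont_moments <- function(alpha, beta, a0 = 1) {
  stopifnot(alpha > 0 || beta > 0, a0 > 0)
  logZ <- function(a) {
    if (beta < 1e-15) {
      if (a <= 0) return(Inf)
      -a * log(a0) - log(a)
    } else {
      a * log(beta) + log(upper_incomplete_gamma(-a, beta * a0))
    }
  }
  Z <- exp(logZ(alpha))
  h <- 1e-5 * max(1, abs(alpha))
  Elog <- -(logZ(alpha + h) - logZ(alpha - h)) / (2 * h)
  En <- if (beta < 1e-15) {
    if (alpha > 1) alpha * a0 / (alpha - 1) else Inf
  } else {
    exp((alpha - 1) * log(beta) +
          log(upper_incomplete_gamma(1 - alpha, beta * a0)) - logZ(alpha))
  }
  list(Z = Z, Elog = Elog, En = En)
}

#' Normalizing constant of the cutoff power-law density
#'
#' `K` such that `K n^-(alpha+1) e^(-beta n)` integrates to 1 on
#' `[a0, Inf)`.  Closed form `K = alpha * a0^alpha` when `beta = 0`;
#' otherwise via the incomplete-gamma form of the normalizing integral.
#'
#' @param alpha Tail exponent (> 0 required when `beta = 0`).
#' @param beta Exponential cutoff rate (>= 0).
#' @param a0 Lower support bound.
#' @return The constant `K`.
#' @export
normalization_K <- function(alpha, beta = 0, a0 = 1) {
  if (beta < 0) stop_domain("`beta` must be >= 0")
  if (beta == 0 && alpha <= 0) {
    stop_domain("non-normalizable: beta = 0 requires alpha > 0")
  }
  1 / plcut_cont_moments(alpha, beta, a0)$Z
}

#' Solve the maximum-entropy constraints for (alpha, beta)
#'
#' Finds the parameters of `P(n) = K n^-(alpha+1) e^(-beta n)` on
#' `[a0, Inf)` (continuous approximation) whose mean log-size equals `C` and
#' whose mean equals `E` -- the two Lagrange constraints of the
#' maximum-entropy problem.  A bounded least-squares search over
#' `alpha in (0.02, 10), beta in [0, 10]` is polished by damped Newton
#' iterations on the residuals; the `beta = 0` branch reduces to
#' [alpha_from_C()].
#'
#' The solve is a nested root-find: for each candidate `alpha`, the cutoff
#' `beta` matching the mean constraint is found by bisection (`E` is
#' strictly decreasing in `beta`), and `alpha` is then adjusted until the
#' mean log-size matches `C` (at fixed `E`, the implied `C` is strictly
#' decreasing in `alpha`, which makes the outer problem one-dimensional
#' and monotone).
#'
#' @param C Mean log size constraint (> `log(a0)`).
#' @param E Mean size constraint (> `a0`).
#' @param a0 Minimum size.
#' @return An object of class `maxent_solution`: a list with `alpha`,
#'   `beta`, `K`, `lambda` (= alpha + 1), `a0`, `implied_C`, `implied_E`
#'   (moments recomputed at the solution) and `residual`.
#' @examples
#' sol <- solve_alpha_beta(C = 1.2, E = 8)
#' tidy(sol)
#' @export
solve_alpha_beta <- function(C, E, a0 = 1) {
  if (C <= log(a0)) stop_domain("infeasible: C must exceed log(a0)")
  if (E <= a0) stop_domain("infeasible: E must exceed a0")
  beta_lo <- 1e-12
  beta_hi <- 10
  beta_for_E <- function(alpha) {
    # E(alpha, beta) is strictly decreasing in beta
    e_lo <- plcut_cont_moments(alpha, beta_lo, a0)$En
    e_hi <- plcut_cont_moments(alpha, beta_hi, a0)$En
    if (is.finite(e_lo) && e_lo < E) {
      # analytic beta = 0 mean: infinite for alpha <= 1
      m0 <- if (alpha <= 1) Inf else alpha * a0 / (alpha - 1)
      # root sits below the numerical floor: treat as beta ~ 0
      return(if (m0 >= E) beta_lo else NA_real_)
    }
    if (e_hi > E) return(NA_real_)                     # beta cap too heavy
    uniroot(function(lb) plcut_cont_moments(alpha, exp(lb), a0)$En - E,
            lower = log(beta_lo), upper = log(beta_hi),
            tol = 1e-14)$root |> exp()
  }
  c_resid <- function(alpha) {
    b <- beta_for_E(alpha)
    if (is.na(b)) return(NA_real_)
    plcut_cont_moments(alpha, b, a0)$Elog - C
  }
  # feasible alpha range: for alpha >= E/(E - a0) the beta = 0 mean already
  # falls below E, so no cutoff can reach it
  alpha_max <- min(10, E / (E - a0) - 1e-9)
  grid <- exp(seq(log(0.021), log(alpha_max), length.out = 40))
  vals <- vapply(grid, function(a) tryCatch(c_resid(a),
                                            error = function(e) NA_real_),
                 numeric(1))
  ok <- which(is.finite(vals))
  if (length(ok) < 2 || all(vals[ok] > 0) || all(vals[ok] < 0)) {
    stop_domain(sprintf(
      "no maximum-entropy solution in the search box (alpha in (0.02, %.3g), beta in [0, 10]) for C = %.4g, E = %.4g",
      alpha_max, C, E))
  }
  i <- ok[which(diff(sign(vals[ok])) != 0)[1]]
  j <- ok[ok > i][1]
  alpha <- uniroot(c_resid, lower = grid[i], upper = grid[j],
                   tol = 1e-12)$root
  beta <- beta_for_E(alpha)
  p <- c(alpha, max(beta, 0))
  if (p[2] <= 2 * beta_lo) p <- c(alpha_from_C(C, a0), 0)
  resid <- function(p) {
    m <- plcut_cont_moments(p[1], p[2], a0)
    c(m$Elog - C, if (is.finite(m$En)) (m$En - E) / E else 0)
  }
  r <- resid(p)
  if (sum(r^2) > 1e-10) {
    stop_domain(sprintf(
      "maxent solve did not converge; residuals (C, E/E): %.3g, %.3g",
      r[1], r[2]))
  }
  m <- plcut_cont_moments(p[1], p[2], a0)
  structure(
    list(alpha = p[1], beta = p[2], K = 1 / m$Z, lambda = p[1] + 1, a0 = a0,
         implied_C = m$Elog, implied_E = m$En, residual = sqrt(sum(r^2))),
    class = "maxent_solution")
}

#' @export
print.maxent_solution <- function(x, ...) {
  cat(sprintf(
    "<maxent_solution> alpha = %.5f, beta = %.5g, K = %.5g (a0 = %g)\n",
    x$alpha, x$beta, x$K, x$a0))
  cat(sprintf("  implied C = %.5f, implied E = %.4f, residual = %.2g\n",
              x$implied_C, x$implied_E, x$residual))
  invisible(x)
}

#' Discrete probability mass of the cutoff power law
#'
#' `P(n) propto n^-(alpha+1) e^(-beta n)` renormalized over integer support
#' `a0, a0+1, ..., n_max`.
#'
#' @param alpha Tail exponent.
#' @param beta Cutoff rate (>= 0).
#' @param a0 Minimum size.
#' @param n_max Upper truncation of the support.
#' @return Tibble with columns `n` and `prob`.
#' @export
plcut_pmf <- function(alpha, beta = 0, a0 = 1, n_max = 1e5) {
  n <- seq.int(a0, n_max)
  w <- exp(-(alpha + 1) * log(n) - beta * n)
  tibble(n = n, prob = w / sum(w))
}

#' Sample from the discrete cutoff power law
#'
#' Inverse-CDF sampling on the truncated integer support (the same law that
#' [fit_powerlaw_cutoff()] fits), used for parameter-recovery tests and
#' fixtures.
#'
#' @inheritParams plcut_pmf
#' @param n Number of draws.
#' @return Integer vector of samples.
#' @export
rplcut <- function(n, alpha, beta = 0, a0 = 1, n_max = 1e6) {
  pmf <- plcut_pmf(alpha, beta, a0, n_max)
  sample(pmf$n, n, replace = TRUE, prob = pmf$prob)
}
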