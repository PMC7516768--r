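#' Maximum-entropy velocity distribution with a size-independent entropy
#' constraint
#'
#' One-dimensional Maxwell-Boltzmann check: when the per-particle entropy
#' of the one-step change does not depend on the particle's own state, the
#' entropy-sum constraint drops out of the maximization (its multiplier is
#' zero) and only the mean-energy constraint survives, leaving the centered
#' Gaussian `P(v) = sqrt(beta/pi) exp(-beta v^2)` with variance
#' `1/(2 beta)`.
#'
#' @param beta Inverse-temperature parameter (> 0).
#' @return List with `density` (function of `v`), `variance`
#'   (`1/(2 beta)`), and `lambda` (the entropy-constraint multiplier, 0).
#' @export
mep_gaussian <- function(beta) {
  stopifnot(beta > 0)
  list(density = function(v) sqrt(beta / pi) * exp(-beta * v^2),
       variance = 1 / (2 * beta),
       lambda = 0)
}

#' Generic dual solve for maximum-entropy multipliers on a grid
#'
#' Maximizes `-sum(p log p)` over a discrete grid subject to
#' `sum(p) = 1`, `sum(p * s) = C`, and `sum(p * f) = E` by minimizing the
#' convex dual in the multipliers `(lambda, beta)` of the entropy-sum and
#' mean constraints, `p propto exp(-lambda s - beta f)`.  A tiny ridge on
#' `lambda` selects the zero multiplier when the entropy feature `s` is
#' constant (the Maxwell-Boltzmann degeneracy).
#'
#' @param values Grid of states.
#' @param s Entropy feature per state (e.g. `log n`, or a constant).
#' @param f Mean feature per state (e.g. `n` or `v^2`).
#' @param C,E Constraint targets for `s` and `f`.
#' @return List with `lambda`, `beta`, and the fitted probabilities `p`.
#' @export
maxent_multipliers <- function(values, s, f, C, E) {
  stopifnot(length(values) == length(s), length(values) == length(f))
  dual <- function(th) {
    logw <- -th[1] * s - th[2] * f
    m <- max(logw)
    log(sum(exp(logw - m))) + m + th[1] * C + th[2] * E + 1e-9 * th[1]^2
  }
  fit <- optim(c(0, 0), dual, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  logw <- -fit$par[1] * s - fit$par[2] * f
  p <- exp(logw - max(logw))
  list(lambda = fit$par[1], beta = fit$par[2], p = p / sum(p))
}

#' Simulate the Yule preferential-attachment process
#'
#' Discrete-time Yule/Barabasi-Albert urn scheme for a growing system: in
#' each cycle, `N_add` balls are added one at a time, each to an urn chosen
#' with probability proportional to its size, and then a new urn of size 1
#' is added; the process runs (from a seed of two size-1 urns) until `M`
#' urns exist.  The stationary size distribution is a pure power law (no
#' exponential cutoff).
#'
#' @param M Number of urns at which to stop.
#' @param N_add Balls added per new urn.
#' @param seed Optional integer seed.
#' @return Integer vector of the `M` urn sizes; total ball count is exactly
#'   `2 + (M - 2) * (N_add + 1)`.
#' @export
simulate_yule <- function(M, N_add = 10, seed = NULL) {
  stopifnot(M >= 3, N_add >= 1)
  if (!is.null(seed)) set.seed(seed)
  total_balls <- 2 + (M - 2) * (N_add + 1)
  owners <- integer(total_balls)
  owners[1:2] <- 1:2
  n_balls <- 2L
  n_urns <- 2L
  while (n_urns < M) {
    for (b in seq_len(N_add)) {
      pick <- owners[sample.int(n_balls, 1L)]
      n_balls <- n_balls + 1L
      owners[n_balls] <- pick
    }
    n_urns <- n_urns + 1L
    n_balls <- n_balls + 1L
    owners[n_balls] <- n_urns
  }
  tabulate(owners[seq_len(n_balls)], nbins = M)
}

#' Simulate a multiplicative-noise (Kesten/Langevin) size process
#'
#' `M` independent units evolve as `n <- gamma * n + delta` with
#' multiplicative factor `gamma` drawn i.i.d. from a mean-1 lognormal and
#' additive noise `delta ~ Uniform(0, delta_max)`; units falling below 1
#' are reset to `n_reset` (the refilled-urn convention).  Written
#' additively, the noise term has standard deviation proportional to `n`
#' (`omega = 1`), in contrast with the `omega = 0.5` of the stable-size
#' process.  An optional exit rate resets units to `n_reset` at random,
#' raising the power-law exponent of the upper tail.
#'
#' @param M Number of units.
#' @param steps Number of update steps.
#' @param gamma_sd Standard deviation of the lognormal factor (mean fixed
#'   at 1); `0` gives the deterministic `gamma = 1`.
#' @param delta_max Upper bound of the uniform additive noise; `0` disables
#'   it.
#' @param n_reset Re-entry size for collapsed (or exited) units.
#' @param exit_rate Optional per-step reset probability.
#' @param pairs_from Collect pairs from this step on (default: second
#'   half).
#' @param pairs_thin Collect pairs every this many steps.
#' @param seed Optional integer seed.
#' @return List with `sizes` (final), and `pairs` (tibble `n_before`,
#'   `n_after` for non-reset transitions).
#' @export
simulate_multiplicative_noise <- function(M = 1e4, steps = 500,
                                          gamma_sd = 0.1, delta_max = 1,
                                          n_reset = 1, exit_rate = 0,
                                          pairs_from = steps %/% 2,
                                          pairs_thin = 5, seed = NULL) {
  stopifnot(M >= 1, steps >= 1, gamma_sd >= 0, n_reset >= 1)
  if (!is.null(seed)) set.seed(seed)
  sdlog <- if (gamma_sd > 0) sqrt(log(1 + gamma_sd^2)) else 0
  meanlog <- -sdlog^2 / 2   # E[gamma] = 1
  n <- rep(as.numeric(n_reset), M)
  chunks <- list()
  for (t in seq_len(steps)) {
    gam <- if (sdlog > 0) rlnorm(M, meanlog, sdlog) else rep(1, M)
    delta <- if (delta_max > 0) runif(M, 0, delta_max) else 0
    n_new <- gam * n + delta
    reset <- n_new < 1
    if (exit_rate > 0) reset <- reset | (runif(M) < exit_rate)
    n_new[reset] <- n_reset
    if (t >= pairs_from && (t - pairs_from) %% pairs_thin == 0) {
      keep <- !reset
      chunks[[length(chunks) + 1L]] <-
        cbind(n_before = n[keep], n_after = n_new[keep])
    }
    n <- n_new
    if (mean(n) > 1e9) {
      stop_domain("process diverging; reduce gamma_sd or add resets")
    }
  }
  pairs <- if (length(chunks)) {
    m <- do.call(rbind, chunks)
    tibble(n_before = m[, 1], n_after = m[, 2])
  } else {
    tibble(n_before = numeric(), n_after = numeric())
  }
  list(sizes = n, pairs = pairs)
}
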