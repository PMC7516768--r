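#' Configure the single-urn master-equation oracle
#'
#' The full process couples urns only through the globally adjusted
#' attraction probability and shrink rate; at stationarity these sit at
#' their mean-field values, and with them held fixed the size of a single
#' urn is a Markov chain on `1..n_max` whose stationary law can be computed
#' exactly from the truncated transition matrix.  This is the exact oracle
#' against which simulation and maximum-entropy predictions are checked.
#'
#' @param mode `"shrink_only"` (case I), `"exit_only"` (case II), or
#'   `"mixed"`.
#' @param q Fixed per-ball attraction probability.
#' @param delta_shrink Fixed per-ball deletion probability; defaults to the
#'   mean-field stationary value `q / (1 + q)`.
#' @param delta_exit Fixed urn exit probability (cases II/III).
#' @param n_max Truncation of the size support (default 2000); transition
#'   mass beyond `n_max` is accumulated at `n_max`.
#' @param tol Total-variation tolerance for the stationary solve.
#' @return An object of class `oracle_config`.
#' @export
oracle_config <- function(mode = c("shrink_only", "exit_only", "mixed"),
                          q = 0.05, delta_shrink = q / (1 + q),
                          delta_exit = 0, n_max = 2000, tol = 1e-12) {
  mode <- match.arg(mode)
  stopifnot(n_max >= 50, q > 0, q < 1, tol > 0)
  if (mode == "shrink_only") delta_exit <- 0
  if (mode == "exit_only") delta_shrink <- 0
  if (delta_exit < 0 || delta_exit > 1 || delta_shrink < 0 ||
      delta_shrink >= 1) {
    stop_domain("invalid probabilities for the oracle chain")
  }
  structure(list(mode = mode, q = q, delta_shrink = delta_shrink,
                 delta_exit = delta_exit, n_max = as.integer(n_max),
                 tol = tol),
            class = "oracle_config")
}

# growth-then-shrink kernel row: distribution of Binom(n + X, 1 - d) with
# X ~ Binom(n, q), as a vector over 0..n_max (before 0 -> 1 remapping)
grow_shrink_row <- function(n, q, d, n_max) {
  row <- numeric(n_max + 1)
  xs <- qbinom(1e-15, n, q):qbinom(1e-15, n, q, lower.tail = FALSE)
  wx <- dbinom(xs, n, q)
  if (d == 0) {
    tgt <- pmin(n + xs, n_max)
    for (k in seq_along(xs)) row[tgt[k] + 1] <- row[tgt[k] + 1] + wx[k]
    return(row)
  }
  for (k in seq_along(xs)) {
    m <- n + xs[k]
    klo <- qbinom(1e-15, m, 1 - d)
    khi <- qbinom(1e-15, m, 1 - d, lower.tail = FALSE)
    ks <- klo:khi
    pk <- dbinom(ks, m, 1 - d) * wx[k]
    ks <- pmin(ks, n_max)
    idx <- ks + 1
    # accumulate (indices can repeat after clipping at n_max)
    for (j in seq_along(idx)) row[idx[j]] <- row[idx[j]] + pk[j]
  }
  row[1] <- row[1] + max(0, 1 - sum(row))  # truncated binomial tails
  row
}

#' One-iteration transition distribution of a single urn
#'
#' Exact distribution of the urn's size after one full iteration, starting
#' from size `n`: case I composes binomial growth with binomial thinning;
#' case II puts mass `delta_exit` on size 1 (the replacing urn is "the same
#' urn") and grows the survivor; the mixed case combines both.  Mass at 0
#' (urns emptied by shrinking) is remapped to 1 -- the replacement step --
#' unless `remap = FALSE`.
#'
#' @param n Starting size, in `1..n_max`.
#' @param config An [oracle_config()].
#' @param remap Apply the 0 -> 1 replacement remapping (default `TRUE`).
#' @return Numeric vector of probabilities over sizes `0..n_max` (index
#'   `i` is size `i - 1`); with `remap = TRUE` the mass at size 0 is 0.
#' @export
transition_pmf <- function(n, config, remap = TRUE) {
  stopifnot(inherits(config, "oracle_config"))
  if (n < 1 || n > config$n_max) stop_domain("`n` out of range 1..n_max")
  n_max <- config$n_max
  row <- switch(
    config$mode,
    shrink_only = grow_shrink_row(n, config$q, config$delta_shrink, n_max),
    exit_only = {
      r <- grow_shrink_row(n, config$q, 0, n_max) * (1 - config$delta_exit)
      r[2] <- r[2] + config$delta_exit
      r
    },
    mixed = {
      r <- grow_shrink_row(n, config$q, config$delta_shrink, n_max) *
        (1 - config$delta_exit)
      r[2] <- r[2] + config$delta_exit
      r
    })
  if (remap) {
    row[2] <- row[2] + row[1]
    row[1] <- 0
  }
  row
}

#' Exact stationary size distribution of the single-urn chain
#'
#' Builds the truncated transition matrix row by row and finds its
#' stationary distribution by power iteration from the uniform start (the
#' method is deterministic; no seed involved), stopping when the
#' total-variation change per sweep drops below `config$tol`.
#'
#' @param config An [oracle_config()].
#' @param max_iter Safety cap on power-iteration sweeps.
#' @return Tibble with columns `n` (sizes `1..n_max`) and `prob`.
#' @export
oracle_stationary <- function(config, max_iter = 1e6) {
  stopifnot(inherits(config, "oracle_config"))
  n_max <- config$n_max
  P <- matrix(0, n_max, n_max)
  for (n in seq_len(n_max)) {
    P[n, ] <- transition_pmf(n, config)[-1]
  }
  v <- rep(1 / n_max, n_max)
  for (it in seq_len(max_iter)) {
    v_new <- as.vector(v %*% P)
    v_new <- v_new / sum(v_new)
    if (0.5 * sum(abs(v_new - v)) < config$tol) {
      return(tibble(n = seq_len(n_max), prob = v_new))
    }
    v <- v_new
  }
  stop_domain("power iteration did not converge within max_iter sweeps")
}

#' Mean-field stationary parameters matching an adaptive-q run
#'
#' For the exit-only process, the adaptive rule pins the expected
#' post-growth total at `N0 (1 + q0)`; exits then remove a fraction
#' `delta_exit` of balls and replacements add one ball per exited urn, so
#' the stationary total and attraction probability solve a one-step fixed
#' point.  For the shrink-only process the shrink step restores `N0`
#' exactly in expectation, so `q* = q0`.
#'
#' @param config An [urn_config()].
#' @return List with `q` (stationary attraction probability) and
#'   `delta_shrink` (stationary per-ball deletion probability; 0 in
#'   exit-only mode).
#' @export
stationary_parameters <- function(config) {
  stopifnot(inherits(config, "urn_config"))
  G <- config$N0 * (1 + config$q0)   # expected post-growth total
  if (config$mode == "shrink_only") {
    return(list(q = config$q0, delta_shrink = config$q0 / (1 + config$q0)))
  }
  if (config$mode == "exit_only") {
    # survivors keep (1 - delta) G balls; ~delta_exit * M replacements at 1
    N_star <- (1 - config$delta_exit) * G + config$delta_exit * config$M
    return(list(q = G / N_star - 1, delta_shrink = 0))
  }
  # mixed: the conservation-consistent shrink rate keeps N near N0
  de <- config$delta_exit
  d_s <- max(0, 1 - (config$N0 - de * config$M) / ((1 - de) * G))
  list(q = config$q0, delta_shrink = d_s)
}
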