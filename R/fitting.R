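# Log normalizing constant and model moments of the discrete law
# P(n) propto n^-(alpha+1) e^(-beta n), n = a0, a0+1, ...
# Truncated series (terms up to `n_terms`) plus an Euler-Maclaurin midpoint
# integral tail, so small alpha with beta = 0 is handled accurately.
plcut_discrete_suff <- function(alpha, beta, a0 = 1, n_terms = 1e5) {
  N <- a0 + n_terms - 1
  if (beta > 0) N <- min(N, a0 + ceiling(746 / beta))
  n <- seq.int(a0, N)
  lt <- -(alpha + 1) * log(n) - beta * n
  keep <- lt > -745
  n <- n[keep]
  t0 <- exp(lt[keep])
  S0 <- sum(t0)
  S1 <- sum(log(n) * t0)
  S2 <- sum(n * t0)
  Nc <- N + 0.5
  if (beta < 1e-14) {
    T0 <- Nc^(-alpha) / alpha
    T1 <- Nc^(-alpha) * (alpha * log(Nc) + 1) / alpha^2
    T2 <- if (alpha > 1) Nc^(1 - alpha) / (alpha - 1) else Inf
  } else {
    x <- beta * Nc
    T0 <- beta^alpha * upper_incomplete_gamma(-alpha, x)
    T2 <- beta^(alpha - 1) * upper_incomplete_gamma(1 - alpha, x)
    T1 <- tryCatch(
      integrate(function(u) exp(-(alpha + 1) * log(u) - beta * u) * log(u),
                Nc, Inf, rel.tol = 1e-10)$value,
      error = function(e) 0)
  }
  Z <- S0 + T0
  list(logZ = log(Z), Elog = (S1 + T1) / Z, En = (S2 + T2) / Z)
}

#' Fit a discrete power law with exponential cutoff by maximum likelihood
#'
#' Maximizes the likelihood of `P(n) propto n^-(alpha+1) e^(-beta n)` on
#' integer support `n >= a0` over `alpha in (0.02, 10)` and
#' `beta in [0, 5]`.  Standard errors come from the observed information at
#' the optimum; a `beta`-at-zero solution is flagged as a boundary case
#' (its `beta` standard error is then reported as `NA`).
#'
#' @param sizes Integer sizes/degrees (all >= `a0`), or distinct values when
#'   `count` is given.
#' @param count Optional counts (or probability weights) matching `sizes`,
#'   e.g. from a tabulated sample or an exact pmf.
#' @param a0 Lower support bound of the fitted law.
#' @param beta_fixed Optionally pin `beta` (e.g. `0` for a pure discrete
#'   Pareto fit) and profile only `alpha`.
#' @return An object of class `plcut_fit` with estimates, standard errors,
#'   log-likelihood, and flags.  Use [tidy()] / [glance()] for tibbles.
#' @examples
#' x <- rplcut(2000, alpha = 0.8, beta = 0.02, n_max = 1e4)
#' fit <- fit_powerlaw_cutoff(x)
#' tidy(fit)
#' @export
fit_powerlaw_cutoff <- function(sizes, count = NULL, a0 = 1,
                                beta_fixed = NULL) {
  if (is.null(count)) {
    count <- rep(1, length(sizes))
  }
  stopifnot(length(sizes) == length(count), all(count >= 0))
  keep <- count > 0
  sizes <- sizes[keep]; count <- count[keep]
  if (any(sizes < a0)) stop_domain("all sizes must be >= a0")
  ntot <- sum(count)
  if (length(unique(sizes)) < 2) {
    stop_domain("degenerate sample: need at least two distinct sizes")
  }
  mlog <- sum(count * log(sizes)) / ntot
  mlin <- sum(count * sizes) / ntot
  nll <- function(p) {
    s <- plcut_discrete_suff(p[1], p[2], a0)
    s$logZ + (p[1] + 1) * mlog + p[2] * mlin
  }
  if (!is.null(beta_fixed)) {
    opt <- optimize(function(a) nll(c(a, beta_fixed)), c(0.02, 10),
                    tol = 1e-10)
    alpha_hat <- opt$minimum
    h <- 1e-4
    info <- (nll(c(alpha_hat + h, beta_fixed)) +
               nll(c(alpha_hat - h, beta_fixed)) -
               2 * nll(c(alpha_hat, beta_fixed))) / h^2
    return(new_plcut_fit(alpha_hat, beta_fixed,
                         se = c(1 / sqrt(ntot * info), NA_real_),
                         loglik = -ntot * opt$objective, ntot, a0,
                         boundary = TRUE, beta_profiled = TRUE))
  }
  alpha0 <- min(max(1 / max(mlog, 0.05), 0.05), 8)
  starts <- list(c(alpha0, 0.5 / mlin), c(alpha0, 1e-3), c(1, 0.05))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      optim(p0, nll, method = "L-BFGS-B", lower = c(0.02, 0),
            upper = c(10, 5),
            control = list(factr = 1e3, maxit = 300,
                           ndeps = c(1e-6, 1e-6))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop_domain("likelihood optimization failed")
  p <- best$par
  boundary <- p[2] < 1e-7
  H <- tryCatch(optimHess(p, nll, control = list(ndeps = c(1e-5, 1e-5))),
                error = function(e) NULL)
  se <- c(NA_real_, NA_real_)
  if (boundary) {
    h <- 1e-4
    info <- (nll(c(p[1] + h, p[2])) + nll(c(p[1] - h, p[2])) -
               2 * nll(p)) / h^2
    se[1] <- 1 / sqrt(ntot * info)
  } else if (!is.null(H)) {
    V <- tryCatch(solve(ntot * H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V) > 0)) se <- sqrt(diag(V))
  }
  new_plcut_fit(p[1], p[2], se, loglik = -ntot * best$value, ntot, a0,
                boundary = boundary, beta_profiled = FALSE)
}

new_plcut_fit <- function(alpha, beta, se, loglik, n, a0, boundary,
                          beta_profiled) {
  structure(
    list(alpha = alpha, beta = beta, stderr_alpha = se[1],
         stderr_beta = se[2], loglik = loglik, n = n, a0 = a0,
         boundary = boundary, beta_profiled = beta_profiled),
    class = "plcut_fit")
}

#' @export
print.plcut_fit <- function(x, ...) {
  cat(sprintf(
    "<plcut_fit> alpha = %.4f (se %.4f), beta = %.5g (se %s)%s\n",
    x$alpha, x$stderr_alpha, x$beta,
    ifelse(is.na(x$stderr_beta), "NA", sprintf("%.5g", x$stderr_beta)),
    if (x$boundary) " [beta boundary]" else ""))
  cat(sprintf("  n = %g, a0 = %g, loglik = %.2f\n", x$n, x$a0, x$loglik))
  invisible(x)
}

#' Estimate the fluctuation-scaling exponent omega
#'
#' The conditional standard deviation of one-iteration size changes scales
#' as `sd(n' - n | n) ~ n^omega`; `omega = 0.5` for binomial (Taylor-law)
#' dynamics and `omega = 1` for multiplicative noise.  Sizes are binned
#' geometrically, bins with fewer than `min_per_bin` pairs are merged
#' upward, and `omega` is the OLS slope of `log(sd)` on `log(bin mean
#' size)`.
#'
#' @param pairs Data frame with columns `n_before` and `n_after` (e.g. the
#'   `pairs` element of an `urn_run`).
#' @param ratio Geometric bin ratio (default 1.5).
#' @param min_per_bin Minimum pairs per bin before merging (default 30).
#' @param n_min Discard pairs with `n_before < n_min` (useful when an
#'   additive noise floor dominates small sizes).
#' @param detrend Remove a linear conditional-mean trend of the change
#'   within each bin before taking the standard deviation (default
#'   `TRUE`).  When survivors drift (e.g. uncompensated growth `+q n` in
#'   the exit-only process) the raw within-bin sd mixes that drift's
#'   variation across the bin into the fluctuation being measured;
#'   detrending recovers the sd of the change about its conditional mean,
#'   which is the scaling quantity.  With no drift the two coincide.
#' @return An object of class `omega_fit`; `tidy()` returns the per-bin
#'   table, `glance()` the slope and fit summary.
#' @export
estimate_omega <- function(pairs, ratio = 1.5, min_per_bin = 30, n_min = 1,
                           detrend = TRUE) {
  stopifnot(all(c("n_before", "n_after") %in% names(pairs)))
  pairs <- dplyr::filter(pairs, .data$n_before >= n_min)
  if (nrow(pairs) < 100) stop_domain("need at least 100 pairs")
  nb <- pairs$n_before
  # centre by the known per-iteration expected growth factor when the
  # simulator recorded one, so that iteration-to-iteration drift variation
  # does not masquerade as size-dependent fluctuation
  delta <- if ("expected_factor" %in% names(pairs)) {
    pairs$n_after - pairs$expected_factor * pairs$n_before
  } else {
    pairs$n_after - pairs$n_before
  }
  edges <- n_min * ratio^(0:ceiling(log(max(nb) / n_min, ratio) + 1))
  bin <- findInterval(nb, edges, rightmost.closed = TRUE)
  # merge bins with < min_per_bin pairs into the next (larger-size) bin;
  # a sparse final group falls back onto the previous one
  tab <- table(bin)
  ids <- as.integer(names(tab))
  counts <- as.integer(tab)
  group <- integer(length(ids))
  g <- 1L; acc <- 0L
  for (k in seq_along(ids)) {
    group[k] <- g
    acc <- acc + counts[k]
    if (acc >= min_per_bin && k < length(ids)) {
      g <- g + 1L
      acc <- 0L
    }
  }
  if (acc < min_per_bin && acc > 0L && g > 1L) {
    group[group == g] <- g - 1L
  }
  bin <- group[match(bin, ids)]
  cond_sd <- function(n, delta) {
    if (!detrend || length(unique(n)) < 3) return(sd(delta))
    sd(stats::residuals(lm(delta ~ n)))
  }
  stats_tbl <- tibble(bin = bin, n = nb, delta = delta) |>
    dplyr::summarise(center = mean(.data$n),
                     sd = cond_sd(.data$n, .data$delta),
                     n_pairs = dplyr::n(), .by = "bin") |>
    dplyr::filter(.data$sd > 0) |>
    dplyr::arrange(.data$center)
  if (nrow(stats_tbl) < 5) {
    stop_domain("fewer than 5 occupied size bins; cannot estimate omega")
  }
  fit <- lm(log(sd) ~ log(center), data = stats_tbl)
  sm <- summary(fit)
  structure(
    list(omega = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         stderr = sm$coefficients[2, 2], r2 = sm$r.squared,
         n_bins = nrow(stats_tbl), n_pairs = nrow(pairs), bins = stats_tbl),
    class = "omega_fit")
}

#' @export
print.omega_fit <- function(x, ...) {
  cat(sprintf(
    "<omega_fit> omega = %.4f (se %.4f), r^2 = %.4f over %d bins (%d pairs)\n",
    x$omega, x$stderr, x$r2, x$n_bins, x$n_pairs))
  invisible(x)
}

#' Logarithmically binned density histogram
#'
#' Geometric bins (default ratio 1.5) with densities normalized by bin
#' width, the standard way to display heavy-tailed size data on a
#' double-logarithmic scale.  Empty bins are omitted.
#'
#' @param x Positive samples.
#' @param ratio Geometric bin ratio.
#' @return Tibble with `center` (geometric bin midpoint), `density`,
#'   `width`, and `count`; `sum(density * width)` is 1.
#' @export
log_binned_histogram <- function(x, ratio = 1.5) {
  stopifnot(all(x > 0), ratio > 1)
  lo <- min(x)
  k <- ceiling(log(max(x) / lo, ratio) + 1e-9)
  edges <- lo * ratio^(0:max(k, 1))
  edges[length(edges)] <- max(edges[length(edges)], max(x) * (1 + 1e-12))
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  cnt <- tabulate(bin, nbins = length(edges) - 1)
  keep <- cnt > 0
  width <- diff(edges)
  tibble(center = sqrt(edges[-length(edges)] * edges[-1])[keep],
         density = (cnt / length(x) / width)[keep],
         width = width[keep], count = cnt[keep])
}
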