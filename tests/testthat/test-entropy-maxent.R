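test_that("exact binomial entropies match direct sums", {
  expect_equal(binomial_entropy_exact(1, 0.5), log(2), tolerance = 1e-12)
  # independent direct sums
  expect_equal(binomial_entropy_exact(1, 0.1),
               -(0.9 * log(0.9) + 0.1 * log(0.1)), tolerance = 1e-12)
  p2 <- c(0.81, 0.18, 0.01)
  expect_equal(binomial_entropy_exact(2, 0.1), -sum(p2 * log(p2)),
               tolerance = 1e-12)
  expect_equal(binomial_entropy_exact(5, 0), 0)
})

test_that("the small-size entropy ratio sits near 0.6", {
  expect_equal(small_n_entropy_ratio(0.05), 0.599, tolerance = 2e-3)
  expect_equal(small_n_entropy_ratio(0.1), 0.6187, tolerance = 2e-3)
  expect_error(small_n_entropy_ratio(0), "undefined")
  # q -> 0 limit approaches 1/2 from above
  expect_gt(small_n_entropy_ratio(1e-6), 0.5)
  expect_lt(small_n_entropy_ratio(1e-6), 0.55)
})

test_that("large-n entropy approximation matches the exact binomial", {
  expect_lt(abs(per_urn_entropy(100, 0.1, "exit_only") -
                  binomial_entropy_exact(100, 0.1)), 0.01)
  # sigma ~ sqrt(n): quadrupling n shifts the entropy by log 2, any mode
  for (mode in c("shrink_only", "exit_only")) {
    expect_equal(per_urn_entropy(40, 0.05, mode) -
                   per_urn_entropy(10, 0.05, mode), log(2),
                 tolerance = 1e-12)
  }
  # case difference is size-independent
  d <- per_urn_entropy(c(2, 20, 200), 0.05, "shrink_only") -
    per_urn_entropy(c(2, 20, 200), 0.05, "exit_only")
  expect_lt(diff(range(d)), 1e-12)
})

test_that("C is the log geometric mean and is permutation-invariant", {
  expect_equal(compute_C(rep(1, 10)), 0)
  expect_equal(compute_C(c(1, 2, 4, 8)), 6 * log(2) / 4, tolerance = 1e-12)
  expect_equal(compute_C(c(8, 1, 4, 2)), compute_C(c(1, 2, 4, 8)))
  expect_equal(compute_C(c(2, 5), count = c(3, 1)),
               (3 * log(2) + log(5)) / 4)
  expect_error(compute_C(c(1, 0.5)), "sizes")
})

test_that("the size-1 correction raises C and respects both scales", {
  x <- c(rep(1, 50), rep(4, 50))
  expect_gte(compute_C_corrected(x, q = 0.05), compute_C(x))
  # no size-1 urns: correction is inert
  y <- c(2, 3, 4, 8)
  expect_equal(compute_C_corrected(y, q = 0.1), compute_C(y))
  # all-ones sample reduces to the substituted value on each scale
  ones <- rep(1, 20)
  expect_equal(compute_C_corrected(ones, q = 0.1, s2_scale = "half"),
               small_n_entropy_ratio(0.1) * 0.5 * log(2), tolerance = 1e-9)
  expect_equal(compute_C_corrected(ones, q = 0.1, s2_scale = "full"),
               small_n_entropy_ratio(0.1) * log(2), tolerance = 1e-9)
  expect_equal(compute_C_corrected(ones, q = 0.1, s2_scale = "half"),
               0.2144, tolerance = 1e-3)
})

test_that("C decreases under mean-preserving spread", {
  base <- rep(10, 100)
  spreads <- list(c(rep(8, 50), rep(12, 50)),
                  c(rep(5, 50), rep(15, 50)),
                  c(rep(2, 50), rep(18, 50)))
  cs <- c(compute_C(base), vapply(spreads, compute_C, numeric(1)))
  expect_true(all(vapply(spreads, mean, numeric(1)) == 10))
  expect_true(all(diff(cs) < 0))
})

test_that("alpha follows 1/(C - log a0) in the cutoff-free case", {
  expect_equal(alpha_from_C(2), 0.5)
  expect_equal(alpha_from_C(1), 1)
  expect_equal(alpha_from_C(1, a0 = exp(0.5)), 2)
  expect_error(alpha_from_C(0.2, a0 = 2), "infeasible")
  # identity alpha * (C - log a0) = 1 round trips through the moments
  for (alpha in c(0.4, 1.3, 3)) {
    C <- stablesize:::plcut_cont_moments(alpha, 0, 1)$Elog
    expect_equal(alpha_from_C(C), alpha, tolerance = 1e-8)
  }
  # parameter recovery on a continuous Pareto sample
  set.seed(3)
  x <- runif(1e6)^(-1 / 0.8)
  expect_lt(abs(alpha_from_C(mean(log(x))) / 0.8 - 1), 0.02)
})

test_that("normalization closes in both closed-form and numeric branches", {
  expect_equal(normalization_K(0.5, 0, 1), 0.5)
  expect_equal(normalization_K(1, 0, 1), 1)
  for (p in list(c(0.5, 0.02, 1), c(1.2, 0.3, 2), c(0.8, 1e-6, 1))) {
    K <- normalization_K(p[1], p[2], p[3])
    total <- integrate(function(x) K * x^(-(p[1] + 1)) * exp(-p[2] * x),
                       p[3], Inf, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-7)
  }
  expect_error(normalization_K(-0.5, 0), "non-normalizable")
})

test_that("the constraint solver recovers planted parameters", {
  m <- stablesize:::plcut_cont_moments(0.8, 0.02, 1)
  sol <- solve_alpha_beta(m$Elog, m$En)
  expect_lt(abs(sol$alpha - 0.8), 1e-4)
  expect_lt(abs(sol$beta - 0.02), 1e-4)
  expect_lt(abs(sol$implied_C - m$Elog), 1e-6)
  expect_lt(abs(sol$implied_E / m$En - 1), 1e-6)
  # beta -> 0 degenerate limit agrees with the closed form
  sol0 <- solve_alpha_beta(2, 1e4)
  expect_lt(abs(sol0$alpha - alpha_from_C(2)), 1e-3)
  # at fixed E, larger C gives smaller alpha (feasible C at E = 12 starts
  # at the beta = 0 boundary value (E - 1)/E ~ 0.917)
  as <- vapply(c(0.95, 1.1, 1.3, 1.5),
               function(C) solve_alpha_beta(C, 12)$alpha, numeric(1))
  expect_true(all(diff(as) < 0))
  # infeasible targets are reported, not silently absorbed
  expect_error(solve_alpha_beta(0.9, 25), "no maximum-entropy solution")
})

test_that("tidiers expose solutions as tibbles", {
  sol <- solve_alpha_beta(1.2, 8)
  td <- tidy(sol)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, c("alpha", "beta", "K", "lambda"))
  expect_equal(glance(sol)$implied_E, 8, tolerance = 1e-5)
})

test_that("upper incomplete gamma matches quadrature for negative orders", {
  for (s in c(-2.3, -0.7, 0.4)) {
    for (x in c(0.05, 1, 4)) {
      ref <- integrate(function(t) t^(s - 1) * exp(-t), x, Inf,
                       rel.tol = 1e-12)$value
      expect_equal(upper_incomplete_gamma(s, x), ref, tolerance = 1e-7)
    }
  }
})
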