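test_that("one-step transition rows are proper distributions", {
  for (cfg in list(oracle_config("shrink_only", q = 0.05),
                   oracle_config("exit_only", q = 0.05, delta_exit = 0.1),
                   oracle_config("mixed", q = 0.05, delta_exit = 0.05))) {
    for (n in c(1, 7, 150, 1990)) {
      row <- transition_pmf(n, cfg)
      expect_equal(sum(row), 1, tolerance = 1e-12)
      expect_equal(row[1], 0)  # replacement removes state 0
    }
  }
  expect_error(transition_pmf(0, oracle_config("exit_only", delta_exit = 0.1)),
               "range")
})

test_that("the grow-and-shrink kernel is a martingale before replacement", {
  cfg <- oracle_config("shrink_only", q = 0.05)
  for (n in c(5, 60, 400)) {
    row <- transition_pmf(n, cfg, remap = FALSE)
    expect_equal(sum((0:cfg$n_max) * row), n, tolerance = 1e-9)
  }
})

test_that("certain exit collapses the chain onto size 1", {
  cfg <- oracle_config("exit_only", q = 0.05, delta_exit = 1, n_max = 100)
  expect_equal(transition_pmf(10, cfg)[2], 1)
  st <- oracle_stationary(cfg)
  expect_equal(st$prob[1], 1, tolerance = 1e-10)
})

test_that("the stationary law solves the fixed-point equation", {
  cfg <- oracle_config("exit_only", q = 0.04, delta_exit = 0.05,
                       n_max = 600)
  st <- oracle_stationary(cfg)
  P <- t(vapply(seq_len(cfg$n_max),
                function(n) transition_pmf(n, cfg)[-1],
                numeric(cfg$n_max)))
  v <- as.vector(st$prob %*% P)
  expect_lt(0.5 * sum(abs(v - st$prob)), 1e-10)
  # scalefree over an intermediate range: log-log slope stable between
  # the first and second decade above the re-entry scale
  sl <- function(lo, hi) {
    sel <- st$n >= lo & st$n <= hi
    unname(coef(lm(log(st$prob[sel]) ~ log(st$n[sel])))[2])
  }
  expect_lt(abs(sl(3, 30) - sl(30, 300)), 0.35)
})

test_that("truncation is immaterial once the tail is exponentially light", {
  base <- oracle_config("exit_only", q = 0.03, delta_exit = 0.1,
                        n_max = 500)
  dbl <- oracle_config("exit_only", q = 0.03, delta_exit = 0.1,
                       n_max = 1000)
  s1 <- oracle_stationary(base)
  s2 <- oracle_stationary(dbl)
  tv <- 0.5 * (sum(abs(s2$prob[1:500] - s1$prob)) + sum(s2$prob[501:1000]))
  expect_lt(tv, 1e-6)
})

test_that("simulation with frozen parameters reproduces the exact law", {
  q <- 0.04; de <- 0.05
  oc <- oracle_config("exit_only", q = q, delta_exit = de, n_max = 2000)
  pmf <- oracle_stationary(oc)
  cfg <- urn_config(M = 5e3, E = round(sum(pmf$n * pmf$prob)), q0 = q,
                    mode = "exit_only", delta_exit = de, iterations = 750,
                    burn_in = 300, thin = 15, q_fixed = TRUE, seed = 55)
  run <- run_quiet(simulate_urns(cfg, collect_pairs = FALSE))
  emp <- tabulate(pmin(run$sizes, 2000), nbins = 2000) / length(run$sizes)
  expect_lt(0.5 * sum(abs(emp - pmf$prob)), 0.02)
})

test_that("the exact loop closes: fitted exponent vs corrected entropy", {
  # full-turnover chain: the scaling-regime exponent of the exact
  # stationary pmf agrees with 1/C_corr computed on the same pmf
  oc <- oracle_config("exit_only", q = 0.0474, delta_exit = 0.05,
                      n_max = 2000)
  pmf <- oracle_stationary(oc)
  Cc <- compute_C_corrected(pmf$n, q = oc$q, count = pmf$prob)
  fit <- fit_powerlaw_cutoff(pmf$n[pmf$n >= 5],
                             count = pmf$prob[pmf$n >= 5] * 1e6, a0 = 5)
  expect_lt(abs(fit$alpha * Cc - 1), 0.1)
})

test_that("mean-field stationary parameters match their balance equations", {
  cfg <- urn_config(M = 1e4, E = 10, q0 = 0.05, mode = "shrink_only")
  sp <- stationary_parameters(cfg)
  expect_equal(sp$q, 0.05)
  expect_equal(sp$delta_shrink, 0.05 / 1.05)
  cfg2 <- urn_config(M = 1e4, E = 10, q0 = 0.05, mode = "exit_only",
                     delta_exit = 0.05)
  sp2 <- stationary_parameters(cfg2)
  G <- cfg2$N0 * 1.05
  expect_equal(sp2$q, G / (0.95 * G + 0.05 * 1e4) - 1, tolerance = 1e-12)
})
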