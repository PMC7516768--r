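test_that("config validation enforces the process invariants", {
  expect_error(urn_config(M = 100, E = 10, q0 = 0), "q0")
  expect_error(urn_config(M = 100, E = 10, mode = "shrink_only",
                          delta_exit = 0.1), "shrink_only")
  expect_error(urn_config(M = 100, N0 = 50), "N0 >= M")
  cfg <- urn_config(M = 100, E = 10)
  expect_s3_class(cfg, "urn_config")
  expect_equal(cfg$N0, 1000L)
})

test_that("growth step draws binomial gains with the right moments", {
  st <- stablesize:::new_urn_state(rep(10L, 1e5), q = 0.05)
  set.seed(1)
  g <- grow_step(st)
  x <- g$gains
  # binomial mean nq and variance nq(1-q), each within 3 standard errors
  expect_lt(abs(mean(x) - 0.5), 3 * sqrt(0.475 / 1e5))
  expect_lt(abs(var(x) - 0.475), 3 * 0.475 * sqrt(2 / 1e5) * 1.5)
  expect_equal(g$state$sizes, st$sizes + x)
  # q = 0 is a deterministic no-op
  st0 <- stablesize:::new_urn_state(rep(10L, 100), q = 0)
  expect_true(all(grow_step(st0)$gains == 0))
})

test_that("shrink step balances growth and conserves the expected total", {
  st <- stablesize:::new_urn_state(rep(10L, 1000), q = 0.05)
  # printed-formula arithmetic: delta = sum(X) / (N + sum(X)) at N = N0
  s <- shrink_step(st, rep(0L, 1000))
  expect_equal(s$delta_shrink, 0)
  expect_true(all(s$losses == 0))
  st2 <- stablesize:::new_urn_state(rep(10L, 1000), q = 0.05)
  gains <- rep(5L, 100)  # total 500 on N = 10000
  st2$sizes[1:100] <- st2$sizes[1:100] + gains
  st2b <- st2; st2b$N <- 10000L
  s2 <- shrink_step(st2b, c(gains, rep(0L, 900)))
  expect_equal(s2$delta_shrink, 500 / 10500, tolerance = 1e-12)
  # post-shrink expected total equals the pre-growth total: MC over
  # replicates of one grow+shrink cycle
  set.seed(2)
  totals <- replicate(300, {
    st <- stablesize:::new_urn_state(rep(20L, 500), q = 0.05)
    g <- grow_step(st)
    sum(shrink_step(g$state, g$gains)$state$sizes)
  })
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - 10000), 3 * se)
})

test_that("exit and replace steps conserve M and reset emptied urns", {
  st <- stablesize:::new_urn_state(rep(3L, 1e4), q = 0.05)
  set.seed(3)
  e <- exit_step(st, 0.1)
  expect_lt(abs(length(e$exited_ids) - 1000), 3 * sqrt(1e4 * 0.1 * 0.9))
  expect_true(all(e$state$sizes[e$exited_ids] == 0))
  r <- replace_step(e$state)
  expect_equal(r$n_replaced, length(e$exited_ids))
  expect_equal(length(r$state$sizes), 1e4)
  expect_gte(min(r$state$sizes), 1)
  # boundary cases
  expect_equal(length(exit_step(st, 0)$exited_ids), 0)
  expect_equal(length(exit_step(st, 1)$exited_ids), 1e4)
})

test_that("q adjustment pins the expected post-growth total", {
  cfg <- urn_config(M = 1000, N0 = 10000, q0 = 0.05)
  expect_equal(update_q(10000, cfg), 0.05)
  expect_equal(update_q(10200, cfg), 10500 / 10200 - 1, tolerance = 1e-12)
  # boundary: N at the cap would give q = 0; clamped with a warning
  expect_warning(q <- update_q(10500, cfg), "clamped")
  expect_gt(q, 0)
  expect_error(update_q(0, cfg), "degenerate")
})

test_that("one iteration preserves urn count and the per-urn martingale", {
  cfg <- urn_config(M = 2000, E = 20, q0 = 0.05, mode = "shrink_only",
                    iterations = 1, burn_in = 0)
  set.seed(4)
  # E[n_{t+1} | n_t] = n_t for one iteration from a fresh state (MC over
  # many replicates of single iterations at n = 20)
  deltas <- replicate(60, {
    st <- stablesize:::new_urn_state(rep(20L, 2000), q = 0.05)
    step <- run_quiet(iterate_urns(st, cfg))
    mean(step$state$sizes - 20)
  })
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3 * se + 1e-3)
  st <- stablesize:::new_urn_state(rep(20L, 2000), q = 0.05)
  out <- run_quiet(iterate_urns(st, cfg))
  expect_equal(length(out$state$sizes), 2000)
  expect_gte(min(out$state$sizes), 1)
})

test_that("runs are seed-reproducible and the total stays near N0", {
  cfg <- urn_config(M = 2000, E = 10, q0 = 0.05, mode = "shrink_only",
                    iterations = 300, burn_in = 100, seed = 11)
  r1 <- run_quiet(simulate_urns(cfg))
  r2 <- run_quiet(simulate_urns(cfg))
  expect_identical(r1$sizes, r2$sizes)
  expect_identical(r1$trajectory, r2$trajectory)
  # time-averaged N within 1% of N0
  expect_lt(abs(mean(r1$trajectory$N) / cfg$N0 - 1), 0.01)
  # zero-iteration run returns the initial state
  r0 <- simulate_urns(urn_config(M = 10, E = 5, iterations = 0,
                                 burn_in = 0, seed = 1))
  expect_true(all(r0$state$sizes == 5))
})

test_that("turnover rate mu spans its range across the three modes", {
  rI <- run_quiet(simulate_urns(urn_config(
    M = 2000, E = 10, mode = "shrink_only", iterations = 100,
    burn_in = 100, seed = 21)))
  rII <- run_quiet(simulate_urns(urn_config(
    M = 2000, E = 10, mode = "exit_only", delta_exit = 0.05,
    iterations = 100, burn_in = 100, seed = 22)))
  rIII <- run_quiet(simulate_urns(urn_config(
    M = 2000, E = 10, mode = "mixed", delta_exit = 0.02,
    iterations = 100, burn_in = 100, seed = 23)))
  expect_equal(measure_turnover(rI)$mu, 0)
  expect_equal(measure_turnover(rII)$mu, 1)
  mu3 <- measure_turnover(rIII)$mu
  expect_gt(mu3, 0.1)
  expect_lt(mu3, 0.9)
})
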