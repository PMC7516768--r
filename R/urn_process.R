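#' Configure a stable-size urn process
#'
#' Sets up the discrete-time urn-and-ball process in which `M` urns exchange
#' balls with a reservoir by preferential attachment while the expected total
#' number of balls stays at its initial value `N0 = M * E`.  One iteration is
#' grow -> shrink (cases I/III) -> urn exit (cases II/III) -> replacement of
#' emptied urns by urns of size 1 -> adjustment of the attraction probability.
#'
#' The three canonical modes are `"shrink_only"` (case I: balls vanish
#' individually, urns never exit while positive), `"exit_only"` (case II: urns
#' only grow, but exit with all their balls at rate `delta_exit`), and
#' `"mixed"` (case III: both mechanisms).
#'
#' @param M Number of urns (held exactly constant).
#' @param E Target mean urn size; the initial ball count is `N0 = M * E`
#'   unless `N0` is given explicitly.
#' @param q0 Initial per-ball attraction probability, in (0, 1).
#' @param mode One of `"shrink_only"`, `"exit_only"`, `"mixed"`.
#' @param delta_exit Per-iteration urn exit probability (step 3); must be 0
#'   for `mode = "shrink_only"`.
#' @param iterations Number of recorded iterations after burn-in.
#' @param burn_in Iterations discarded before recording.
#' @param thin Interval (in iterations) between pooled size snapshots.
#' @param N0 Initial total ball count; defaults to `M * E`.
#' @param q_fixed If `TRUE`, the attraction probability is held at `q0`
#'   instead of being adjusted each iteration (used to match the
#'   fixed-parameter master-equation oracle, where urns decouple).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#'
#' @return An object of class `urn_config`.
#' @seealso [simulate_urns()], [oracle_config()]
#' @export
urn_config <- function(M, E = 10, q0 = 0.05,
                       mode = c("shrink_only", "exit_only", "mixed"),
                       delta_exit = 0, iterations = 200, burn_in = 100,
                       thin = 10, N0 = NULL, q_fixed = FALSE, seed = NULL) {
  mode <- match.arg(mode)
  M <- as.integer(M)
  N0 <- as.integer(N0 %||% round(M * E))
  stopifnot(M >= 1, N0 >= M, iterations >= 0, burn_in >= 0, thin >= 1)
  if (q0 <= 0 || q0 >= 1) stop_domain("`q0` must be in (0, 1)")
  if (delta_exit < 0 || delta_exit > 1) {
    stop_domain("`delta_exit` must be in [0, 1]")
  }
  if (mode == "shrink_only" && delta_exit != 0) {
    stop_domain("`mode = \"shrink_only\"` requires `delta_exit = 0`")
  }
  structure(
    list(M = M, N0 = N0, E = N0 / M, q0 = q0, mode = mode,
         delta_exit = delta_exit, iterations = as.integer(iterations),
         burn_in = as.integer(burn_in), thin = as.integer(thin),
         q_fixed = isTRUE(q_fixed), seed = seed),
    class = "urn_config")
}

#' @export
print.urn_config <- function(x, ...) {
  cat("<urn_config> mode =", x$mode,
      sprintf("M = %d, N0 = %d (E = %.3g), q0 = %.4g, delta_exit = %.4g\n",
              x$M, x$N0, x$E, x$q0, x$delta_exit),
      sprintf("  %d + %d iterations, thin = %d\n",
              x$burn_in, x$iterations, x$thin))
  invisible(x)
}

new_urn_state <- function(sizes, t = 0L, q) {
  structure(list(sizes = as.integer(sizes), t = as.integer(t),
                 q = q, N = sum(as.integer(sizes))),
            class = "urn_state")
}

#' Growth step: preferential attachment of new balls
#'
#' Each ball attracts a new ball from the reservoir with probability
#' `state$q`, so urn `i` gains `X_i ~ Binomial(n_i, q)` balls -- gains are
#' proportional to size on average, which is the preferential-attachment
#' rule in urn form.
#'
#' @param state An `urn_state` (see [simulate_urns()] internals).
#' @return A list with the updated `state` and the integer vector `gains`.
#' @export
grow_step <- function(state) {
  if (state$q < 0 || state$q >= 1) {
    stop_domain("attraction probability q must be in [0, 1)")
  }
  gains <- rbinom(length(state$sizes), state$sizes, state$q)
  state$sizes <- state$sizes + gains
  list(state = state, gains = gains)
}

#' Shrink step: per-ball deletion conserving the mean total
#'
#' Every ball (post-growth) disappears with probability `delta_shrink`,
#' chosen so that the expected total after shrinking equals the process's
#' initial total `N0`: with post-growth total `N_t + sum(gains)` this is
#' `delta_shrink = (N_t + sum(gains) - N0) / (N_t + sum(gains))`, which at
#' stationarity (`N_t = N0`) reduces to `sum(gains) / (N_t + sum(gains))`
#' -- the deletion rate exactly balancing this iteration's growth.
#'
#' In the mixed case the urn-exit step that follows also removes balls, so
#' conservation requires the smaller rate `delta_shrink = 1 - (N0 -
#' delta_exit * M) / ((1 - delta_exit) * (N_t + sum(gains)))`, which
#' reduces to the pure-shrink formula when `delta_exit = 0`;
#' [iterate_urns()] passes this via `delta`.
#'
#' @param state Post-growth `urn_state` (`state$N` still holds the
#'   start-of-iteration total).
#' @param gains Integer vector of this iteration's per-urn gains.
#' @param N0 Ball-count target (the run's initial total); defaults to the
#'   start-of-iteration total, in which case shrinking exactly balances
#'   this iteration's growth.
#' @param delta Optional override of the shrink probability.
#' @return List with updated `state`, integer `losses`, and `delta_shrink`.
#' @export
shrink_step <- function(state, gains, N0 = state$N, delta = NULL) {
  gtot <- sum(gains)
  delta_shrink <- delta %||%
    min(max((state$N + gtot - N0) / (state$N + gtot), 0), 1 - 1e-12)
  losses <- if (delta_shrink == 0) integer(length(state$sizes)) else
    rbinom(length(state$sizes), state$sizes, delta_shrink)
  state$sizes <- state$sizes - losses
  list(state = state, losses = losses, delta_shrink = delta_shrink)
}

#' Exit step: urns leave with all their balls
#'
#' Each urn independently exits (size set to 0) with probability
#' `delta_exit`; its balls leave the system.
#'
#' @param state An `urn_state`.
#' @param delta_exit Exit probability in \[0, 1\].
#' @return List with updated `state`, integer vector `exited_ids`, and
#'   `balls_removed` (balls lost to exits).
#' @export
exit_step <- function(state, delta_exit) {
  if (delta_exit < 0 || delta_exit > 1) {
    stop_domain("`delta_exit` must be in [0, 1]")
  }
  exited <- which(runif(length(state$sizes)) < delta_exit)
  balls_removed <- sum(state$sizes[exited])
  state$sizes[exited] <- 0L
  list(state = state, exited_ids = exited, balls_removed = balls_removed)
}

#' Replacement step: emptied urns re-enter at size 1
#'
#' Every urn at size 0 (whether emptied by shrinking or by exit) is replaced
#' by an urn containing one ball, so the urn count `M` is strictly conserved.
#'
#' @param state An `urn_state`.
#' @return List with updated `state` and the count `n_replaced`.
#' @export
replace_step <- function(state) {
  zero <- state$sizes == 0L
  state$sizes[zero] <- 1L
  list(state = state, n_replaced = sum(zero))
}

#' Attraction-probability adjustment
#'
#' Returns the next attraction probability `q` solving
#' `N_t * (1 + q) = N0 * (1 + q0)`, i.e. the expected post-growth total is
#' pinned to its initial value, making `N_t` mean-reverting.  Values outside
#' (0, 1) (possible after a large upward fluctuation) are clamped to
#' `[1e-6, 1 - 1e-6]` with a warning.
#'
#' @param N_t Current total ball count (start of next iteration).
#' @param config An `urn_config`.
#' @return The adjusted probability.
#' @export
update_q <- function(N_t, config) {
  if (N_t <= 0) stop_domain("degenerate state: N_t must be positive")
  q <- config$N0 * (1 + config$q0) / N_t - 1
  if (q <= 0 || q >= 1) {
    warning(sprintf("adjusted q = %.3g outside (0, 1); clamped", q),
            call. = FALSE)
    q <- clamp_prob(q)
  }
  q
}

#' One full iteration of the stable-size process
#'
#' Composes grow -> shrink (if the mode has one) -> exit (if the mode has
#' one) -> replace -> q-adjustment, and returns the new state together with
#' the iteration's bookkeeping.
#'
#' @param state An `urn_state`.
#' @param config An `urn_config`.
#' @return List with the new `state` and an `outcome` list holding `gains`,
#'   `losses`, `exited_ids`, `n_replaced`, `delta_shrink`,
#'   `balls_removed_by_shrink`, `balls_removed_by_exit`, and `persisting`
#'   (logical: urns that neither exited nor were replaced).
#' @export
iterate_urns <- function(state, config) {
  n_before <- state$sizes
  q_prev <- state$q
  g <- grow_step(state)
  state <- g$state
  losses <- integer(config$M)
  delta_shrink <- 0
  if (config$mode %in% c("shrink_only", "mixed")) {
    delta <- if (config$mode == "mixed") {
      de <- config$delta_exit
      max(0, 1 - (config$N0 - de * config$M) /
            ((1 - de) * (state$N + sum(g$gains))))
    } else NULL
    s <- shrink_step(state, g$gains, N0 = config$N0, delta = delta)
    state <- s$state
    losses <- s$losses
    delta_shrink <- s$delta_shrink
  }
  exited_ids <- integer(0)
  balls_exit <- 0L
  if (config$mode %in% c("exit_only", "mixed")) {
    e <- exit_step(state, config$delta_exit)
    state <- e$state
    exited_ids <- e$exited_ids
    balls_exit <- e$balls_removed
  }
  zeroed <- state$sizes == 0L
  r <- replace_step(state)
  state <- r$state
  state$N <- sum(state$sizes)
  state$q <- if (config$q_fixed) config$q0 else update_q(state$N, config)
  state$t <- state$t + 1L
  list(state = state,
       outcome = list(gains = g$gains, losses = losses, q_used = q_prev,
                      exited_ids = exited_ids, n_replaced = r$n_replaced,
                      delta_shrink = delta_shrink,
                      balls_removed_by_shrink = sum(losses),
                      balls_removed_by_exit = balls_exit,
                      persisting = !zeroed,
                      n_before = n_before))
}

#' Simulate the stable-size urn process
#'
#' Runs `burn_in + iterations` full iterations from an even initial
#' configuration (`round(N0/M)` balls per urn) and collects, after burn-in,
#' pooled size snapshots every `thin` iterations, a per-iteration trajectory
#' table, and (optionally) consecutive-size pairs for urns that persisted
#' through an iteration (used for fluctuation-scaling and growth-rate
#' analysis).
#'
#' @param config An [urn_config()].
#' @param collect_pairs Collect `(n_before, n_after)` pairs for persisting
#'   urns at every recorded iteration (default `TRUE`).
#' @return An object of class `urn_run` with elements `config`, `state`
#'   (final `urn_state`), `trajectory` (tibble with columns `t`, `N`, `q`,
#'   `delta_shrink`, `balls_removed_by_shrink`, `balls_removed_by_exit`,
#'   `n_replaced`, `n_exited`), `sizes` (integer vector of pooled snapshot
#'   sizes) and `pairs` (tibble with `t`, `n_before`, `n_after`).
#' @examples
#' run <- simulate_urns(urn_config(M = 500, E = 10, iterations = 50,
#'                                 burn_in = 50, seed = 1))
#' measure_turnover(run)
#' @export
simulate_urns <- function(config, collect_pairs = TRUE) {
  stopifnot(inherits(config, "urn_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- new_urn_state(rep(max(1L, as.integer(round(config$N0 / config$M))),
                             config$M),
                         t = 0L, q = config$q0)
  n_rec <- config$iterations
  traj <- list(t = integer(n_rec), N = integer(n_rec), q = numeric(n_rec),
               delta_shrink = numeric(n_rec),
               balls_removed_by_shrink = integer(n_rec),
               balls_removed_by_exit = integer(n_rec),
               n_replaced = integer(n_rec), n_exited = integer(n_rec))
  snapshots <- list()
  pair_chunks <- list()
  for (k in seq_len(config$burn_in)) {
    state <- iterate_urns(state, config)$state
  }
  for (k in seq_len(n_rec)) {
    n_before <- state$sizes
    step <- iterate_urns(state, config)
    state <- step$state
    out <- step$outcome
    traj$t[k] <- state$t
    traj$N[k] <- state$N
    traj$q[k] <- state$q
    traj$delta_shrink[k] <- out$delta_shrink
    traj$balls_removed_by_shrink[k] <- out$balls_removed_by_shrink
    traj$balls_removed_by_exit[k] <- out$balls_removed_by_exit
    traj$n_replaced[k] <- out$n_replaced
    traj$n_exited[k] <- length(out$exited_ids)
    if (k %% config$thin == 0 || config$thin == 1L) {
      snapshots[[length(snapshots) + 1L]] <- state$sizes
    }
    if (collect_pairs) {
      keep <- out$persisting
      # expected one-iteration growth factor of a surviving urn, from the
      # iteration's realized (q_t, delta_shrink_t); used to centre size
      # changes when estimating the fluctuation-scaling exponent
      f_t <- (1 + out$q_used) * (1 - out$delta_shrink)
      pair_chunks[[k]] <- cbind(t = rep.int(state$t, sum(keep)),
                                n_before = n_before[keep],
                                n_after = state$sizes[keep],
                                expected_factor = rep.int(f_t, sum(keep)))
    }
  }
  pairs <- if (collect_pairs && length(pair_chunks)) {
    m <- do.call(rbind, pair_chunks)
    tibble(t = as.integer(m[, "t"]), n_before = as.integer(m[, "n_before"]),
           n_after = as.integer(m[, "n_after"]),
           expected_factor = m[, "expected_factor"])
  } else {
    tibble(t = integer(), n_before = integer(), n_after = integer(),
           expected_factor = numeric())
  }
  structure(
    list(config = config, state = state, trajectory = as_tibble(traj),
         sizes = if (length(snapshots)) unlist(snapshots) else state$sizes,
         pairs = pairs),
    class = "urn_run")
}

#' @export
print.urn_run <- function(x, ...) {
  cat("<urn_run>", x$config$mode,
      sprintf("M = %d, %d recorded iterations\n",
              x$config$M, nrow(x$trajectory)),
      sprintf("  pooled sizes: %d snapshots (%d values), mean %.3f\n",
              length(x$sizes) %/% x$config$M, length(x$sizes),
              mean(x$sizes)))
  invisible(x)
}

#' Turnover summary of a run
#'
#' The turnover rate `mu` is the fraction of removed balls (network: removed
#' edge-ends) attributable to urn (node) exit, out of all removals in one
#' iteration, averaged over recorded iterations.  `mu = 0` for a pure
#' shrinking process and `mu = 1` when exit is the only removal mechanism;
#' the network analogue is bounded by 0.5 because every edge lost to an
#' exiting node is also lost by a surviving neighbour.
#'
#' @param run An `urn_run` or `network_run`.
#' @return A one-row tibble with `mu`, `delta_exit_balls` (mean fraction of
#'   balls/edge-ends removed by exit per iteration), `mean_size` and
#'   `median_size` of the pooled sizes/degrees.
#' @export
measure_turnover <- function(run) {
  UseMethod("measure_turnover")
}

#' @export
measure_turnover.urn_run <- function(run) {
  tr <- run$trajectory
  if (nrow(tr) == 0) stop_domain("no recorded iterations")
  removed <- tr$balls_removed_by_exit + tr$balls_removed_by_shrink
  ok <- removed > 0
  if (!any(ok)) stop_domain("turnover undefined: no removals in the window")
  tibble(
    mu = mean(tr$balls_removed_by_exit[ok] / removed[ok]),
    delta_exit_balls = mean(tr$balls_removed_by_exit / tr$N),
    delta_exit_balls_median = median(tr$balls_removed_by_exit / tr$N),
    mean_size = mean(run$sizes),
    median_size = median(run$sizes))
}
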