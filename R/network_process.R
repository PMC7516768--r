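#' Configure the stable-size network process
#'
#' Network analogue of the urn process: `M` nodes and `N` undirected,
#' unweighted edges.  Per iteration, a number of rewiring moves (a random
#' edge is broken; a receiver `i` and a new neighbour `j` are each chosen
#' with probability proportional to degree) is followed by node exit
#' (random at rate `delta_exit`, or deterministically at a fixed `lifespan`)
#' and node re-entry with one preferential edge, after which edges are
#' topped up preferentially so `N` is conserved.
#'
#' @param M Number of nodes.
#' @param N Number of edges; default mean degree 6 (`N = 3 * M`).
#' @param delta_exit Per-iteration node exit probability (`exit_rule =
#'   "rate"`).
#' @param exit_rule `"rate"` or `"lifespan"`.
#' @param lifespan Iterations a node survives under the lifespan rule.
#' @param rewires_per_iteration Rewiring moves per iteration (default
#'   `N / 10`, so rewiring and turnover act on comparable timescales).
#' @param iterations Recorded iterations after burn-in.
#' @param burn_in Iterations discarded before recording.
#' @param thin Interval between pooled degree snapshots.
#' @param seed Integer seed.
#' @return An object of class `network_config`.
#' @export
network_config <- function(M, N = 3 * M, delta_exit = 0.05,
                           exit_rule = c("rate", "lifespan"),
                           lifespan = NULL,
                           rewires_per_iteration = ceiling(N / 10),
                           iterations = 200, burn_in = 100, thin = 10,
                           seed = NULL) {
  exit_rule <- match.arg(exit_rule)
  M <- as.integer(M); N <- as.integer(N)
  stopifnot(M >= 4, N >= M / 2, N <= M * (M - 1) / 2,
            delta_exit >= 0, delta_exit <= 1,
            rewires_per_iteration >= 1, iterations >= 0, burn_in >= 0,
            thin >= 1)
  if (exit_rule == "lifespan") {
    stopifnot(!is.null(lifespan), lifespan >= 1)
    lifespan <- as.integer(lifespan)
  }
  structure(
    list(M = M, N = N, delta_exit = delta_exit, exit_rule = exit_rule,
         lifespan = lifespan,
         rewires_per_iteration = as.integer(rewires_per_iteration),
         iterations = as.integer(iterations), burn_in = as.integer(burn_in),
         thin = as.integer(thin), seed = seed),
    class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat("<network_config>",
      sprintf("M = %d, N = %d, exit_rule = %s, delta_exit = %.4g\n",
              x$M, x$N, x$exit_rule, x$delta_exit),
      sprintf("  %d rewires/iteration, %d + %d iterations\n",
              x$rewires_per_iteration, x$burn_in, x$iterations))
  invisible(x)
}

# pick one node with probability proportional to `weights`
preferential_pick <- function(weights) {
  sample.int(length(weights), 1L, prob = weights)
}

#' Simulate the stable-size network process
#'
#' Runs the rewiring / exit / entry dynamics from an Erdos-Renyi (G(n, m))
#' start and collects post-burn-in degree snapshots and per-iteration
#' turnover.  The graph stays simple (no self-loops or multi-edges), node
#' count is exactly `M` and edge count exactly `N` after every iteration.
#'
#' Turnover accounting: each broken edge costs two edge-ends; for an
#' exiting node of degree `k`, `k` of the `2k` lost ends are its own, so
#' exit can account for at most half of all losses -- `mu <= 0.5` by
#' construction, which is why the network variant always keeps an
#' exponential cutoff.
#'
#' @param config A [network_config()].
#' @return An object of class `network_run` with `config`, `edges` (tibble
#'   `from`, `to`), `degrees`, `ages`, `degree_samples` (pooled snapshot
#'   degrees), and `turnover` (per-iteration tibble with `t`, `mu`,
#'   `deg_exit_own`, `ends_lost`, `n_exited`, `infeasible_rewires`).
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  M <- config$M; N <- config$N
  R <- config$rewires_per_iteration
  g0 <- igraph::sample_gnm(M, N)
  E <- igraph::as_edgelist(g0, names = FALSE)
  storage.mode(E) <- "integer"
  A <- matrix(FALSE, M, M)
  A[E] <- TRUE; A[E[, 2:1, drop = FALSE]] <- TRUE
  deg <- tabulate(c(E), nbins = M)
  ages <- if (config$exit_rule == "lifespan") {
    sample.int(config$lifespan, M, replace = TRUE) - 1L
  } else integer(M)
  n_rec <- config$iterations
  rec <- list(t = integer(n_rec), mu = numeric(n_rec),
              deg_exit_own = integer(n_rec), ends_lost = integer(n_rec),
              n_exited = integer(n_rec), infeasible = integer(n_rec))
  snapshots <- list()

  one_iteration <- function() {
    infeasible <- 0L
    for (r in seq_len(R)) {
      repeat {
        e <- sample.int(nrow(E), 1L)
        a <- E[e, 1L]; b <- E[e, 2L]
        A[a, b] <<- FALSE; A[b, a] <<- FALSE
        deg[a] <<- deg[a] - 1L; deg[b] <<- deg[b] - 1L
        i <- preferential_pick(deg)
        w <- deg
        w[i] <- 0L
        w[A[, i]] <- 0L
        if (sum(w) > 0) {
          j <- preferential_pick(w)
          E[e, ] <<- c(i, j)
          A[i, j] <<- TRUE; A[j, i] <<- TRUE
          deg[i] <<- deg[i] + 1L; deg[j] <<- deg[j] + 1L
          break
        }
        # receiver has no feasible partner: restore and resample the edge
        A[a, b] <<- TRUE; A[b, a] <<- TRUE
        deg[a] <<- deg[a] + 1L; deg[b] <<- deg[b] + 1L
        infeasible <- infeasible + 1L
      }
    }
    ex <- if (config$exit_rule == "rate") {
      which(runif(M) < config$delta_exit)
    } else {
      which(ages >= config$lifespan - 1L)
    }
    deg_exit_own <- sum(deg[ex])
    broken <- 0L
    if (length(ex)) {
      inex <- logical(M); inex[ex] <- TRUE
      drop <- inex[E[, 1L]] | inex[E[, 2L]]
      broken <- sum(drop)
      if (broken) {
        dropped <- E[drop, , drop = FALSE]
        A[dropped] <<- FALSE
        A[dropped[, 2:1, drop = FALSE]] <<- FALSE
        deg <<- deg - tabulate(c(dropped), nbins = M)
        E <<- E[!drop, , drop = FALSE]
      }
    }
    ages <<- ages + 1L
    ages[ex] <<- 0L
    # re-entry: exited nodes and survivors stranded at degree 0 each get
    # one preferential edge
    need_link <- unique(c(ex, which(deg == 0L)))
    for (v in need_link) {
      w <- deg
      w[v] <- 0L
      w[A[, v]] <- 0L
      u <- if (sum(w) > 0) preferential_pick(w) else {
        cand <- setdiff(seq_len(M), c(v, which(A[, v])))
        cand[sample.int(length(cand), 1L)]
      }
      E <<- rbind(E, c(v, u))
      A[v, u] <<- TRUE; A[u, v] <<- TRUE
      deg[v] <<- deg[v] + 1L; deg[u] <<- deg[u] + 1L
    }
    # top up preferentially to conserve N
    guard <- 0L
    while (nrow(E) < N) {
      i <- preferential_pick(deg)
      w <- deg
      w[i] <- 0L
      w[A[, i]] <- 0L
      if (sum(w) == 0) {
        guard <- guard + 1L
        if (guard > 100L) stop_domain("cannot restore N: graph saturated")
        next
      }
      j <- preferential_pick(w)
      E <<- rbind(E, c(i, j))
      A[i, j] <<- TRUE; A[j, i] <<- TRUE
      deg[i] <<- deg[i] + 1L; deg[j] <<- deg[j] + 1L
    }
    while (nrow(E) > N) {
      ok <- deg[E[, 1L]] > 1L & deg[E[, 2L]] > 1L
      e <- which(ok)[sample.int(sum(ok), 1L)]
      a <- E[e, 1L]; b <- E[e, 2L]
      A[a, b] <<- FALSE; A[b, a] <<- FALSE
      deg[a] <<- deg[a] - 1L; deg[b] <<- deg[b] - 1L
      E <<- E[-e, , drop = FALSE]
    }
    ends_lost <- 2L * R + 2L * broken
    list(deg_exit_own = deg_exit_own, ends_lost = ends_lost,
         n_exited = length(ex), infeasible = infeasible)
  }

  for (k in seq_len(config$burn_in)) one_iteration()
  for (k in seq_len(n_rec)) {
    out <- one_iteration()
    rec$t[k] <- config$burn_in + k
    rec$mu[k] <- if (out$ends_lost > 0) {
      out$deg_exit_own / out$ends_lost
    } else NA_real_
    rec$deg_exit_own[k] <- out$deg_exit_own
    rec$ends_lost[k] <- out$ends_lost
    rec$n_exited[k] <- out$n_exited
    rec$infeasible[k] <- out$infeasible
    if (k %% config$thin == 0) {
      snapshots[[length(snapshots) + 1L]] <- deg
    }
  }
  structure(
    list(config = config,
         edges = tibble(from = E[, 1L], to = E[, 2L]),
         degrees = deg, ages = ages,
         degree_samples = if (length(snapshots)) unlist(snapshots) else deg,
         turnover = as_tibble(rec)),
    class = "network_run")
}

#' @export
print.network_run <- function(x, ...) {
  cat("<network_run>",
      sprintf("M = %d, N = %d; mean degree %.2f; mean mu = %.3f\n",
              x$config$M, x$config$N, mean(x$degrees),
              mean(x$turnover$mu, na.rm = TRUE)))
  invisible(x)
}

#' @export
measure_turnover.network_run <- function(run) {
  tr <- run$turnover
  ok <- !is.na(tr$mu)
  if (!any(ok)) stop_domain("turnover undefined: no recorded losses")
  tibble(mu = mean(tr$mu[ok]),
         delta_exit_balls = mean(tr$deg_exit_own / (2 * run$config$N)),
         delta_exit_balls_median =
           median(tr$deg_exit_own / (2 * run$config$N)),
         mean_size = mean(run$degree_samples),
         median_size = median(run$degree_samples))
}

#' Convert a network run to an igraph object
#'
#' @param run A `network_run`.
#' @return An `igraph` graph on `M` vertices.
#' @export
as_igraph <- function(run) {
  stopifnot(inherits(run, "network_run"))
  igraph::graph_from_edgelist(as.matrix(run$edges[, c("from", "to")]),
                              directed = FALSE) |>
    igraph::add_vertices(max(0, run$config$M - max(run$edges$from,
                                                   run$edges$to)))
}

#' Write a network run to disk
#'
#' @param run A `network_run`.
#' @param path Output path.
#' @param format `"edgelist"` (two whitespace-separated node ids per line)
#'   or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(run, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    utils::write.table(run$edges, path, row.names = FALSE,
                       col.names = FALSE, sep = " ")
  } else {
    igraph::write_graph(as_igraph(run), path, format = "graphml")
  }
  invisible(path)
}
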