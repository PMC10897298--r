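#' Search configuration for disassembly-augmented greedy modularity
#'
#' @param node_strategy node-disassembly criterion; one of `"random"`,
#'   `"weak"`, `"low_embeddedness"`, `"non_triad"`.
#' @param community_strategy community-disassembly criterion; one of
#'   `"random"`, `"weak"`, `"low_density"`, `"low_tpr"`,
#'   `"high_conductance"`.
#' @param p_node probability per iteration of a node-disassembly move.
#' @param p_comm probability per iteration of a community-disassembly move.
#' @param iter_multiplier iteration budget multiplier `p`: the search runs
#'   `round(p * n)` iterations (the plain greedy baseline needs at most
#'   `n - 1`).
#' @param seed integer seed; restart `r` uses `seed + r - 1`.
#' @param n_restarts number of independent restarts; the best partition
#'   over all restarts is returned.
#' @param exploit_to_convergence if `TRUE`, an exploitation iteration
#'   applies greedy merges to convergence instead of a single merge.
#' @return a list of class `dgm_config`.
#' @export
dgm_config <- function(node_strategy = "random",
                       community_strategy = "weak",
                       p_node = 0.05,
                       p_comm = 0.05,
                       iter_multiplier = 30,
                       seed = 1L,
                       n_restarts = 1L,
                       exploit_to_convergence = FALSE) {
  node_strategy <- match.arg(node_strategy, NODE_STRATEGIES)
  community_strategy <- match.arg(community_strategy, COMMUNITY_STRATEGIES)
  if (!is.numeric(p_node) || !is.numeric(p_comm) ||
      p_node < 0 || p_comm < 0 || p_node + p_comm > 1) {
    stop("need p_node >= 0, p_comm >= 0 and p_node + p_comm <= 1", call. = FALSE)
  }
  if (!is.numeric(iter_multiplier) || iter_multiplier <= 0) {
    stop("iter_multiplier must be positive", call. = FALSE)
  }
  if (!is.numeric(n_restarts) || n_restarts < 1) {
    stop("n_restarts must be a positive integer", call. = FALSE)
  }
  structure(
    list(node_strategy = node_strategy,
         community_strategy = community_strategy,
         p_node = p_node, p_comm = p_comm,
         iter_multiplier = iter_multiplier,
         seed = as.integer(seed),
         n_restarts = as.integer(n_restarts),
         exploit_to_convergence = isTRUE(exploit_to_convergence)),
    class = "dgm_config"
  )
}

# One disassembly kick at node scale, using the configured strategy and
# falling back to a random node when the strategy has no candidate.
node_kick <- function(state, strategy) {
  sel <- select_node(state, strategy)
  if (is.null(sel) && strategy != "random") sel <- select_node(state, "random")
  if (is.null(sel)) return(FALSE)
  disassemble_node(state, sel$community, sel$node)
  TRUE
}

comm_kick <- function(state, strategy) {
  cid <- select_community(state, strategy)
  if (is.null(cid) && strategy != "random") cid <- select_community(state, "random")
  if (is.null(cid)) return(FALSE)
  disassemble_community(state, cid)
  TRUE
}

#' Disassembly-augmented greedy modularity search
#'
#' Starting from singleton communities, runs `round(iter_multiplier * n)`
#' iterations per restart. Each iteration draws a uniform number `u`:
#' `u < p_comm` triggers a community-disassembly move under the configured
#' community strategy, `u < p_comm + p_node` a node-disassembly move under
#' the configured node strategy, and otherwise the best strictly positive
#' greedy merge is applied. Exploration draws before the first local
#' optimum is reached are no-ops, so the plain greedy trajectory is a
#' prefix of every run and the best result can never fall below the greedy
#' baseline. When exploitation is drawn at a local optimum
#' (no positive merge), an escape move perturbs the partition: two
#' node-disassembly moves, or - on every fourth consecutive escape without
#' an improvement of the best modularity - one community disassembly plus a
#' node move (see the methods vignette for the rationale of this two-scale
#' schedule). The best `(q, partition)` snapshot over all iterations and
#' restarts is returned; with `p_node = p_comm = 0` escapes are disabled
#' and the result is identical to [run_greedy()].
#'
#' @param g a [dgm_graph] with at least one edge.
#' @param config a [dgm_config].
#' @return a list of class `dgm_result`: `best_partition`, `best_q`,
#'   `n_communities`, `trajectory` (data frame with columns `restart`,
#'   `iteration`, `action`, `q`), `config`, `seed`.
#' @examples
#' karate <- load_fixture("karate")
#' res <- run_dgm(karate$graph, dgm_config(seed = 1, n_restarts = 2))
#' round(res$best_q, 4)
#' @export
run_dgm <- function(g, config = dgm_config()) {
  stopifnot(inherits(g, "dgm_graph"))
  if (!inherits(config, "dgm_config")) stop("`config` must be a dgm_config", call. = FALSE)
  if (g$m < 1L) stop("cannot run on an empty graph (m = 0)", call. = FALSE)
  T_iter <- max(1L, as.integer(round(config$iter_multiplier * g$n)))
  explore_on <- (config$p_node + config$p_comm) > 0
  best_q <- -Inf
  best_memb <- NULL
  trajs <- vector("list", config$n_restarts)
  for (r in seq_len(config$n_restarts)) {
    set.seed(config$seed + r - 1L)
    st <- init_singletons(g)
    actions <- character(T_iter)
    qs <- numeric(T_iter)
    stall <- 0L
    converged <- FALSE   # exploration waits for the first local optimum,
                         # so the plain greedy trajectory is a prefix
    if (st$q > best_q) { best_q <- st$q; best_memb <- st$memb }
    for (t in seq_len(T_iter)) {
      u <- stats::runif(1)
      if (u < config$p_comm) {
        cid <- if (converged) select_community(st, config$community_strategy) else NULL
        if (!is.null(cid)) {
          disassemble_community(st, cid)
          actions[t] <- "explore_comm"
        } else actions[t] <- "noop"
      } else if (u < config$p_comm + config$p_node) {
        sel <- if (converged) select_node(st, config$node_strategy) else NULL
        if (!is.null(sel)) {
          disassemble_node(st, sel$community, sel$node)
          actions[t] <- "explore_node"
        } else actions[t] <- "noop"
      } else {
        bm <- best_merge(st, positive_only = TRUE)
        if (!is.null(bm)) {
          apply_merge(st, bm$i, bm$j)
          if (config$exploit_to_convergence) {
            repeat {
              if (st$q > best_q) { best_q <- st$q; best_memb <- st$memb; stall <- 0L }
              bm <- best_merge(st, positive_only = TRUE)
              if (is.null(bm)) break
              apply_merge(st, bm$i, bm$j)
            }
          }
          actions[t] <- "merge"
        } else if (explore_on) {
          converged <- TRUE
          if (stall %% 4L == 3L) {
            comm_kick(st, config$community_strategy)
            node_kick(st, config$node_strategy)
            actions[t] <- "escape_comm"
          } else {
            node_kick(st, config$node_strategy)
            node_kick(st, config$node_strategy)
            actions[t] <- "escape_node"
          }
          stall <- stall + 1L
        } else {
          actions[t] <- "noop"
        }
      }
      qs[t] <- st$q
      if (st$q > best_q) {
        best_q <- st$q
        best_memb <- st$memb
        stall <- 0L
      }
    }
    trajs[[r]] <- data.frame(restart = r, iteration = seq_len(T_iter),
                             action = actions, q = qs,
                             stringsAsFactors = FALSE)
  }
  labels <- as.character(match(best_memb, sort(unique(best_memb))))
  best_partition <- dgm_partition(stats::setNames(labels, g$nodes))
  structure(
    list(best_partition = best_partition,
         best_q = best_q,
         n_communities = n_communities(best_partition),
         trajectory = do.call(rbind, trajs),
         config = config,
         seed = config$seed),
    class = "dgm_result"
  )
}

#' @export
print.dgm_result <- function(x, ...) {
  cat(sprintf("<dgm_result> best Q = %.4f, %d communities (%s community / %s node, %d restart%s)\n",
              x$best_q, x$n_communities,
              x$config$community_strategy, x$config$node_strategy,
              x$config$n_restarts, if (x$config$n_restarts > 1) "s" else ""))
  invisible(x)
}

#' Per-iteration trajectory with running maximum
#'
#' Expands a search result's trajectory into a plotting-ready table: one
#' row per iteration with the action taken, the modularity after the
#' action, and the running maximum (non-decreasing; its final value equals
#' `best_q`).
#'
#' @param result a `dgm_result`.
#' @return a data frame with columns `restart`, `iteration`, `action`, `q`,
#'   `running_max`.
#' @export
trajectory_summary <- function(result) {
  stopifnot(inherits(result, "dgm_result"))
  tr <- result$trajectory
  if (is.null(tr) || !nrow(tr)) stop("empty trajectory", call. = FALSE)
  tr$running_max <- cummax(tr$q)
  tr
}
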