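#' Normalized mutual information between two partitions
#'
#' \deqn{NMI(U, V) = \frac{2 \sum_{ij} P_{UV}(i,j) \log \frac{P_{UV}(i,j)}
#' {P_U(i) P_V(j)}}{H(U) + H(V)}}
#' computed from the co-membership contingency table. The value lies in
#' `[0, 1]`, is symmetric and invariant to community relabelling; identical
#' partitions score 1 and independent labelings score 0. Degenerate cases
#' where both entropies vanish (both partitions are a single community) are
#' defined as 1 (the partitions are identical); one trivial partition
#' against a non-trivial one scores 0.
#'
#' @param u,v [dgm_partition]s covering the same node set.
#' @return a number in `[0, 1]`.
#' @export
nmi <- function(u, v) {
  stopifnot(inherits(u, "dgm_partition"), inherits(v, "dgm_partition"))
  nodes <- names(u$membership)
  if (length(nodes) != length(v$membership) ||
      !setequal(nodes, names(v$membership))) {
    stop("partitions must cover the same node set", call. = FALSE)
  }
  a <- factor(u$membership[nodes])
  b <- factor(v$membership[nodes])
  tab <- table(a, b)
  n <- length(nodes)
  pij <- tab / n
  pu <- rowSums(pij)
  pv <- colSums(pij)
  hu <- -sum(ifelse(pu > 0, pu * log(pu), 0))
  hv <- -sum(ifelse(pv > 0, pv * log(pv), 0))
  if (hu == 0 && hv == 0) return(1)
  if (hu == 0 || hv == 0) return(0)
  outer_p <- outer(pu, pv)
  pos <- pij > 0
  mi <- sum(pij[pos] * log(pij[pos] / outer_p[pos]))
  val <- 2 * mi / (hu + hv)
  min(max(val, 0), 1)
}

#' Run the full strategy grid
#'
#' Runs the disassembly-augmented search for all 20 combinations of the
#' five community strategies and four node strategies with a shared budget
#' and seed policy, as in a strategy-comparison experiment on a benchmark
#' network.
#'
#' @param g a [dgm_graph].
#' @param base_config a [dgm_config]; its strategies are overridden cell by
#'   cell while probabilities, budget, seed and restarts are shared.
#' @return a data frame with columns `community_strategy`, `node_strategy`,
#'   `best_q`, `n_communities` (20 rows).
#' @export
strategy_grid <- function(g, base_config = dgm_config()) {
  rows <- list()
  for (cs in COMMUNITY_STRATEGIES) {
    for (ns in NODE_STRATEGIES) {
      cfg <- base_config
      cfg$community_strategy <- cs
      cfg$node_strategy <- ns
      res <- run_dgm(g, cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        community_strategy = cs, node_strategy = ns,
        best_q = res$best_q, n_communities = res$n_communities,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Compare a detected partition to a reference partition
#'
#' @param g a [dgm_graph].
#' @param p a detected [dgm_partition].
#' @param ref a reference (ground-truth) [dgm_partition] on the same nodes.
#' @return a list with the modularity, community count and mean internal
#'   density of both partitions, and their normalized mutual information.
#' @export
compare_to_reference <- function(g, p, ref) {
  stopifnot(inherits(p, "dgm_partition"), inherits(ref, "dgm_partition"))
  if (!setequal(names(p$membership), names(ref$membership))) {
    stop("partitions must cover the same node set", call. = FALSE)
  }
  list(
    q = modularity_q(g, p),
    q_reference = modularity_q(g, ref),
    n_communities = n_communities(p),
    n_communities_reference = n_communities(ref),
    nmi = nmi(p, ref),
    mean_internal_density = mean_internal_density(g, p),
    mean_internal_density_reference = mean_internal_density(g, ref)
  )
}
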