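#' Newman modularity of a partition
#'
#' Computes \eqn{Q(S) = \sum_{c \in S} [ l_c/L - (k_c/(2L))^2 ]}, where
#' \eqn{l_c} is the number of edges inside community \eqn{c}, \eqn{k_c} the
#' sum of degrees of its members and \eqn{L} the number of edges in the
#' graph. \eqn{Q} lies in \eqn{[-1/2, 1)}; the all-in-one partition scores
#' exactly 0.
#'
#' @param g a [dgm_graph] with at least one edge.
#' @param p a [dgm_partition] of the nodes of `g`.
#' @return the modularity, a single number.
#' @export
modularity_q <- function(g, p) {
  if (g$m < 1L) stop("modularity is undefined on an empty graph (m = 0)", call. = FALSE)
  memb <- partition_index(g, p)
  L <- g$m
  same <- memb[g$edges[, 1L]] == memb[g$edges[, 2L]]
  k <- max(memb)
  lc <- tabulate(memb[g$edges[same, 1L]], nbins = k)
  kc <- as.numeric(rowsum(as.numeric(g$deg), memb)[, 1L])
  sum(lc / L) - sum((kc / (2 * L))^2)
}

#' Per-community edge statistics
#'
#' For every community: member count `n_s`, internal edge count `l_c`,
#' degree sum `k_c` and boundary edge count `m_out` (edges with exactly one
#' endpoint inside). These satisfy `k_c = 2 * l_c + m_out`.
#'
#' @param g a [dgm_graph].
#' @param p a [dgm_partition] of the nodes of `g`.
#' @return a data frame with one row per community, columns `community`,
#'   `n_s`, `l_c`, `k_c`, `m_out`.
#' @export
community_stats <- function(g, p) {
  memb <- partition_index(g, p)
  labels <- unique(p$membership[g$nodes])
  k <- max(memb)
  same <- memb[g$edges[, 1L]] == memb[g$edges[, 2L]]
  lc <- tabulate(memb[g$edges[same, 1L]], nbins = k)
  kc <- as.numeric(rowsum(as.numeric(g$deg), memb)[, 1L])
  ns <- tabulate(memb, nbins = k)
  data.frame(community = labels, n_s = ns, l_c = lc, k_c = kc,
             m_out = kc - 2 * lc, stringsAsFactors = FALSE)
}

#' Internal/external degree split of a node
#'
#' Counts how many of `v`'s neighbours lie inside versus outside `v`'s own
#' community.
#'
#' @param g a [dgm_graph].
#' @param p a [dgm_partition] of the nodes of `g`.
#' @param v a node label.
#' @return a list with `k_int`, `k_ext` and `k_v` (`k_int + k_ext`).
#' @export
degree_split <- function(g, p, v) {
  i <- node_index(g, v)
  memb <- partition_index(g, p)
  nb <- g$adj[[i]]
  k_int <- sum(memb[nb] == memb[i])
  list(k_int = k_int, k_ext = length(nb) - k_int, k_v = length(nb))
}

#' Embeddedness of a node in its community
#'
#' The fraction of a node's neighbours that share its community,
#' \eqn{f(v, C) = k_v^C / k_v \in [0, 1]}. Low embeddedness marks nodes
#' loosely attached to their community.
#'
#' @inheritParams degree_split
#' @return a number in `[0, 1]`.
#' @export
embeddedness <- function(g, p, v) {
  s <- degree_split(g, p, v)
  if (s$k_v == 0L) stop("embeddedness is undefined for an isolated node", call. = FALSE)
  s$k_int / s$k_v
}

#' Is a node weak?
#'
#' A node is weak when its internal degree does not exceed its external
#' degree (`k_int <= k_ext`); weak nodes weaken their community.
#'
#' @param split a degree split as returned by [degree_split()].
#' @return `TRUE` or `FALSE`.
#' @export
is_weak_node <- function(split) {
  split$k_int <= split$k_ext
}

#' Nodes participating in a triangle of an induced subgraph
#'
#' A triad is a set of three mutually connected nodes. Both co-members and
#' the connecting edges must lie inside the induced subgraph on `members`.
#'
#' @param g a [dgm_graph].
#' @param members node labels.
#' @return the subset of `members` (sorted) that belong to at least one
#'   triangle of the induced subgraph.
#' @export
triad_nodes <- function(g, members) {
  idx <- node_index(g, members)
  marked <- triad_mark(g$adj, idx)
  sort(g$nodes[marked])
}

# Integer-index triangle marking on the subgraph induced by `idx`.
triad_mark <- function(adj, idx) {
  n <- length(adj)
  inset <- logical(n)
  inset[idx] <- TRUE
  mark <- logical(n)
  for (u in idx) {
    nb <- adj[[u]]
    nb <- nb[inset[nb] & nb > u]
    if (length(nb) < 1L) next
    innb <- logical(n)
    all_u <- adj[[u]]
    all_u <- all_u[inset[all_u]]
    innb[all_u] <- TRUE
    for (v in nb) {
      w <- adj[[v]]
      w <- w[inset[w] & innb[w]]
      if (length(w)) {
        mark[u] <- TRUE
        mark[v] <- TRUE
        mark[w] <- TRUE
      }
    }
  }
  which(mark)
}

#' Internal edge density of a community
#'
#' The number of internal edges over the maximum possible,
#' \eqn{m_s / (n_s (n_s - 1) / 2)}. Undefined for singleton communities.
#'
#' @param stats a single-row data frame or list with fields `n_s` and `l_c`
#'   (see [community_stats()]).
#' @return a number in `[0, 1]`.
#' @export
internal_edge_density <- function(stats) {
  if (stats$n_s < 2) {
    stop("internal edge density is undefined for communities of size < 2",
         call. = FALSE)
  }
  stats$l_c / (stats$n_s * (stats$n_s - 1) / 2)
}

#' Triad participation ratio of a community
#'
#' The fraction of a community's nodes that belong to at least one internal
#' triangle. Low values mark loosely knit communities.
#'
#' @param g a [dgm_graph].
#' @param members non-empty vector of node labels.
#' @return a number in `[0, 1]`.
#' @export
triad_participation_ratio <- function(g, members) {
  if (!length(members)) stop("empty member set", call. = FALSE)
  length(triad_nodes(g, members)) / length(members)
}

#' Conductance of a community
#'
#' \eqn{m_{out} / (2 m_c + m_{out})}: boundary edges over all edge
#' endpoints touching the community. High conductance marks a poorly
#' separated community. Undefined when the community touches no edge.
#'
#' @param stats a single-row data frame or list with fields `l_c` and
#'   `m_out` (see [community_stats()]).
#' @return a number in `[0, 1]`.
#' @export
conductance <- function(stats) {
  den <- 2 * stats$l_c + stats$m_out
  if (den <= 0) {
    stop("conductance is undefined for a community touching no edge", call. = FALSE)
  }
  stats$m_out / den
}

#' Internal-minus-external edge balance of a community
#'
#' Returns `l_c - m_out`. The community with the smallest balance is the
#' "weak" community targeted by the weak-community disassembly strategy.
#'
#' @param stats a single-row data frame or list with fields `l_c` and `m_out`.
#' @return an integer (possibly negative).
#' @export
community_edge_balance <- function(stats) {
  stats$l_c - stats$m_out
}

#' Mean internal edge density of a partition
#'
#' Unweighted arithmetic mean of [internal_edge_density()] over all
#' communities with at least two members; singleton communities, for which
#' the density is undefined, are skipped.
#'
#' @param g a [dgm_graph].
#' @param p a [dgm_partition] of the nodes of `g`.
#' @return a number in `[0, 1]`.
#' @export
mean_internal_density <- function(g, p) {
  st <- community_stats(g, p)
  st <- st[st$n_s >= 2L, , drop = FALSE]
  if (!nrow(st)) {
    stop("mean internal density is undefined: all communities are singletons",
         call. = FALSE)
  }
  mean(st$l_c / (st$n_s * (st$n_s - 1) / 2))
}

#' Full per-community quality table
#'
#' Combines [community_stats()] with density, triad participation ratio,
#' conductance and edge balance; the table behind the `metrics` command of
#' the command-line interface.
#'
#' @param g a [dgm_graph].
#' @param p a [dgm_partition] of the nodes of `g`.
#' @return a data frame with columns `community`, `n_s`, `l_c`, `m_out`,
#'   `density`, `tpr`, `conductance`, `balance`. Density and conductance are
#'   `NA` where undefined.
#' @export
community_metrics <- function(g, p) {
  st <- community_stats(g, p)
  comms <- partition_communities(p)
  dens <- ifelse(st$n_s >= 2, st$l_c / (st$n_s * (st$n_s - 1) / 2), NA_real_)
  tpr <- vapply(st$community, function(cc) {
    triad_participation_ratio(g, comms[[cc]])
  }, numeric(1))
  cond <- ifelse(2 * st$l_c + st$m_out > 0, st$m_out / (2 * st$l_c + st$m_out),
                 NA_real_)
  data.frame(community = st$community, n_s = st$n_s, l_c = st$l_c,
             m_out = st$m_out, density = dens, tpr = tpr, conductance = cond,
             balance = st$l_c - st$m_out, stringsAsFactors = FALSE)
}
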