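# Small graph builders and independent oracles used across the suite.

edges_chr <- function(...) {
  m <- matrix(as.character(unlist(list(...))), ncol = 2, byrow = TRUE)
  m
}

# triangle 1-2-3
k3 <- function() dgm_graph(edges_chr(1, 2, 2, 3, 3, 1))

# two triangles {1,2,3} and {4,5,6} joined by the bridge 3-4
joined_triangles <- function() {
  dgm_graph(edges_chr(1, 2, 2, 3, 3, 1, 4, 5, 5, 6, 6, 4, 3, 4))
}

path3 <- function() dgm_graph(edges_chr(1, 2, 2, 3))

# star with centre "c" and leaves l1..l3
star4 <- function() dgm_graph(edges_chr("c", "l1", "c", "l2", "c", "l3"))

single_edge <- function() dgm_graph(edges_chr("a", "b"))

partition_of <- function(g, groups) {
  memb <- character(0)
  for (k in seq_along(groups)) {
    memb[as.character(groups[[k]])] <- as.character(k)
  }
  dgm_partition(memb[g$nodes])
}

# random connected simple graph on n nodes (labels "1".."n")
random_connected_graph <- function(n, p) {
  repeat {
    em <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(em)) < p
    if (sum(keep) < n - 1) next
    g <- dgm_graph(apply(em[keep, , drop = FALSE], 2, as.character),
                   nodes = as.character(seq_len(n)))
    if (length(induced_components(g, g$nodes)) == 1L) return(g)
  }
}

# random partition of a graph's nodes into at most kmax groups
random_partition <- function(g, kmax = 4L) {
  memb <- sample.int(kmax, g$n, replace = TRUE)
  dgm_partition(stats::setNames(as.character(memb), g$nodes))
}

# --- independent oracles -------------------------------------------------

as_igraph <- function(g) {
  igraph::graph_from_edgelist(
    cbind(g$nodes[g$edges[, 1L]], g$nodes[g$edges[, 2L]]), directed = FALSE)
}

igraph_modularity <- function(g, p) {
  ig <- as_igraph(g)
  memb <- p$membership[igraph::V(ig)$name]
  igraph::modularity(ig, as.integer(factor(memb)))
}

# all set partitions of n elements as restricted growth strings
all_rgs <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in 1:(maxv + 1L)) rec(c(prefix, v), max(maxv, v))
  }
  rec(1L, 1L)
  out
}

# exhaustive maximum modularity by set-partition enumeration (n <= 8)
brute_max_modularity <- function(g) {
  stopifnot(g$n <= 8L)
  L <- g$m
  e1 <- g$edges[, 1L]
  e2 <- g$edges[, 2L]
  deg <- as.numeric(g$deg)
  best <- -Inf
  for (memb in all_rgs(g$n)) {
    same <- memb[e1] == memb[e2]
    lc <- tabulate(memb[e1][same], nbins = max(memb))
    kc <- rowsum(deg, memb)[, 1L]
    q <- sum(lc / L) - sum((kc / (2 * L))^2)
    if (q > best) best <- q
  }
  best
}

# from-scratch modularity of an agglomeration state via the public metric
state_scratch_q <- function(state) {
  modularity_q(state$g, state_partition(state))
}
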