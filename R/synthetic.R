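#' Configuration for the planted-partition benchmark generator
#'
#' The generator emulates LFR-style benchmarks: community sizes and node
#' degrees follow truncated power laws and a mixing parameter `mu` fixes
#' the fraction of each node's edges that leave its community.
#'
#' @param n number of nodes (at least 10).
#' @param mu mixing parameter in `[0, 1]`: expected fraction of each node's
#'   edges leaving its community (`mu = 0`: all edges internal).
#' @param gamma degree-distribution exponent (> 1).
#' @param beta community-size exponent (> 1).
#' @param avg_degree target mean degree.
#' @param seed integer seed; identical configurations generate identical
#'   graphs.
#' @return a list of class `lfr_config`.
#' @export
lfr_config <- function(n = 250L, mu = 0.1, gamma = 3, beta = 1.5,
                       avg_degree = 10, seed = 1L) {
  if (!is.numeric(n) || n < 10) stop("need n >= 10", call. = FALSE)
  if (!is.numeric(mu) || mu < 0 || mu > 1) stop("need 0 <= mu <= 1", call. = FALSE)
  if (!is.numeric(gamma) || gamma <= 1) stop("need gamma > 1", call. = FALSE)
  if (!is.numeric(beta) || beta <= 1) stop("need beta > 1", call. = FALSE)
  if (!is.numeric(avg_degree) || avg_degree < 2) stop("need avg_degree >= 2", call. = FALSE)
  structure(list(n = as.integer(n), mu = mu, gamma = gamma, beta = beta,
                 avg_degree = avg_degree, seed = as.integer(seed)),
            class = "lfr_config")
}

# Discrete truncated power-law sample: P(x) proportional to x^(-expo) on lo:hi.
sample_power <- function(size, lo, hi, expo) {
  vals <- lo:hi
  probs <- vals^(-expo)
  vals[sample.int(length(vals), size, replace = TRUE, prob = probs)]
}

# smallest lower cutoff whose truncated power-law mean is closest to target
power_law_kmin <- function(kmax, gamma, target) {
  best <- 2L; bestgap <- Inf
  for (kmin in 2:max(2L, kmax - 1L)) {
    vals <- kmin:kmax
    m <- sum(vals^(1 - gamma)) / sum(vals^(-gamma))
    if (abs(m - target) < bestgap) { bestgap <- abs(m - target); best <- kmin }
  }
  best
}

# simple graph on `members` realizing (approximately) the internal degree
# sequence `dint`; returns a 2-column integer edge matrix in member indexing.
wire_internal <- function(members, dint) {
  size <- length(members)
  # parity and graphicality fixes: shave the largest entries
  repeat {
    if (sum(dint) %% 2 == 1) {
      w <- which.max(dint)
      dint[w] <- dint[w] - 1L
    }
    if (sum(dint) == 0) return(matrix(integer(0), 0, 2))
    if (igraph::is_graphical(dint)) break
    w <- which.max(dint)
    dint[w] <- dint[w] - 1L
  }
  ig <- igraph::sample_degseq(dint, method = "fast.heur.simple")
  el <- igraph::as_edgelist(ig, names = FALSE)
  cbind(members[el[, 1L]], members[el[, 2L]])
}

#' Generate a planted-partition benchmark graph
#'
#' Community sizes are drawn from a truncated power law with exponent
#' `beta`, node degrees from a truncated power law with exponent `gamma`
#' (lower cutoff tuned to the target mean degree, upper cutoff about
#' `n / 10`), and each node's edges are split internal/external according
#' to `mu`. Internal edges are wired per community through a
#' degree-sequence model; external edges pair stubs across communities with
#' rejection of self-loops, duplicate edges and same-community pairs
#' (bounded retries; unplaceable stubs are dropped). The empirical mixing
#' `realized_mu` (fraction of edges between communities) is reported and
#' stays within 0.05 of `mu` at benchmark sizes.
#'
#' @param config an [lfr_config].
#' @return a list with `graph` (a [dgm_graph]), `planted` (a
#'   [dgm_partition]), `realized_mu` and `config`.
#' @export
generate_planted <- function(config) {
  stopifnot(inherits(config, "lfr_config"))
  set.seed(config$seed)
  n <- config$n
  kmax <- max(3L, as.integer(round(n / 10)))
  kmin <- power_law_kmin(kmax, config$gamma, config$avg_degree)
  smin <- kmax + 2L
  smax <- max(smin + 5L, as.integer(round(2.5 * smin)))
  if (2L * smin > n) {
    stop(sprintf("infeasible configuration: need n >= %d for two communities",
                 2L * smin), call. = FALSE)
  }
  smax <- min(smax, n - smin)
  # community sizes: draw until they cover n, then repair the remainder
  sizes <- integer(0)
  while (sum(sizes) < n) sizes <- c(sizes, sample_power(1L, smin, smax, config$beta))
  excess <- sum(sizes) - n
  sizes[length(sizes)] <- sizes[length(sizes)] - excess
  while (sizes[length(sizes)] < smin) {
    # fold a too-small remainder into the other communities
    short <- smin - sizes[length(sizes)]
    give <- which(sizes[-length(sizes)] > smin)
    if (length(give) < 1L) break
    g1 <- give[1L]
    take <- min(short, sizes[g1] - smin)
    sizes[g1] <- sizes[g1] - take
    sizes[length(sizes)] <- sizes[length(sizes)] + take
    if (take == 0L) break
  }
  if (length(sizes) < 2L) stop("generation error: fewer than two communities", call. = FALSE)
  # assign nodes and degrees
  perm <- sample.int(n)
  comm_of <- integer(n)
  start <- 1L
  for (ci in seq_along(sizes)) {
    comm_of[perm[start:(start + sizes[ci] - 1L)]] <- ci
    start <- start + sizes[ci]
  }
  deg <- sample_power(n, kmin, kmax, config$gamma)
  dint <- as.integer(round((1 - config$mu) * deg))
  dint <- pmin(dint, sizes[comm_of] - 1L)
  dext <- deg - dint
  if (config$mu == 0) dext[] <- 0L
  # internal wiring
  edges <- matrix(integer(0), 0, 2)
  for (ci in seq_along(sizes)) {
    members <- which(comm_of == ci)
    edges <- rbind(edges, wire_internal(members, dint[members]))
  }
  n_int <- nrow(edges)
  # external stub pairing with rejection
  adj <- matrix(FALSE, n, n)
  if (n_int) {
    adj[edges] <- TRUE
    adj[edges[, c(2L, 1L)]] <- TRUE
  }
  stubs <- rep(seq_len(n), dext)
  if (length(stubs) %% 2 == 1) stubs <- stubs[-which.max(dext[stubs])[1L]]
  ext_edges <- matrix(integer(0), 0, 2)
  tries <- 0L
  while (length(stubs) >= 2L && tries < 100L) {
    tries <- tries + 1L
    stubs <- stubs[sample.int(length(stubs))]
    half <- length(stubs) %/% 2L
    a <- stubs[seq_len(half)]
    b <- stubs[half + seq_len(half)]
    leftover <- if (length(stubs) %% 2L == 1L) stubs[length(stubs)] else integer(0)
    keepback <- integer(0)
    for (e in seq_len(half)) {
      u <- a[e]; v <- b[e]
      if (u == v || comm_of[u] == comm_of[v] || adj[u, v]) {
        keepback <- c(keepback, u, v)
      } else {
        ext_edges <- rbind(ext_edges, c(min(u, v), max(u, v)))
        adj[u, v] <- TRUE; adj[v, u] <- TRUE
      }
    }
    stubs <- c(keepback, leftover)
  }
  all_edges <- rbind(edges, ext_edges)
  if (!nrow(all_edges)) stop("generation error: produced no edges", call. = FALSE)
  labels <- as.character(seq_len(n))
  g <- dgm_graph(cbind(labels[all_edges[, 1L]], labels[all_edges[, 2L]]),
                 nodes = labels)
  planted <- dgm_partition(stats::setNames(as.character(comm_of), labels),
                           provenance = "planted")
  realized_mu <- nrow(ext_edges) / nrow(all_edges)
  list(graph = g, planted = planted, realized_mu = realized_mu, config = config)
}

#' Ring of cliques
#'
#' `k` cliques of size `s`; consecutive cliques are joined by one bridge
#' edge, closing into a ring. A standard structured fixture whose optimal
#' clique-per-community partition is known analytically.
#'
#' @param k number of cliques (at least 3).
#' @param s clique size (at least 3).
#' @return same structure as [generate_planted()]: `graph`, `planted`
#'   (the cliques), `realized_mu`.
#' @export
ring_of_cliques <- function(k, s) {
  if (!is.numeric(k) || k < 3) stop("need k >= 3 cliques", call. = FALSE)
  if (!is.numeric(s) || s < 3) stop("need clique size s >= 3", call. = FALSE)
  k <- as.integer(k); s <- as.integer(s)
  n <- k * s
  edges <- list()
  for (ci in seq_len(k)) {
    members <- (ci - 1L) * s + seq_len(s)
    pairs <- utils::combn(members, 2L)
    edges[[ci]] <- t(pairs)
  }
  bridges <- cbind((seq_len(k) - 1L) * s + s,               # last node of clique i
                   (seq_len(k) %% k) * s + 1L)              # first node of clique i+1
  all_edges <- rbind(do.call(rbind, edges), bridges)
  labels <- as.character(seq_len(n))
  g <- dgm_graph(cbind(labels[all_edges[, 1L]], labels[all_edges[, 2L]]),
                 nodes = labels)
  planted <- dgm_partition(
    stats::setNames(as.character(rep(seq_len(k), each = s)), labels),
    provenance = "planted")
  list(graph = g, planted = planted, realized_mu = k / g$m)
}

#' Sweep the mixing parameter on planted benchmarks
#'
#' For every `mu` and every replicate seed: generate a planted graph, run
#' the plain greedy baseline and the disassembly-augmented search, and
#' report both modularities plus the NMI of the detected partition against
#' the planted one.
#'
#' @param mus numeric vector of mixing parameters.
#' @param base an [lfr_config]; its `mu` and `seed` are overridden per row.
#' @param dgm a [dgm_config]; its `seed` is offset per replicate.
#' @param n_seeds replicates per `mu`.
#' @return a data frame with columns `mu`, `seed`, `realized_mu`,
#'   `q_greedy`, `q_dgm`, `n_communities_dgm`, `nmi_dgm_planted`.
#' @export
mu_sweep <- function(mus, base = lfr_config(), dgm = dgm_config(),
                     n_seeds = 5L) {
  rows <- list()
  for (mu in mus) {
    for (s in seq_len(n_seeds)) {
      cfg <- base
      cfg$mu <- mu
      cfg$seed <- base$seed + s - 1L
      pg <- generate_planted(cfg)
      gr <- run_greedy(pg$graph)
      dcfg <- dgm
      dcfg$seed <- dgm$seed + s - 1L
      dr <- run_dgm(pg$graph, dcfg)
      rows[[length(rows) + 1L]] <- data.frame(
        mu = mu, seed = cfg$seed, realized_mu = pg$realized_mu,
        q_greedy = gr$q, q_dgm = dr$best_q,
        n_communities_dgm = dr$n_communities,
        nmi_dgm_planted = nmi(dr$best_partition, pg$planted),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
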