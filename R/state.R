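#' Incremental agglomeration state
#'
#' `init_singletons()` builds the mutable bookkeeping used by the greedy
#' agglomeration and the disassembly moves: the current membership, the
#' symmetric matrix of inter-community edge counts (diagonal = internal edge
#' counts), per-community degree sums and the current modularity. The state
#' is an environment and is modified in place by [apply_merge()],
#' [disassemble_node()] and [disassemble_community()].
#'
#' With one community per node the modularity is
#' \eqn{q = -\sum_i (k_i/(2L))^2}.
#'
#' @param g a [dgm_graph] with at least one edge.
#' @return an environment of class `dgm_state` with fields `g`, `L`, `memb`
#'   (integer community id per node index), `active` (logical per community
#'   id), `csize`, `M` (edge-count matrix), `kc` (degree sums) and `q`.
#' @export
init_singletons <- function(g) {
  stopifnot(inherits(g, "dgm_graph"))
  if (g$m < 1L) stop("cannot agglomerate an empty graph (m = 0)", call. = FALSE)
  n <- g$n
  st <- new.env(parent = emptyenv())
  st$g <- g
  st$L <- g$m
  st$memb <- seq_len(n)
  st$active <- rep(TRUE, n)
  st$csize <- rep(1L, n)
  M <- matrix(0, n, n)
  for (e in seq_len(g$m)) {
    i <- g$edges[e, 1L]; j <- g$edges[e, 2L]
    M[i, j] <- M[i, j] + 1
    M[j, i] <- M[j, i] + 1
  }
  st$M <- M
  st$kc <- as.numeric(g$deg)
  st$q <- -sum((st$kc / (2 * st$L))^2)
  class(st) <- c("dgm_state", "environment")
  st
}

#' @export
print.dgm_state <- function(x, ...) {
  cat(sprintf("<dgm_state> %d communities over %d nodes, Q = %.4f\n",
              sum(x$active), x$g$n, x$q))
  invisible(x)
}

#' Modularity gain of merging two communities
#'
#' The exact change in modularity from merging communities `i` and `j`:
#' \eqn{\Delta Q = 2 (e_{ij} - a_i a_j)} with \eqn{e_{ij}} the fraction of
#' edge endpoints joining the two communities and \eqn{a_i = k_{c(i)}/(2L)}.
#' Applying the merge changes the state's `q` by exactly this amount.
#'
#' @param state a `dgm_state`.
#' @param i,j distinct active community ids.
#' @return a single number.
#' @export
delta_q <- function(state, i, j) {
  check_community(state, i)
  check_community(state, j)
  if (i == j) stop("cannot merge a community with itself", call. = FALSE)
  L <- state$L
  state$M[i, j] / L - 2 * (state$kc[i] / (2 * L)) * (state$kc[j] / (2 * L))
}

check_community <- function(state, i) {
  if (!is.numeric(i) || length(i) != 1L || i < 1L || i > length(state$active) ||
      !state$active[i]) {
    stop(sprintf("unknown or inactive community id: %s", as.character(i)[1L]),
         call. = FALSE)
  }
  invisible(i)
}

#' Best merge candidate
#'
#' Finds the pair of connected communities with the largest modularity gain.
#' Ties are broken deterministically by the smallest `(i, j)` id pair, which
#' makes the plain greedy baseline reproducible.
#'
#' @param state a `dgm_state`.
#' @param positive_only if `TRUE` (default), return `NULL` when the best
#'   gain is not strictly positive.
#' @return a list `(i, j, dq)` or `NULL` when no connected pair qualifies.
#' @export
best_merge <- function(state, positive_only = TRUE) {
  act <- which(state$active)
  if (length(act) < 2L) return(NULL)
  L <- state$L
  A <- state$M[act, act, drop = FALSE]
  pos <- which(A > 0)                     # only connected pairs can gain
  if (!length(pos)) return(NULL)
  K <- length(act)
  ri <- (pos - 1L) %% K + 1L
  ci <- (pos - 1L) %/% K + 1L
  up <- ri < ci
  if (!any(up)) return(NULL)
  ri <- ri[up]; ci <- ci[up]
  a <- state$kc[act] / (2 * L)
  dq <- A[pos][up] / L - 2 * a[ri] * a[ci]
  mx <- max(dq)
  if (positive_only && mx <= 0) return(NULL)
  ties <- which(dq == mx)
  pick <- ties[order(ri[ties], ci[ties])[1L]]
  list(i = act[ri[pick]], j = act[ci[pick]], dq = mx)
}

#' Merge two communities in place
#'
#' Community `j` is absorbed into `i` (the smaller id survives); edge
#' tallies, degree sums, sizes and the modularity are updated incrementally.
#'
#' @param state a `dgm_state`.
#' @param i,j distinct active community ids.
#' @return the state, invisibly (modified in place).
#' @export
apply_merge <- function(state, i, j) {
  check_community(state, i)
  check_community(state, j)
  if (i == j) stop("cannot merge a community with itself", call. = FALSE)
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  dq <- delta_q(state, i, j)
  eij <- state$M[i, j]
  act <- which(state$active)
  others <- act[act != i & act != j]
  newint <- state$M[i, i] + state$M[j, j] + eij
  if (length(others)) {
    merged <- state$M[i, others] + state$M[j, others]
    state$M[i, others] <- merged
    state$M[others, i] <- merged
  }
  state$M[i, i] <- newint
  state$M[j, ] <- 0
  state$M[, j] <- 0
  state$kc[i] <- state$kc[i] + state$kc[j]
  state$kc[j] <- 0
  state$csize[i] <- state$csize[i] + state$csize[j]
  state$csize[j] <- 0L
  state$active[j] <- FALSE
  state$memb[state$memb == j] <- i
  state$q <- state$q + dq
  invisible(state)
}

#' Partition snapshot of a state
#'
#' @param state a `dgm_state`.
#' @return a [dgm_partition] with consecutive integer community labels.
#' @export
state_partition <- function(state) {
  memb <- state$memb
  labels <- as.character(match(memb, sort(unique(memb))))
  dgm_partition(stats::setNames(labels, state$g$nodes))
}

# Modularity recomputed from the per-community tallies (O(#communities)).
state_q_from_tallies <- function(state) {
  act <- which(state$active)
  sum(diag(state$M)[act]) / state$L - sum((state$kc[act] / (2 * state$L))^2)
}

# Rebuild communities from explicit member sets, after `clear_community`.
# `sets` is a list of integer node-index vectors. Used by the disassembly
# moves; assumes membership for the affected nodes is being reassigned.
assign_new_communities <- function(state, sets) {
  free <- which(!state$active)
  if (length(sets) > length(free)) stop("internal error: no free community ids")
  ids <- free[seq_along(sets)]
  for (k in seq_along(sets)) {
    state$memb[sets[[k]]] <- ids[k]
  }
  n <- length(state$active)
  for (k in seq_along(sets)) {
    cid <- ids[k]
    S <- sets[[k]]
    nb <- unlist(state$g$adj[S], use.names = FALSE)
    counts <- tabulate(state$memb[nb], nbins = n)
    counts[cid] <- counts[cid] / 2   # internal edges double-counted
    state$M[cid, ] <- counts
    state$M[, cid] <- counts
    state$kc[cid] <- sum(state$g$deg[S])
    state$csize[cid] <- length(S)
    state$active[cid] <- TRUE
  }
  ids
}

clear_community <- function(state, cid) {
  state$M[cid, ] <- 0
  state$M[, cid] <- 0
  state$kc[cid] <- 0
  state$csize[cid] <- 0L
  state$active[cid] <- FALSE
}

#' Plain greedy modularity agglomeration (CNM baseline)
#'
#' Starts from singleton communities and repeatedly applies the merge with
#' the largest strictly positive modularity gain until none remains.
#' Deterministic: ties are broken by the smallest community-id pair.
#'
#' @param g a [dgm_graph] with at least one edge.
#' @return a list with `partition` (a [dgm_partition]), `q` (final
#'   modularity) and `n_communities`.
#' @examples
#' karate <- load_fixture("karate")
#' res <- run_greedy(karate$graph)
#' round(res$q, 4)
#' @export
run_greedy <- function(g) {
  st <- init_singletons(g)
  repeat {
    bm <- best_merge(st, positive_only = TRUE)
    if (is.null(bm)) break
    apply_merge(st, bm$i, bm$j)
  }
  list(partition = state_partition(st), q = st$q,
       n_communities = sum(st$active))
}
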