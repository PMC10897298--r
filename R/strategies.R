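#' @keywords internal
NODE_STRATEGIES <- c("random", "weak", "low_embeddedness", "non_triad")

#' @keywords internal
COMMUNITY_STRATEGIES <- c("random", "weak", "low_density", "low_tpr",
                          "high_conductance")

# uniform pick from a vector (length-safe, consumes one RNG draw)
pick_one <- function(x) {
  if (length(x) == 0L) return(NULL)
  if (length(x) == 1L) return(x[[1L]])
  x[[sample.int(length(x), 1L)]]
}

# per-node internal degrees for all nodes, given current membership
node_internal_degrees <- function(state) {
  g <- state$g
  memb <- state$memb
  vapply(seq_len(g$n), function(u) {
    nb <- g$adj[[u]]
    sum(memb[nb] == memb[u])
  }, numeric(1))
}

#' Select a node-disassembly target
#'
#' Chooses a node to pull out of its community under one of four criteria:
#' \describe{
#'   \item{`random`}{uniform community with more than one member, then a
#'     uniform member;}
#'   \item{`weak`}{uniform pick among nodes whose external degree is at
#'     least their internal degree, with internal degree at least 2, in
#'     communities with more than one member;}
#'   \item{`low_embeddedness`}{the node with globally minimal embeddedness
#'     among communities with more than one member, ties broken uniformly;}
#'   \item{`non_triad`}{uniform pick among members of communities with more
#'     than four members that sit in no internal triangle.}
#' }
#' Selection draws from R's ambient random stream; an empty candidate set is
#' a normal outcome and yields `NULL`.
#'
#' @param state a `dgm_state`.
#' @param strategy one of `"random"`, `"weak"`, `"low_embeddedness"`,
#'   `"non_triad"`.
#' @return a list `(community, node)` of internal ids, or `NULL`.
#' @export
select_node <- function(state, strategy = NODE_STRATEGIES) {
  strategy <- match.arg(strategy, NODE_STRATEGIES)
  elig <- which(state$active & state$csize > 1L)
  if (!length(elig)) return(NULL)
  memb <- state$memb
  if (strategy == "random") {
    cid <- pick_one(elig)
    v <- pick_one(which(memb == cid))
    return(list(community = cid, node = v))
  }
  in_elig <- memb %in% elig
  if (strategy == "weak") {
    kint <- node_internal_degrees(state)
    kext <- state$g$deg - kint
    cand <- which(in_elig & kext >= kint & kint >= 2)
    v <- pick_one(cand)
    if (is.null(v)) return(NULL)
    return(list(community = memb[v], node = v))
  }
  if (strategy == "low_embeddedness") {
    kint <- node_internal_degrees(state)
    deg <- state$g$deg
    ok <- in_elig & deg > 0
    if (!any(ok)) return(NULL)
    emb <- ifelse(ok, kint / pmax(deg, 1), Inf)
    v <- pick_one(which(emb == min(emb[ok]) & ok))
    return(list(community = memb[v], node = v))
  }
  # non_triad
  big <- which(state$active & state$csize > 4L)
  if (!length(big)) return(NULL)
  cand <- integer(0)
  for (cid in big) {
    members <- which(memb == cid)
    tri <- triad_mark(state$g$adj, members)
    cand <- c(cand, setdiff(members, tri))
  }
  v <- pick_one(cand)
  if (is.null(v)) return(NULL)
  list(community = memb[v], node = v)
}

#' Select a community-disassembly target
#'
#' Chooses a community to dissolve under one of five criteria (only
#' communities with more than one member are eligible):
#' \describe{
#'   \item{`random`}{uniform pick;}
#'   \item{`weak`}{smallest internal-minus-external edge balance
#'     `l_c - m_out`;}
#'   \item{`low_density`}{smallest internal edge density;}
#'   \item{`low_tpr`}{smallest triad participation ratio;}
#'   \item{`high_conductance`}{largest conductance (among communities where
#'     it is defined).}
#' }
#' Ties are broken uniformly at random; `NULL` when nothing is eligible.
#'
#' @param state a `dgm_state`.
#' @param strategy one of `"random"`, `"weak"`, `"low_density"`,
#'   `"low_tpr"`, `"high_conductance"`.
#' @return an internal community id, or `NULL`.
#' @export
select_community <- function(state, strategy = COMMUNITY_STRATEGIES) {
  strategy <- match.arg(strategy, COMMUNITY_STRATEGIES)
  elig <- which(state$active & state$csize > 1L)
  if (!length(elig)) return(NULL)
  if (strategy == "random") return(pick_one(elig))
  lc <- diag(state$M)[elig]
  mout <- state$kc[elig] - 2 * lc
  if (strategy == "weak") {
    bal <- lc - mout
    return(pick_one(elig[bal == min(bal)]))
  }
  if (strategy == "low_density") {
    ns <- state$csize[elig]
    dens <- lc / (ns * (ns - 1) / 2)
    return(pick_one(elig[dens == min(dens)]))
  }
  if (strategy == "low_tpr") {
    tpr <- vapply(elig, function(cid) {
      members <- which(state$memb == cid)
      length(triad_mark(state$g$adj, members)) / length(members)
    }, numeric(1))
    return(pick_one(elig[tpr == min(tpr)]))
  }
  # high_conductance
  den <- 2 * lc + mout
  ok <- den > 0
  if (!any(ok)) return(NULL)
  cond <- ifelse(ok, mout / pmax(den, 1), -Inf)
  pick_one(elig[cond == max(cond[ok]) & ok])
}

#' Disassemble a single node out of its community
#'
#' The node becomes a singleton community; each connected component of the
#' remainder of its old community becomes its own community. The modularity
#' is updated consistently and typically decreases.
#'
#' @param state a `dgm_state`.
#' @param community the node's (active) community id.
#' @param v an internal node index belonging to `community`.
#' @return a move record: list with `kind = "node"`, `target_community`,
#'   `target_node` and `created_communities`; the state is modified in
#'   place.
#' @export
disassemble_node <- function(state, community, v) {
  check_community(state, community)
  if (state$memb[v] != community) {
    stop("node does not belong to the given community", call. = FALSE)
  }
  if (state$csize[community] < 2L) {
    stop("cannot disassemble a node out of a singleton community", call. = FALSE)
  }
  members <- which(state$memb == community)
  rest <- members[members != v]
  comps <- components_of(state$g$adj, rest)
  clear_community(state, community)
  ids <- assign_new_communities(state, c(list(v), comps))
  state$q <- state_q_from_tallies(state)
  list(kind = "node", target_community = community, target_node = v,
       created_communities = ids)
}

#' Disassemble a whole community into singletons
#'
#' Every member becomes its own community; tallies and modularity are
#' updated consistently (the modularity strictly decreases whenever the
#' community had internal edges).
#'
#' @param state a `dgm_state`.
#' @param community an active community id with more than one member.
#' @return a move record: list with `kind = "community"`,
#'   `target_community` and `created_communities`; the state is modified in
#'   place.
#' @export
disassemble_community <- function(state, community) {
  check_community(state, community)
  if (state$csize[community] < 2L) {
    stop("cannot disassemble a singleton community", call. = FALSE)
  }
  members <- which(state$memb == community)
  clear_community(state, community)
  ids <- assign_new_communities(state, as.list(members))
  state$q <- state_q_from_tallies(state)
  list(kind = "community", target_community = community,
       created_communities = ids)
}
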