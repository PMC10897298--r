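#' Undirected simple graphs
#'
#' `dgm_graph()` builds the package's graph container from a two-column edge
#' table. Graphs are undirected, unweighted and simple: self loops are
#' rejected and duplicate edges (in either orientation) collapse to one.
#' Node identifiers are opaque tokens; internally nodes are re-indexed to
#' `1:n` but every user-facing interface speaks in the original labels.
#'
#' @param edges a two-column matrix or data frame of edge endpoints
#'   (character or integer labels; coerced to character).
#' @param nodes optional character vector of node labels, used to include
#'   isolated nodes and to fix the node ordering. Defaults to the sorted
#'   set of labels seen in `edges`.
#' @return an object of class `dgm_graph` with elements `nodes` (character
#'   labels), `n`, `m`, `deg` (integer degrees), `adj` (adjacency lists of
#'   integer node indices) and `edges` (an `m x 2` integer index matrix).
#' @examples
#' g <- dgm_graph(cbind(c("a", "b", "c"), c("b", "c", "a")))
#' g$n  # 3
#' g$m  # 3
#' @export
dgm_graph <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2L) stop("`edges` must have two columns", call. = FALSE)
  e1 <- as.character(edges[, 1L])
  e2 <- as.character(edges[, 2L])
  if (any(is.na(e1) | is.na(e2) | e1 == "" | e2 == "")) {
    stop("edge endpoints must be non-missing labels", call. = FALSE)
  }
  if (any(e1 == e2)) {
    bad <- which(e1 == e2)[1L]
    stop(sprintf("self-loop on node '%s' is not allowed", e1[bad]), call. = FALSE)
  }
  if (is.null(nodes)) {
    nodes <- sort(unique(c(e1, e2)))
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate node labels", call. = FALSE)
    missing <- setdiff(unique(c(e1, e2)), nodes)
    if (length(missing)) {
      stop(sprintf("edge endpoint(s) not in `nodes`: %s",
                   paste(utils::head(missing, 5L), collapse = ", ")), call. = FALSE)
    }
  }
  i1 <- match(e1, nodes)
  i2 <- match(e2, nodes)
  lo <- pmin(i1, i2)
  hi <- pmax(i1, i2)
  keep <- !duplicated(lo * (length(nodes) + 1) + hi)
  lo <- lo[keep]; hi <- hi[keep]
  ord <- order(lo, hi)
  em <- cbind(lo[ord], hi[ord])
  n <- length(nodes)
  adj <- vector("list", n)
  if (nrow(em)) {
    ends <- c(em[, 1L], em[, 2L])
    nbrs <- c(em[, 2L], em[, 1L])
    o <- order(ends, nbrs)
    adj <- unname(split(nbrs[o], factor(ends[o], levels = seq_len(n))))
  } else {
    adj <- rep(list(integer(0)), n)
  }
  adj <- lapply(adj, as.integer)
  deg <- lengths(adj)
  structure(
    list(nodes = nodes, n = n, m = nrow(em), deg = as.integer(deg),
         adj = adj, edges = em),
    class = "dgm_graph"
  )
}

#' @export
print.dgm_graph <- function(x, ...) {
  cat(sprintf("<dgm_graph> %d nodes, %d edges\n", x$n, x$m))
  invisible(x)
}

node_index <- function(g, v) {
  i <- match(as.character(v), g$nodes)
  if (anyNA(i)) {
    stop(sprintf("unknown node(s): %s",
                 paste(utils::head(as.character(v)[is.na(i)], 5L), collapse = ", ")),
         call. = FALSE)
  }
  i
}

#' Read a whitespace-delimited edge list
#'
#' Each non-comment line must carry at least two whitespace-separated tokens;
#' the first two are the edge endpoints and any further tokens (e.g. weights)
#' are ignored with a warning. Duplicate lines and reversed duplicates
#' collapse to a single edge.
#'
#' @param path path to the edge-list file.
#' @param comment_prefix lines starting with this prefix are skipped.
#' @return a [dgm_graph].
#' @export
read_edgelist <- function(path, comment_prefix = "#") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), comment_prefix) & nzchar(trimws(lines))
  idx <- which(keep)
  toks <- strsplit(trimws(lines[idx]), "[[:space:]]+")
  bad <- which(lengths(toks) < 2L)
  if (length(bad)) {
    stop(sprintf("malformed edge list line %d: '%s' (need two endpoints)",
                 idx[bad[1L]], lines[idx[bad[1L]]]), call. = FALSE)
  }
  if (any(lengths(toks) > 2L)) {
    warning("extra tokens on edge lines ignored (graphs are unweighted)")
  }
  e1 <- vapply(toks, `[[`, "", 1L)
  e2 <- vapply(toks, `[[`, "", 2L)
  loop <- which(e1 == e2)
  if (length(loop)) {
    stop(sprintf("self-loop at line %d: '%s'", idx[loop[1L]], lines[idx[loop[1L]]]),
         call. = FALSE)
  }
  dgm_graph(cbind(e1, e2))
}

#' Read a GML graph (Newman-collection dialect)
#'
#' Parses `graph`/`node`/`edge` blocks with `id`, optional `label` and
#' `value` node attributes, and `source`/`target` edge keys. A node `label`
#' is used as the node identifier when present, otherwise the numeric `id`.
#' When every node carries a numeric `value`, those values are exposed as a
#' reference partition retrievable with [reference_partition()].
#' Directed graphs are rejected; edge weights are ignored with a warning.
#'
#' @param path path to the GML file.
#' @return a [dgm_graph], with a `reference` attribute when node values are
#'   present.
#' @export
read_gml <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ig <- tryCatch(
    igraph::read_graph(path, format = "gml"),
    error = function(e) stop(sprintf("GML parse error in %s: %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
  if (igraph::is_directed(ig)) {
    stop("directed GML graphs are not supported", call. = FALSE)
  }
  va <- igraph::vertex_attr_names(ig)
  if ("label" %in% va) {
    labels <- as.character(igraph::vertex_attr(ig, "label"))
  } else if ("id" %in% va) {
    labels <- as.character(igraph::vertex_attr(ig, "id"))
  } else {
    labels <- as.character(seq_len(igraph::vcount(ig)))
  }
  if (anyDuplicated(labels)) labels <- make.unique(labels)
  if ("weight" %in% igraph::edge_attr_names(ig)) {
    warning("edge weights in GML file ignored (graphs are unweighted)")
  }
  el <- igraph::as_edgelist(ig, names = FALSE)
  if (nrow(el) == 0L) stop("GML graph has no edges", call. = FALSE)
  loops <- el[, 1L] == el[, 2L]
  if (any(loops)) stop("GML graph contains self-loops", call. = FALSE)
  g <- dgm_graph(cbind(labels[el[, 1L]], labels[el[, 2L]]), nodes = sort(labels))
  if ("value" %in% va) {
    vals <- igraph::vertex_attr(ig, "value")
    if (is.numeric(vals) && !anyNA(vals)) {
      memb <- stats::setNames(as.character(vals), labels)[g$nodes]
      attr(g, "reference") <- dgm_partition(memb, provenance = "gml value")
    }
  }
  g
}

#' Reference partition attached to a graph
#'
#' Returns the reference (ground-truth) partition read alongside a graph,
#' e.g. the numeric `value` node attribute of a GML file, or `NULL` when
#' none is present.
#'
#' @param g a [dgm_graph].
#' @return a [dgm_partition] or `NULL`.
#' @export
reference_partition <- function(g) attr(g, "reference")

#' Bundled example networks
#'
#' `load_fixture("karate")` returns Zachary's karate club network
#' (34 nodes, 78 edges) together with the two-faction reference partition
#' (the group around the instructor versus the group around the club
#' president) observed when the club split.
#'
#' @param name fixture name; currently only `"karate"`.
#' @return a list with elements `graph` (a [dgm_graph]) and
#'   `reference` (a [dgm_partition] with two communities).
#' @export
load_fixture <- function(name) {
  available <- c("karate")
  if (!is.character(name) || length(name) != 1L || !(name %in% available)) {
    stop(sprintf("unknown fixture '%s'; available: %s",
                 as.character(name)[1L], paste(available, collapse = ", ")),
         call. = FALSE)
  }
  g <- read_edgelist(system.file("extdata", "karate.edgelist", package = "dgmod"))
  ref <- read_membership(system.file("extdata", "karate_factions.tsv", package = "dgmod"))
  attr(ref, "provenance") <- "faction"
  list(graph = g, reference = ref)
}

#' Connected components of an induced subgraph
#'
#' Computes the connected components of the subgraph induced by `nodes`,
#' the splitting step used after a node is pulled out of its community.
#'
#' @param g a [dgm_graph].
#' @param nodes node labels (a subset of `g$nodes`).
#' @return a list of character vectors (sorted within and between
#'   components), whose union is `nodes`.
#' @export
induced_components <- function(g, nodes) {
  idx <- node_index(g, nodes)
  comps <- components_of(g$adj, idx)
  out <- lapply(comps, function(ix) sort(g$nodes[ix]))
  out[order(vapply(out, `[[`, "", 1L))]
}

# BFS components of the subgraph induced on integer node indices `idx`.
components_of <- function(adj, idx) {
  if (!length(idx)) return(list())
  inset <- logical(length(adj))
  inset[idx] <- TRUE
  seen <- logical(length(adj))
  comps <- list()
  for (s in idx) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      members <- c(members, u)
      nb <- adj[[u]]
      nb <- nb[inset[nb] & !seen[nb]]
      if (length(nb)) {
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

#' Write and read membership tables
#'
#' A membership table is a two-column tab-separated file with a header line
#' `node<TAB>community` and one row per node, sorted by node label. Writing
#' then reading a partition reproduces it exactly.
#'
#' @param p a [dgm_partition].
#' @param path file path.
#' @return `write_membership()` returns `path` invisibly;
#'   `read_membership()` returns a [dgm_partition].
#' @export
write_membership <- function(p, path) {
  stopifnot(inherits(p, "dgm_partition"))
  nodes <- sort(names(p$membership))
  df <- data.frame(node = nodes, community = unname(p$membership[nodes]),
                   stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write membership file %s: %s", path,
                 conditionMessage(ok)), call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_membership
#' @export
read_membership <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) stop("membership file needs columns node, community", call. = FALSE)
  dgm_partition(stats::setNames(df[[2L]], df[[1L]]))
}
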