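#' Node partitions
#'
#' A partition assigns every node to exactly one community. Communities are
#' identified by arbitrary labels; empty communities cannot occur because a
#' community exists only as the set of nodes assigned to it.
#'
#' @param membership named vector mapping node label to community label.
#' @param provenance optional string describing where the labels come from
#'   (e.g. `"faction"` for the karate ground truth).
#' @return an object of class `dgm_partition` with elements `membership`
#'   (named character vector) and `provenance`.
#' @export
dgm_partition <- function(membership, provenance = NULL) {
  if (is.null(names(membership)) || any(!nzchar(names(membership)))) {
    stop("`membership` must be a named vector (node -> community)", call. = FALSE)
  }
  if (anyNA(membership)) stop("membership contains NA", call. = FALSE)
  if (anyDuplicated(names(membership))) {
    stop("duplicate node labels in membership", call. = FALSE)
  }
  structure(
    list(membership = stats::setNames(as.character(membership), names(membership)),
         provenance = provenance),
    class = "dgm_partition"
  )
}

#' @export
print.dgm_partition <- function(x, ...) {
  k <- length(unique(x$membership))
  cat(sprintf("<dgm_partition> %d nodes in %d communities%s\n",
              length(x$membership), k,
              if (is.null(x$provenance)) "" else sprintf(" (%s)", x$provenance)))
  invisible(x)
}

#' Communities of a partition
#'
#' @param p a [dgm_partition].
#' @return a named list of character vectors, one per community.
#' @export
partition_communities <- function(p) {
  stopifnot(inherits(p, "dgm_partition"))
  split(names(p$membership), p$membership)
}

#' Number of communities in a partition
#'
#' @param p a [dgm_partition].
#' @return integer count.
#' @export
n_communities <- function(p) {
  stopifnot(inherits(p, "dgm_partition"))
  length(unique(p$membership))
}

# Check that `p` partitions exactly the node set of `g`; returns integer
# community ids aligned with g$nodes.
partition_index <- function(g, p) {
  stopifnot(inherits(g, "dgm_graph"), inherits(p, "dgm_partition"))
  if (length(p$membership) != g$n || !setequal(names(p$membership), g$nodes)) {
    stop("partition does not cover exactly the graph's node set", call. = FALSE)
  }
  memb <- p$membership[g$nodes]
  as.integer(factor(memb, levels = unique(memb)))
}
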