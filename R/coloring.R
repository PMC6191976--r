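# Run code under a fixed RNG seed when one is supplied; otherwise consume
# the current stream (used so greedy_color seeds once and the per-round
# luby_mis draws flow from that single generator).
maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Luby maximal independent set
#'
#' Extracts a maximal independent set (MIS) of the subgraph induced by
#' \code{active} using Luby's randomized parallel scheme: in each round every
#' surviving node proposes itself with probability
#' \eqn{p(v) = 1 / (2\,\mathrm{deg}(v))} (probability 1 for residual-isolated
#' nodes, favoring low-degree vertices); when both endpoints of an edge
#' propose, the higher-degree endpoint is kept (degree ties broken toward
#' the larger node index); winners join the set and are removed together
#' with their neighbors, until the residual set is empty.  Degrees are
#' recomputed against the shrinking residual graph each round.  Per-round
#' uniform draws are consumed in ascending node-index order, so the result
#' depends only on \code{(graph, active, seed)}.
#'
#' @param graph a \code{\link{weighted_graph}}; only the edge pattern is
#'   used (weights are ignored).
#' @param active nonempty integer vector of node indices to draw from.
#' @param seed integer seed, or \code{NULL} to consume the caller's RNG
#'   stream.
#' @return Sorted integer vector of node indices: a maximal independent set
#'   of the induced subgraph.
#' @examples
#' tri <- weighted_graph(c(1, 1, 2), c(2, 3, 3), rep(1, 3), n = 3)
#' length(luby_mis(tri, 1:3, seed = 1))   # always 1 on a triangle
#' @export
luby_mis <- function(graph, active, seed = NULL) {
  if (!length(active)) stop("active node set must be nonempty")
  active <- sort(unique(as.integer(active)))
  stopifnot(min(active) >= 1, max(active) <= graph$n)
  csr <- graph_csr(graph)
  maybe_with_seed(seed, luby_mis_impl(graph, csr, active))
}

luby_mis_impl <- function(graph, csr, active) {
  n <- graph$n
  residual <- logical(n)
  residual[active] <- TRUE
  chosen <- integer(0)
  while (any(residual)) {
    res <- which(residual)
    deg <- vapply(res, function(u) {
      nb <- csr_neighbors(csr, u)$nbr
      sum(residual[nb])
    }, integer(1))
    p <- ifelse(deg == 0L, 1, 1 / (2 * deg))
    # draws consumed in ascending node-index order (res is sorted)
    cand <- res[stats::runif(length(res)) < p]
    if (!length(cand)) next
    # total order on candidates: residual degree, then node index
    key <- numeric(n)
    key[cand] <- deg[match(cand, res)] * (n + 1) + cand
    is_cand <- logical(n)
    is_cand[cand] <- TRUE
    win <- vapply(cand, function(u) {
      nb <- csr_neighbors(csr, u)$nbr
      nb <- nb[is_cand[nb]]
      !length(nb) || all(key[nb] < key[u])
    }, logical(1))
    winners <- cand[win]
    if (!length(winners)) next
    chosen <- c(chosen, winners)
    residual[winners] <- FALSE
    for (u in winners) {
      residual[csr_neighbors(csr, u)$nbr] <- FALSE
    }
  }
  sort(chosen)
}

#' Greedy graph coloring by iterated MIS extraction
#'
#' Partitions \code{nodes} into independent sets: repeatedly extract a
#' maximal independent set of the residual induced subgraph
#' (\code{\link{luby_mis}}), assign it the next color, remove it, until no
#' node remains.  Because each class is a MIS of its residual graph, every
#' remaining node has a neighbor in each earlier class, which bounds the
#' number of colors by \eqn{\Delta + 1} (\eqn{\Delta} = maximum degree of
#' the colored subgraph).  The partition is proper by construction; the
#' method does not seek the chromatic number, only a small, fast partition.
#'
#' @param graph a \code{\link{weighted_graph}}.
#' @param nodes node indices to color (default all nodes).
#' @param seed integer seed for the single RNG stream driving all rounds.
#' @return An object of class \code{coloring_partition}: list with
#'   \code{classes} (list of sorted integer vectors, extraction order),
#'   \code{k}, and \code{ordering} (the induced permutation: classes
#'   concatenated, ascending index within each class).
#' @export
greedy_color <- function(graph, nodes = seq_len(graph$n), seed = NULL) {
  nodes <- sort(unique(as.integer(nodes)))
  if (!length(nodes)) {
    return(structure(list(classes = list(), k = 0L, ordering = integer()),
                     class = "coloring_partition"))
  }
  csr <- graph_csr(graph)
  maybe_with_seed(seed, {
    classes <- list()
    remaining <- nodes
    while (length(remaining)) {
      cls <- luby_mis_impl(graph, csr, remaining)
      classes[[length(classes) + 1L]] <- cls
      remaining <- setdiff(remaining, cls)
    }
    structure(list(classes = classes, k = length(classes),
                   ordering = unlist(classes, use.names = FALSE)),
              class = "coloring_partition")
  })
}

#' @export
print.coloring_partition <- function(x, ...) {
  cat("coloring_partition: k =", x$k, "classes over",
      length(x$ordering), "nodes\n")
  invisible(x)
}

#' Validate a coloring partition
#'
#' Checks that the classes are disjoint and that no edge of \code{graph}
#' has both endpoints in one class (propriety).
#'
#' @param graph a \code{\link{weighted_graph}}.
#' @param partition a \code{coloring_partition}.
#' @return A list with \code{ok} (logical) and \code{violation}
#'   (\code{NULL}, or a one-line description of the first offending node or
#'   edge).
#' @export
verify_coloring <- function(graph, partition) {
  all_nodes <- unlist(partition$classes, use.names = FALSE)
  if (anyDuplicated(all_nodes)) {
    u <- all_nodes[duplicated(all_nodes)][1]
    return(list(ok = FALSE,
                violation = paste0("node ", graph$node_ids[u],
                                   " appears in more than one class")))
  }
  csr <- graph_csr(graph)
  color <- rep(NA_integer_, graph$n)
  for (c_idx in seq_along(partition$classes))
    color[partition$classes[[c_idx]]] <- c_idx
  for (u in all_nodes) {
    nb <- csr_neighbors(csr, u)$nbr
    bad <- nb[!is.na(color[nb]) & color[nb] == color[u]]
    if (length(bad)) {
      return(list(ok = FALSE,
                  violation = paste0("edge (", graph$node_ids[u], ", ",
                                     graph$node_ids[bad[1]],
                                     ") inside class ", color[u])))
    }
  }
  list(ok = TRUE, violation = NULL)
}
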