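#' Sparse symmetric weighted graph
#'
#' The central container of the package: an undirected weighted graph with
#' non-negative edge weights, no self loops, and external string node
#' identifiers.  Internally the adjacency is held as a symmetric sparse
#' matrix (\code{Matrix::dsCMatrix}) storing each undirected edge once, so a
#' graph with \code{n} nodes and \code{m} edges costs about
#' \code{2 * n + 2 * m} stored values (one index and one weight per edge plus
#' two per-node slots for column offsets and thresholds); see
#' \code{\link{storage_footprint}}.
#'
#' @param i,j integer vectors of endpoint indices (1-based, any orientation).
#' @param w numeric vector of edge weights, finite and non-negative.
#' @param n node count.
#' @param node_ids character vector of external identifiers, length \code{n};
#'   defaults to \code{"v1" ... "vn"}.
#' @return An object of class \code{weighted_graph} with elements \code{W}
#'   (symmetric sparse matrix), \code{node_ids}, \code{n}, \code{m}.
#' @examples
#' g <- weighted_graph(c(1, 2), c(2, 3), c(1, 0.5), n = 3,
#'                     node_ids = c("a", "b", "c"))
#' graph_n(g); graph_m(g)
#' @export
weighted_graph <- function(i, j, w, n, node_ids = NULL) {
  stopifnot(length(i) == length(j), length(i) == length(w))
  if (is.null(node_ids)) node_ids <- paste0("v", seq_len(n))
  stopifnot(length(node_ids) == n, !anyDuplicated(node_ids))
  if (length(i)) {
    if (any(!is.finite(w)) || any(w < 0))
      stop("edge weights must be finite and non-negative")
    if (any(i == j))
      stop("self-loop forbidden at node '", node_ids[i[which(i == j)[1]]], "'")
    lo <- pmin(i, j); hi <- pmax(i, j)
    key <- (lo - 1) * n + hi
    if (anyDuplicated(key)) {
      d <- which(duplicated(key))[1]
      stop("duplicate edge between '", node_ids[lo[d]], "' and '",
           node_ids[hi[d]], "'")
    }
    W <- Matrix::sparseMatrix(i = lo, j = hi, x = w, dims = c(n, n),
                              symmetric = TRUE)
  } else {
    W <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(n, n), symmetric = TRUE)
  }
  W <- Matrix::drop0(W)
  new_weighted_graph(W, node_ids)
}

new_weighted_graph <- function(W, node_ids) {
  structure(
    list(W = W, node_ids = node_ids, n = nrow(W), m = length(W@x)),
    class = "weighted_graph"
  )
}

#' @rdname weighted_graph
#' @param graph a \code{weighted_graph}.
#' @export
graph_n <- function(graph) graph$n

#' @rdname weighted_graph
#' @export
graph_m <- function(graph) graph$m

#' @export
print.weighted_graph <- function(x, ...) {
  cat("weighted_graph:", x$n, "nodes,", x$m, "edges\n")
  invisible(x)
}

#' Dense adjacency of a small graph (testing / oracle use)
#' @param graph a \code{weighted_graph}.
#' @return A base dense symmetric matrix.
#' @export
as_dense <- function(graph) {
  as.matrix(graph$W)
}

# Full (both-triangle) column-compressed form used by traversal code.
# Columns of the dgCMatrix are per-node neighbor lists by symmetry.
as_general <- function(graph) {
  methods::as(methods::as(graph$W, "generalMatrix"), "CsparseMatrix")
}

# Compressed neighbor lists: ptr (length n+1, 0-based offsets), nbr, w.
graph_csr <- function(graph) {
  G <- as_general(graph)
  list(ptr = G@p, nbr = G@i + 1L, w = G@x)
}

# Neighbors of node u from a graph_csr structure.
csr_neighbors <- function(csr, u) {
  lo <- csr$ptr[u] + 1L
  hi <- csr$ptr[u + 1L]
  if (hi < lo) return(list(nbr = integer(), w = numeric()))
  idx <- lo:hi
  list(nbr = csr$nbr[idx], w = csr$w[idx])
}

#' Edge list of a graph
#'
#' @param graph a \code{weighted_graph}.
#' @return A data frame with columns \code{from}, \code{to} (external ids)
#'   and \code{weight}, one row per undirected edge.
#' @export
graph_edges <- function(graph) {
  Wt <- methods::as(graph$W, "TsparseMatrix")
  i <- Wt@i + 1L
  j <- Wt@j + 1L
  data.frame(from = graph$node_ids[pmin(i, j)],
             to = graph$node_ids[pmax(i, j)],
             weight = Wt@x,
             stringsAsFactors = FALSE)
}

#' Weighted node degrees
#'
#' The diagonal of the degree matrix \eqn{D}: \eqn{d_{ii} = \sum_j W_{ij}},
#' the sum of weights incident to each node.  Zero exactly for isolated
#' nodes.
#'
#' @param graph a \code{weighted_graph}.
#' @return Numeric vector of length \code{n}, named by external id.
#' @export
graph_degree <- function(graph) {
  d <- as.numeric(Matrix::rowSums(methods::as(graph$W, "generalMatrix")))
  names(d) <- graph$node_ids
  d
}

#' Symmetric degree normalization
#'
#' Rescales a raw similarity network \eqn{\hat W} to
#' \eqn{W = D^{-1/2} \hat W D^{-1/2}}, where \eqn{D} is diagonal with
#' \eqn{d_{ii} = \sum_j \hat W_{ij}}.  The output is symmetric, weights lie
#' in \eqn{[0, 1]} whenever every raw weight is at most the smaller of its
#' endpoint degrees, and no node is dropped: isolated nodes (with
#' \eqn{d_{ii} = 0}) keep an all-zero row and column, with the corresponding
#' \eqn{D^{-1/2}} entry defined as 0 so no division by zero occurs.
#'
#' @param raw a \code{weighted_graph} with non-negative weights.
#' @return A \code{weighted_graph} over the same node set.
#' @examples
#' g <- weighted_graph(c(1, 2), c(3, 3), c(1, 1), n = 3)
#' as_dense(normalize_graph(g))   # off-diagonal entries 1/sqrt(2)
#' @export
normalize_graph <- function(raw) {
  d <- unname(graph_degree(raw))
  s <- ifelse(d > 0, 1 / sqrt(d), 0)
  Wt <- methods::as(raw$W, "TsparseMatrix")
  x <- Wt@x * s[Wt@i + 1L] * s[Wt@j + 1L]
  W <- Matrix::sparseMatrix(i = Wt@i + 1L, j = Wt@j + 1L, x = x,
                            dims = dim(raw$W), symmetric = TRUE)
  new_weighted_graph(Matrix::drop0(W), raw$node_ids)
}

#' Compressed-storage footprint
#'
#' Number of stored real values the compressed representation of a graph
#' may occupy: exactly \code{2 * n + 2 * m} (one neighbor index and one
#' weight per edge plus two per-node slots).  The in-memory payload of a
#' \code{weighted_graph} (column pointers, row indices, weights) never
#' exceeds this bound; see \code{\link{storage_payload}}.
#'
#' @param graph a \code{weighted_graph}.
#' @return Integer-valued numeric: \code{2 * n + 2 * m}.
#' @export
storage_footprint <- function(graph) {
  2 * graph$n + 2 * graph$m
}

#' Actual stored payload of a graph object
#'
#' Counts the index/weight payload values held by the sparse representation
#' (row indices, weights, column offsets); excludes bookkeeping scalars.
#' Always at most \code{\link{storage_footprint}}.
#'
#' @param graph a \code{weighted_graph}.
#' @return Number of stored payload values.
#' @export
storage_payload <- function(graph) {
  length(graph$W@i) + length(graph$W@x) + length(graph$W@p)
}

#' Induced subgraph
#'
#' @param graph a \code{weighted_graph}.
#' @param nodes integer vector of (internal, 1-based) node indices to keep,
#'   in the order they should appear in the subgraph.
#' @return A \code{weighted_graph} on \code{length(nodes)} nodes.
#' @export
induced_subgraph <- function(graph, nodes) {
  stopifnot(!anyDuplicated(nodes), all(nodes >= 1), all(nodes <= graph$n))
  Wsub <- methods::as(graph$W, "generalMatrix")[nodes, nodes, drop = FALSE]
  Wsub <- Matrix::forceSymmetric(methods::as(Wsub, "CsparseMatrix"), uplo = "U")
  new_weighted_graph(Matrix::drop0(Wsub), graph$node_ids[nodes])
}

# Map external ids to internal indices, erroring on unknown ids.
resolve_ids <- function(graph, ids) {
  idx <- match(ids, graph$node_ids)
  if (anyNA(idx))
    stop("unknown node id(s): ", paste(ids[is.na(idx)][1:min(3, sum(is.na(idx)))],
                                       collapse = ", "))
  idx
}
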