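#' Binary node labeling
#'
#' Partition of the node set for one binary class into labeled positives
#' \code{S+}, labeled negatives \code{S-}, and unlabeled nodes \code{U}
#' (everything else).  The three sets are disjoint and cover the node set.
#'
#' @param graph the \code{\link{weighted_graph}} (or its node count).
#' @param s_pos,s_neg integer vectors of internal node indices.
#' @return An object of class \code{node_labeling} with elements
#'   \code{s_pos}, \code{s_neg}, \code{u}, \code{n}.
#' @export
node_labeling <- function(graph, s_pos, s_neg) {
  n <- if (inherits(graph, "weighted_graph")) graph$n else as.integer(graph)
  s_pos <- sort(unique(as.integer(s_pos)))
  s_neg <- sort(unique(as.integer(s_neg)))
  if (length(intersect(s_pos, s_neg)))
    stop("a node cannot be labeled both positive and negative")
  if (length(s_pos) && (min(s_pos) < 1 || max(s_pos) > n)) stop("s_pos out of range")
  if (length(s_neg) && (min(s_neg) < 1 || max(s_neg) > n)) stop("s_neg out of range")
  u <- setdiff(seq_len(n), c(s_pos, s_neg))
  structure(list(s_pos = s_pos, s_neg = s_neg, u = u, n = n),
            class = "node_labeling")
}

#' @export
print.node_labeling <- function(x, ...) {
  cat("node_labeling:", length(x$s_pos), "positive,", length(x$s_neg),
      "negative,", length(x$u), "unlabeled (n =", x$n, ")\n")
  invisible(x)
}

labeled_set <- function(labeling) c(labeling$s_pos, labeling$s_neg)
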