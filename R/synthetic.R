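# Sample k-subsets of {0, ..., npairs-1} by geometric gap-skipping:
# each index is included independently with probability p, but only the
# included positions are ever touched, so expected cost is O(p * npairs)
# rather than O(npairs).  npairs may exceed 2^31; doubles are exact here.
sample_pair_indices <- function(npairs, p) {
  if (npairs <= 0 || p <= 0) return(numeric(0))
  if (p >= 1) return(seq_len(npairs) - 1)
  out <- vector("list", 8L)
  chunk <- max(1024L, ceiling(npairs * p * 1.2))
  pos <- -1
  k <- 0L
  while (pos < npairs - 1) {
    gaps <- stats::rgeom(chunk, p) + 1
    cum <- pos + cumsum(gaps)
    keep <- cum <= npairs - 1
    k <- k + 1L
    out[[k]] <- cum[keep]
    if (!all(keep)) break
    pos <- cum[length(cum)]
  }
  unlist(out[seq_len(k)], use.names = FALSE)
}

# Map 0-based linear indices over the upper triangle (row-major, i < j,
# 0-based nodes) of an n x n matrix back to (i, j).
pair_from_index <- function(t, n) {
  # offset(i) = i*n - i*(i+1)/2 is the first index of row i
  i <- floor((2 * n - 1 - sqrt((2 * n - 1)^2 - 8 * t)) / 2)
  off <- i * n - i * (i + 1) / 2
  # guard against floating-point edge cases of the closed form
  too_big <- off > t
  i[too_big] <- i[too_big] - 1
  off <- i * n - i * (i + 1) / 2
  nxt <- off + (n - 1 - i)
  too_small <- t >= nxt
  i[too_small] <- i[too_small] + 1
  off <- i * n - i * (i + 1) / 2
  j <- t - off + i + 1
  list(i = as.integer(i + 1), j = as.integer(j + 1))  # back to 1-based
}

#' Erdős–Rényi weighted benchmark graph
#'
#' G(n, p) with every unordered pair independently an edge with probability
#' \code{p} and i.i.d. uniform \eqn{[0,1]} weights — the synthetic
#' benchmark family used for scalability studies of network-based function
#' prediction, where the density \eqn{\sigma = np} is matched to real
#' protein networks (tens to a few hundred expected neighbors).  Edge
#' sampling uses geometric gap-skipping, so generation costs O(expected
#' edge count), permitting million-node graphs.
#'
#' @param n node count.
#' @param p edge probability in \eqn{[0,1]}; give either \code{p} or
#'   \code{sigma}.
#' @param sigma target density \eqn{\sigma = n p}; converted to
#'   \code{p = sigma / n}.
#' @param seed integer seed; the graph is a deterministic function of
#'   \code{(n, p, seed)}.
#' @return A \code{\link{weighted_graph}} with node ids \code{"v1"..."vn"}.
#' @examples
#' g <- generate_erdos(200, sigma = 10, seed = 42)
#' mean(graph_degree(g) > 0)
#' @export
generate_erdos <- function(n, p = NULL, sigma = NULL, seed = 1L) {
  n <- as.numeric(n)
  if (n < 0) stop("n must be non-negative")
  if (is.null(p) == is.null(sigma)) stop("give exactly one of p or sigma")
  if (is.null(p)) p <- sigma / n
  if (p < 0 || p > 1) stop("edge probability must lie in [0,1]")
  withr::with_seed(as.integer(seed), {
    npairs <- n * (n - 1) / 2
    t <- sample_pair_indices(npairs, p)
    ij <- pair_from_index(t, n)
    w <- stats::runif(length(t))
    weighted_graph(ij$i, ij$j, w, n = as.integer(n))
  })
}

#' Unbalanced random labeling
#'
#' Samples a labeled set \eqn{S} of \code{labeled_fraction * n} nodes
#' uniformly, marks a \code{pos_fraction} share of \eqn{S} positive and the
#' rest negative; everything else is unlabeled.  Mirrors the strong
#' positive-class rarity of real functional classes (defaults: 1\%
#' positives, 80\% labeled).
#'
#' @param graph a \code{\link{weighted_graph}}.
#' @param pos_fraction share of labeled nodes that are positive, in (0,1).
#' @param labeled_fraction share of nodes that are labeled, in (0,1].
#' @param seed integer seed.
#' @return A \code{\link{node_labeling}}.
#' @export
generate_unbalanced_labels <- function(graph, pos_fraction = 0.01,
                                       labeled_fraction = 0.8, seed = 1L) {
  stopifnot(pos_fraction > 0, pos_fraction < 1,
            labeled_fraction > 0, labeled_fraction <= 1)
  n <- graph$n
  n_s <- round(labeled_fraction * n)
  n_pos <- round(pos_fraction * n_s)
  if (n_pos < 1 || n_s - n_pos < 1)
    stop("fractions leave an empty labeled class; increase n or the fractions")
  withr::with_seed(as.integer(seed), {
    s <- sample.int(n, n_s)
    node_labeling(graph, s_pos = s[seq_len(n_pos)],
                  s_neg = s[(n_pos + 1):n_s])
  })
}

#' Planted two-community fixture
#'
#' A stochastic block model with a small positive community
#' (\code{pos_fraction * n} nodes) and a large negative one: edge
#' probability \code{p_in} within each community, \code{p_out} across,
#' uniform \eqn{[0,1]} weights.  A \code{labeled_fraction} share of each
#' community is labeled (stratified), the rest is unlabeled but keeps its
#' ground-truth community for recovery scoring.  This is the package's
#' recoverability test bed: with \code{p_in >> p_out} the unlabeled
#' positives are identifiable from connectivity alone.
#'
#' @param n node count.
#' @param pos_fraction positive community share, in (0,1).
#' @param p_in,p_out within/between community edge probabilities,
#'   \code{p_in > p_out}.
#' @param labeled_fraction labeled share of each community, in (0,1).
#' @param seed integer seed.
#' @return List with \code{graph} (a \code{\link{weighted_graph}}),
#'   \code{labeling} (a \code{\link{node_labeling}}), and \code{truth}
#'   (integer vector of the planted positive nodes, labeled and unlabeled).
#' @export
generate_planted_fixture <- function(n, pos_fraction = 0.05, p_in = 0.05,
                                     p_out = 0.002, labeled_fraction = 0.5,
                                     seed = 1L) {
  stopifnot(p_in > p_out, p_out >= 0, p_in <= 1,
            pos_fraction > 0, pos_fraction < 1,
            labeled_fraction > 0, labeled_fraction < 1)
  n <- as.integer(n)
  n1 <- as.integer(round(pos_fraction * n))   # positive community: nodes 1..n1
  n2 <- n - n1
  if (n1 < 2 || n2 < 2) stop("degenerate community sizes")
  withr::with_seed(as.integer(seed), {
    # within-community blocks reuse the triangular sampler
    t1 <- sample_pair_indices(n1 * (n1 - 1) / 2, p_in)
    e1 <- pair_from_index(t1, n1)
    t2 <- sample_pair_indices(n2 * (n2 - 1) / 2, p_in)
    e2 <- pair_from_index(t2, n2)
    # bipartite block: linear indices over the n1 x n2 grid
    tb <- sample_pair_indices(as.numeric(n1) * n2, p_out)
    bi <- as.integer(tb %/% n2) + 1L
    bj <- as.integer(tb %% n2) + 1L
    i <- c(e1$i, e2$i + n1, bi)
    j <- c(e1$j, e2$j + n1, bj + n1)
    w <- stats::runif(length(i))
    graph <- weighted_graph(i, j, w, n = n)
    lab1 <- sample.int(n1, max(1L, round(labeled_fraction * n1)))
    lab2 <- n1 + sample.int(n2, max(1L, round(labeled_fraction * n2)))
    labeling <- node_labeling(graph, s_pos = lab1, s_neg = lab2)
    list(graph = graph, labeling = labeling, truth = seq_len(n1))
  })
}
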