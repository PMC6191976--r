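#' Read a weighted graph from an edge list
#'
#' Parses a text file with one undirected edge per line
#' (\code{id_a id_b weight}).  A line holding a single field declares a node
#' without edges (this is how isolated nodes survive the format; they are
#' kept, never dropped).  Node identifiers are arbitrary strings; internal
#' indices are assigned by first appearance (a deterministic, reproducible
#' order).  Lines starting with \code{#} and blank lines are skipped.
#'
#' @param path path to the edge-list file.
#' @param delimiter field separator; the default splits on any whitespace
#'   run, so both TSV and space-separated files parse.
#' @return A \code{\link{weighted_graph}}.
#' @section Errors: a duplicated unordered pair, a self loop, or a negative
#'   or non-numeric weight aborts with a message naming the offending pair
#'   or line.
#' @export
read_edge_list <- function(path, delimiter = "") {
  if (!file.exists(path)) stop("graph file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(weighted_graph(integer(), integer(), numeric(), n = 0L,
                          node_ids = character()))
  }
  parts <- if (nzchar(delimiter)) strsplit(lines, delimiter, fixed = TRUE)
           else strsplit(trimws(lines), "\\s+")
  nf <- lengths(parts)
  if (any(!nf %in% c(1L, 3L)))
    stop("line ", lineno[which(!nf %in% c(1L, 3L))[1]],
         ": expected 3 fields (id_a, id_b, weight) or 1 (isolated node)")
  edge <- nf == 3L
  a <- vapply(parts[edge], `[[`, "", 1L)
  b <- vapply(parts[edge], `[[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(parts[edge], `[[`, "", 3L)))
  bad <- which(!is.finite(w) | w < 0)
  if (length(bad))
    stop("line ", lineno[edge][bad[1]],
         ": weight must be a finite non-negative number")
  # first-appearance order across declaration and edge lines alike
  occur <- vector("list", length(parts))
  occur[!edge] <- lapply(parts[!edge], `[[`, 1L)
  occur[edge] <- Map(c, a, b)
  ids <- unique(unlist(occur, use.names = FALSE))
  i <- match(a, ids)
  j <- match(b, ids)
  weighted_graph(i, j, w, n = length(ids), node_ids = ids)
}

#' Write a graph as an edge list
#'
#' Emits every node id as a single-field declaration line (in internal
#' index order) followed by the edges, so \code{\link{read_edge_list}}
#' reconstructs the graph exactly — same indices, isolated nodes included.
#'
#' @param graph a \code{\link{weighted_graph}}.
#' @param path output path.
#' @param sep field separator (default tab).
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(graph, path, sep = "\t") {
  ed <- graph_edges(graph)
  o <- order(match(ed$from, graph$node_ids), match(ed$to, graph$node_ids))
  ed <- ed[o, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(graph$node_ids, con)
  if (nrow(ed))
    writeLines(paste(ed$from, ed$to,
                     formatC(ed$weight, digits = 17, format = "g"),
                     sep = sep), con)
  invisible(path)
}

#' Read a weighted graph from Matrix Market coordinate format
#'
#' Accepts \code{symmetric} or \code{general} headers; a general matrix must
#' be numerically symmetric (each entry mirrored exactly).  1-based MTX
#' coordinates become internal indices 1..n; node ids default to
#' \code{"v1" ... "vn"}.
#'
#' @param path path to a \code{.mtx} file.
#' @param node_ids optional character vector of external ids, length n.
#' @return A \code{\link{weighted_graph}}.
#' @section Errors: a nonzero diagonal entry or an asymmetric general matrix
#'   aborts, reporting the first offending entry or pair.
#' @export
read_matrix_market <- function(path, node_ids = NULL) {
  if (!file.exists(path)) stop("graph file not found: ", path)
  M <- methods::as(Matrix::readMM(path), "TsparseMatrix")
  if (nrow(M) != ncol(M)) stop("matrix is not square")
  n <- nrow(M)
  i <- M@i + 1L
  j <- M@j + 1L
  x <- M@x
  nz <- x != 0
  i <- i[nz]; j <- j[nz]; x <- x[nz]
  if (any(i == j)) {
    k <- which(i == j)[1]
    stop("nonzero diagonal entry at (", i[k], ",", i[k], "); self loops forbidden")
  }
  if (methods::is(M, "symmetricMatrix")) {
    # one triangle stored; take entries as-is
    lo <- pmin(i, j); hi <- pmax(i, j)
  } else {
    # general: every entry must have an exact mirror
    key <- paste(i, j)
    mirror <- match(paste(j, i), key)
    if (anyNA(mirror) || any(x != x[mirror])) {
      k <- which(is.na(mirror) | x != x[mirror])[1]
      stop("general matrix is not symmetric: entry (", i[k], ",", j[k],
           ") has no equal mirror entry")
    }
    up <- i < j
    lo <- i[up]; hi <- j[up]; x <- x[up]
  }
  weighted_graph(lo, hi, x, n = n, node_ids = node_ids)
}

#' Write a graph in Matrix Market symmetric coordinate format
#'
#' @param graph a \code{\link{weighted_graph}}.
#' @param path output path (conventionally \code{.mtx}).  External node ids
#'   are not representable in MTX; pass them separately if needed.
#' @return \code{path}, invisibly.
#' @export
write_matrix_market <- function(graph, path) {
  Matrix::writeMM(graph$W, path)
  invisible(path)
}

#' Read node labels
#'
#' Two-column text file: node id and one of \code{+}, \code{-}, \code{?}
#' (\code{?} or absence from the file means unlabeled).  Lines starting with
#' \code{#} are skipped.
#'
#' @param path path to the label file.
#' @param graph the \code{\link{weighted_graph}} the labels refer to.
#' @return A \code{\link{node_labeling}}.
#' @export
read_labels <- function(path, graph) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(node_labeling(graph, integer(), integer()))
  parts <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(parts) != 2L))
    stop("label file must have two fields per line: id, label")
  ids <- vapply(parts, `[[`, "", 1L)
  lab <- vapply(parts, `[[`, "", 2L)
  if (!all(lab %in% c("+", "-", "?")))
    stop("labels must be one of '+', '-', '?'; got '",
         lab[!lab %in% c("+", "-", "?")][1], "'")
  idx <- resolve_ids(graph, ids)
  node_labeling(graph, s_pos = idx[lab == "+"], s_neg = idx[lab == "-"])
}

#' Write node labels
#'
#' @param labeling a \code{\link{node_labeling}}.
#' @param graph the graph the labeling refers to.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_labels <- function(labeling, graph, path) {
  lab <- rep("?", graph$n)
  lab[labeling$s_pos] <- "+"
  lab[labeling$s_neg] <- "-"
  utils::write.table(data.frame(id = graph$node_ids, label = lab),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
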