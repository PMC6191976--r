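#' Precision, recall and F-measure of a predicted positive set
#'
#' \eqn{P = TP/(TP+FP)} (0 when nothing is predicted positive),
#' \eqn{R = TP/(TP+FN)} (0 when there are no true positives), and the
#' F-measure, their harmonic mean (0 when \eqn{P + R = 0}).  With rare
#' positives these are far more informative than the error rate.
#'
#' @param predicted_pos,true_pos vectors (node indices or ids) identifying
#'   predicted and true positives; subsets of \code{universe}.
#' @param universe the evaluation universe (all scored nodes).
#' @return List with \code{precision}, \code{recall}, \code{f_measure},
#'   \code{tp}, \code{fp}, \code{fn}.
#' @export
precision_recall_f <- function(predicted_pos, true_pos, universe) {
  predicted_pos <- unique(predicted_pos)
  true_pos <- unique(true_pos)
  stopifnot(all(predicted_pos %in% universe), all(true_pos %in% universe))
  tp <- length(intersect(predicted_pos, true_pos))
  fp <- length(predicted_pos) - tp
  fn <- length(true_pos) - tp
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f_measure = f, tp = tp, fp = fp, fn = fn)
}

#' Area under the precision–recall curve (average precision)
#'
#' The average-precision formulation used in the CAFA protein-ranking
#' challenges: thresholds sweep the distinct score values in descending
#' order (tied scores form a single step), and the area is
#' \eqn{\sum_t P(t) \, \Delta R(t)} — precision at each threshold times the
#' recall gained there.  Step interpolation, not trapezoidal (the latter
#' inflates PR areas).
#'
#' @param scores named numeric vector of ranking scores (names identify the
#'   nodes), or plain numeric with \code{truth} given positionally.
#' @param true_pos identifiers (or positions) of the true positives; at
#'   least one positive and one negative must be in scope.
#' @return The area, in \eqn{[0, 1]}.
#' @examples
#' auprc(c(a = 0.9, b = 0.8, c = 0.1), true_pos = c("a", "c"))  # 5/6
#' @export
auprc <- function(scores, true_pos) {
  y <- if (!is.null(names(scores))) names(scores) %in% true_pos
       else seq_along(scores) %in% true_pos
  npos <- sum(y)
  nneg <- length(y) - npos
  if (npos == 0 || nneg == 0)
    stop("AUPRC needs at least one positive and one negative in scope")
  o <- order(scores, decreasing = TRUE)
  y <- y[o]
  s <- scores[o]
  # collapse tied scores into single threshold steps
  grp <- cumsum(!duplicated(s))
  tp_g <- as.numeric(rowsum(as.numeric(y), grp))  # groups in ascending order
  n_g <- tabulate(grp)
  tp <- cumsum(tp_g)
  tot <- cumsum(n_g)
  prec <- tp / tot
  rec <- tp / npos
  drec <- diff(c(0, rec))
  sum(prec * drec)
}

#' Stratified cross-validation of the Hopfield classifier
#'
#' Splits positives and negatives independently into \code{folds} folds
#' (stratification keeps the class ratio in every fold); per fold, the
#' fold's labels are hidden (those nodes become \eqn{U}),
#' \code{\link{cosnet_predict}} runs on the rest, and the hidden nodes'
#' predictions are collected.  Metrics are micro-averaged: all held-out
#' decisions and scores are pooled before computing precision, recall, F
#' and AUPRC, so every node is evaluated exactly once.
#'
#' @param graph a \code{\link{weighted_graph}}.
#' @param full_labels a \code{\link{node_labeling}} labeling every node
#'   (\code{U} empty), the ground truth.
#' @param folds number of folds, at least 2 (default 5).
#' @param seed integer seed (fold shuffling and per-fold prediction seeds).
#' @param ... passed to \code{\link{cosnet_predict}}.
#' @return List with \code{precision}, \code{recall}, \code{f_measure},
#'   \code{auprc}, and \code{per_node} (data frame: id, fold, score,
#'   predicted_label, true_label).
#' @export
cross_validate <- function(graph, full_labels, folds = 5L, seed = 1L, ...) {
  stopifnot(folds >= 2L)
  if (length(full_labels$u))
    stop("cross_validate needs a fully labeled ground truth")
  pos <- full_labels$s_pos
  neg <- full_labels$s_neg
  if (!length(pos) || !length(neg)) stop("both classes must be present")
  fold_of <- integer(full_labels$n)
  withr::with_seed(as.integer(seed), {
    fold_of[pos] <- sample(rep_len(seq_len(folds), length(pos)))
    fold_of[neg] <- sample(rep_len(seq_len(folds), length(neg)))
  })
  for (f in seq_len(folds)) {
    hidden <- which(fold_of == f)
    if (!length(setdiff(pos, hidden)) || !length(setdiff(neg, hidden)))
      stop("hiding fold ", f, " leaves a training set without ",
           "positives or negatives; use fewer folds")
  }
  per_fold <- lapply(seq_len(folds), function(f) {
    hidden <- which(fold_of == f)
    if (!length(hidden)) return(NULL)
    lab_f <- node_labeling(graph,
                           s_pos = setdiff(pos, hidden),
                           s_neg = setdiff(neg, hidden))
    pred <- cosnet_predict(graph, lab_f, seed = as.integer(seed) + f, ...)
    tab <- pred$table
    tab$fold <- f
    tab$true_label <- ifelse(resolve_ids(graph, tab$id) %in% pos, "+", "-")
    tab
  })
  all_tab <- do.call(rbind, per_fold)
  pr <- precision_recall_f(all_tab$id[all_tab$predicted_label == "+"],
                           all_tab$id[all_tab$true_label == "+"],
                           universe = all_tab$id)
  scores <- stats::setNames(all_tab$score, all_tab$id)
  ap <- auprc(scores, all_tab$id[all_tab$true_label == "+"])
  list(precision = pr$precision, recall = pr$recall,
       f_measure = pr$f_measure, auprc = ap, per_node = all_tab)
}
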