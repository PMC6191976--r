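#' Weighted label projection of the labeled sub-network
#'
#' For every labeled node \eqn{i \in S}, the pair
#' \eqn{(\Delta^+_i, \Delta^-_i)} of summed connection weights toward
#' labeled positive and labeled negative neighbors.  This two-dimensional
#' projection of the labeled sub-network is what the parameter learning
#' step classifies: a labeled state sits near an energy minimum exactly
#' when each labeled node's field, built from these two sums, agrees with
#' its own label.
#'
#' @param graph a \code{\link{weighted_graph}}.
#' @param labeling a \code{\link{node_labeling}} with nonempty labeled set.
#' @return A data frame with columns \code{node} (internal index, the
#'   labeled set in ascending order), \code{delta_pos}, \code{delta_neg},
#'   \code{label} (\code{+1}/\code{-1}).
#' @export
project_labeled <- function(graph, labeling) {
  s <- sort(labeled_set(labeling))
  if (!length(s)) stop("labeled set S is empty")
  G <- as_general(graph)
  dp <- if (length(labeling$s_pos))
    as.numeric(Matrix::rowSums(G[s, labeling$s_pos, drop = FALSE]))
  else numeric(length(s))
  dn <- if (length(labeling$s_neg))
    as.numeric(Matrix::rowSums(G[s, labeling$s_neg, drop = FALSE]))
  else numeric(length(s))
  data.frame(node = s, delta_pos = dp, delta_neg = dn,
             label = ifelse(s %in% labeling$s_pos, 1L, -1L))
}

#' Learn the activation angle and threshold on the labeled sub-network
#'
#' Grid search for the pair \eqn{(\rho, q)} making the known labels as
#' consistent as possible with the network's fields: labeled node \eqn{i}
#' is scored positive when
#' \eqn{\sin\rho \cdot \Delta^+_i - \cos\rho \cdot \Delta^-_i - q \ge 0},
#' and \eqn{(\rho, q)} is chosen to maximize the F-measure of that
#' classifier on \eqn{S}.  Maximizing F rather than accuracy is the
#' cost-sensitive ingredient: with 1\% positives the all-negative classifier
#' has 99\% accuracy but F = 0.  The grid spans \eqn{\rho \in [0, \pi/2)}
#' (\code{grid_rho} equispaced values, right endpoint excluded) and \eqn{q}
#' over the range of the projected scores (\code{grid_q} values).  Several
#' \eqn{(\rho, q)} typically fit the labeled data equally well; F ties are
#' broken toward the pair with the largest \emph{margin}
#' \eqn{\min_i s_i (z_i - q)} (with \eqn{s_i = \pm 1} the label and
#' \eqn{z_i} the projected score; the coefficient vector
#' \eqn{(\sin\rho, -\cos\rho)} has unit norm, so margins are comparable
#' across \eqn{\rho}).  A large margin places the labeled state deep inside
#' its energy minimum and keeps both activation values bounded away from
#' zero, so neither class is silenced in the subsequent dynamics.
#' Remaining ties resolve to the larger \eqn{\rho}, then the smaller
#' \eqn{|q|}.  The selected \eqn{q} becomes the uniform threshold
#' \eqn{\lambda_i = q}.
#'
#' @param projection output of \code{\link{project_labeled}}.
#' @param labeling the \code{\link{node_labeling}} (both classes must be
#'   present among the labeled nodes).
#' @param grid_rho,grid_q grid resolutions, each at least 2.
#' @return A \code{\link{hopfield_params}} with scalar \code{thresholds}
#'   \eqn{= q}; attribute \code{f_measure} records the achieved F on S.
#' @export
learn_parameters <- function(projection, labeling, grid_rho = 90L,
                             grid_q = 100L) {
  if (!length(labeling$s_pos) || !length(labeling$s_neg))
    stop("cannot learn imbalance parameters without both labeled classes")
  stopifnot(grid_rho >= 2L, grid_q >= 2L)
  ispos <- projection$label > 0
  npos <- sum(ispos)
  rho_grid <- (seq_len(grid_rho) - 1L) / grid_rho * (pi / 2)
  best <- list(f = -Inf, margin = -Inf, rho = NA_real_, q = NA_real_)
  for (rho in rho_grid) {
    z <- sin(rho) * projection$delta_pos - cos(rho) * projection$delta_neg
    q_grid <- seq(min(z), max(z), length.out = grid_q)
    pred <- outer(z, q_grid, `>=`)           # |S| x grid_q
    tp <- colSums(pred & ispos)
    fp <- colSums(pred & !ispos)
    f <- ifelse(tp + fp + npos > 0, 2 * tp / (tp + fp + npos), 0)
    # min_i s_i (z_i - q): worst signed distance of a labeled point
    margin <- pmin(min(z[ispos]) - q_grid, q_grid - max(z[!ispos]))
    # within this rho: best F, then widest margin, then smallest |q|
    o <- order(-f, -margin, abs(q_grid))
    j <- o[1]
    # across rho: F, then margin; remaining ties resolve to the larger rho
    # (rho_grid is ascending, so replacing on ties keeps the last one)
    f_better <- f[j] > best$f + 1e-12
    f_tie <- abs(f[j] - best$f) <= 1e-12
    if (f_better || (f_tie && margin[j] >= best$margin - 1e-12)) {
      best <- list(f = max(f[j], best$f),
                   margin = max(margin[j], best$margin),
                   rho = rho, q = q_grid[j])
    }
  }
  params <- hopfield_params(best$rho, thresholds = best$q)
  attr(params, "f_measure") <- best$f
  params
}

#' Regularize thresholds against the all-negative minimum
#'
#' With rare positives the trivial all-negative state is a deep energy
#' minimum; this step biases every neuron toward the positive state in
#' proportion to the positive prior and the neuron's connectivity:
#' \deqn{\lambda'_i = \lambda_i - \beta \cdot \frac{|S^+|}{|S|} \cdot
#'   \sum_{j \in N(i)} w_{ij}.}
#' \eqn{\beta = 0} leaves the parameters untouched.  After this step the
#' thresholds are per-node.
#'
#' @param params a \code{\link{hopfield_params}}.
#' @param graph the \code{\link{weighted_graph}} (full node set).
#' @param labeling the \code{\link{node_labeling}} giving the positive
#'   prior \eqn{|S^+|/|S|}.
#' @param beta non-negative regularization strength (default 1).
#' @return A \code{\link{hopfield_params}} with per-node thresholds.
#' @export
regularize_thresholds <- function(params, graph, labeling, beta = 1) {
  stopifnot(beta >= 0)
  s_size <- length(labeled_set(labeling))
  if (!s_size) stop("labeled set S is empty")
  prior <- length(labeling$s_pos) / s_size
  lam <- params$thresholds
  if (length(lam) == 1L) lam <- rep(lam, graph$n)
  lam <- lam - beta * prior * unname(graph_degree(graph))
  hopfield_params(params$rho, thresholds = lam)
}

#' Predict unlabeled node labels with the cost-sensitive Hopfield network
#'
#' The full pipeline for one binary class:
#' \enumerate{
#'   \item learn \eqn{(\rho, \lambda)} on the labeled sub-network
#'     (\code{\link{project_labeled}} + \code{\link{learn_parameters}});
#'   \item regularize the thresholds
#'     (\code{\link{regularize_thresholds}}, strength \code{beta});
#'   \item restrict the network to the unlabeled set \eqn{U}, folding each
#'     labeled neighbor's clamped activation into an effective threshold
#'     \eqn{\lambda^{\mathrm{eff}}_u = \lambda'_u - \sum_{j \in S} w_{uj}
#'     x_j} with \eqn{x_j = \sin\rho} for positives, \eqn{-\cos\rho} for
#'     negatives; color the \eqn{U}-subgraph
#'     (\code{\link{greedy_color}}) and run the color-parallel dynamics
#'     (\code{\link{run_colored}}) from the neutral all-zero state to
#'     equilibrium \eqn{\hat x}.
#' }
#' \eqn{U^+ = \{u : \hat x_u = \sin\rho\}}; the ranking score of \eqn{u} is
#' its internal activation \eqn{h_u} at equilibrium (the continuous field,
#' which ranks within each predicted class; its sign matches the
#' bipartition).
#'
#' @param graph a \code{\link{weighted_graph}} (typically degree-normalized).
#' @param labeling a \code{\link{node_labeling}}; both labeled classes must
#'   be present and \eqn{U} may be empty (then no dynamics runs).
#' @param seed integer seed driving the coloring (and class-order shuffle
#'   when \code{shuffle_omega}).
#' @param beta regularization strength (default 1).
#' @param grid_rho,grid_q learning grid resolutions.
#' @param max_sweeps dynamics sweep budget.
#' @param mode \code{"colored"} (default) or \code{"sequential"} — the
#'   latter runs \code{\link{run_async}} under the induced permutation
#'   \eqn{\pi(\omega)} and must give bit-identical results (the package's
#'   central equivalence); exposed as an oracle/debug mode.
#' @param shuffle_omega if \code{TRUE}, process color classes in a seeded
#'   random order instead of extraction order; the order is fixed for the
#'   whole run.
#' @return Object of class \code{cosnet_prediction}: data-frame-like list
#'   with \code{table} (columns \code{id}, \code{score},
#'   \code{predicted_label}, one row per unlabeled node, sorted by id),
#'   \code{u_pos}/\code{u_neg} (internal indices), \code{params},
#'   \code{converged}.
#' @export
cosnet_predict <- function(graph, labeling, seed = 1L, beta = 1,
                           grid_rho = 90L, grid_q = 100L,
                           max_sweeps = 1000L,
                           mode = c("colored", "sequential"),
                           shuffle_omega = FALSE) {
  mode <- match.arg(mode)
  u <- labeling$u
  proj <- project_labeled(graph, labeling)
  params <- learn_parameters(proj, labeling, grid_rho, grid_q)
  params <- regularize_thresholds(params, graph, labeling, beta)
  if (!length(u)) {
    tab <- data.frame(id = character(), score = numeric(),
                      predicted_label = character(),
                      stringsAsFactors = FALSE)
    return(structure(list(table = tab, u_pos = integer(), u_neg = integer(),
                          params = params, converged = TRUE),
                     class = "cosnet_prediction"))
  }
  sub <- induced_subgraph(graph, u)          # W_U, nodes in `u` order
  # clamp labeled neighbors into effective thresholds
  G <- as_general(graph)
  x_clamp <- numeric(graph$n)
  x_clamp[labeling$s_pos] <- params$act_pos
  x_clamp[labeling$s_neg] <- params$act_neg
  field_from_s <- as.numeric(G[u, , drop = FALSE] %*% x_clamp)  # 0 on U
  lam_eff <- params$thresholds[u] - field_from_s
  sub_params <- hopfield_params(params$rho, thresholds = lam_eff)
  part <- greedy_color(sub, seed = seed)
  omega <- seq_len(part$k)
  if (shuffle_omega && part$k > 1L)
    omega <- withr::with_seed(as.integer(seed) + 1L, sample.int(part$k))
  init <- numeric(sub$n)
  res <- withCallingHandlers(
    if (mode == "colored")
      run_colored(sub, sub_params, init, part, omega, max_sweeps)
    else
      run_async(sub, sub_params, init,
                permutation = unlist(part$classes[omega], use.names = FALSE),
                max_sweeps = max_sweeps),
    warning = function(w) {
      warning("dynamics on U did not converge; using state at sweep budget",
              call. = FALSE)
      invokeRestart("muffleWarning")
    }
  )
  xhat <- res$state
  csr <- graph_csr(sub)
  scores <- vapply(seq_len(sub$n), function(i) {
    nb <- csr_neighbors(csr, i)
    sum(nb$w * xhat[nb$nbr])
  }, numeric(1)) - lam_eff
  is_pos <- xhat == sub_params$act_pos
  tab <- data.frame(id = sub$node_ids,
                    score = scores,
                    predicted_label = ifelse(is_pos, "+", "-"),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$id), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 u_pos = u[is_pos], u_neg = u[!is_pos],
                 params = params, converged = res$converged),
            class = "cosnet_prediction")
}

#' @export
print.cosnet_prediction <- function(x, ...) {
  cat("cosnet_prediction:", length(x$u_pos), "positive,",
      length(x$u_neg), "negative of", nrow(x$table), "unlabeled node(s)\n")
  invisible(x)
}

#' Predict several independent classes, optionally in parallel
#'
#' Each binary class is an independent problem over the same graph, so
#' classes may run concurrently; results are identical to sequential
#' execution class by class (each worker gets its own explicit seed and no
#' state is shared).
#'
#' @param graph a \code{\link{weighted_graph}}.
#' @param labelings named list of \code{\link{node_labeling}} objects.
#' @param threads number of worker processes (forked; 1 = sequential).
#' @param ... passed to \code{\link{cosnet_predict}}.
#' @param seed integer; class \code{i} runs with seed \code{seed + i - 1}.
#' @return Named list of \code{cosnet_prediction} objects, in input order.
#' @export
cosnet_predict_many <- function(graph, labelings, threads = 1L, seed = 1L,
                                ...) {
  stopifnot(threads >= 1L)
  run_one <- function(i) cosnet_predict(graph, labelings[[i]],
                                        seed = as.integer(seed) + i - 1L, ...)
  idx <- seq_along(labelings)
  out <- if (threads > 1L && .Platform$OS.type == "unix")
    parallel::mclapply(idx, run_one, mc.cores = threads)
  else
    lapply(idx, run_one)
  names(out) <- names(labelings)
  out
}
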