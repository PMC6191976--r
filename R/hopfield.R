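#' Hopfield network parameters
#'
#' The two-valued activation alphabet is parameterized by an angle
#' \eqn{\rho \in [0, \pi/2)}: a neuron in the positive state takes value
#' \eqn{\sin\rho \in [0, 1)} and in the negative state \eqn{-\cos\rho \in
#' (-1, 0]}.  Decoupling activation values from labels is how the model
#' absorbs class imbalance: with rare positives, a small \eqn{|-\cos\rho|}
#' or large \eqn{\sin\rho} rebalances the influence of the two classes on
#' each neuron's input field.  \code{thresholds} is the per-neuron
#' activation threshold \eqn{\lambda_i}.
#'
#' @param rho angle in \eqn{[0, \pi/2)}.
#' @param thresholds numeric vector (recycled to length \code{n} by callers
#'   that know the graph) of finite thresholds.
#' @return Object of class \code{hopfield_params}: \code{rho},
#'   \code{thresholds}, \code{act_pos} (\eqn{\sin\rho}), \code{act_neg}
#'   (\eqn{-\cos\rho}).
#' @export
hopfield_params <- function(rho, thresholds) {
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho >= pi / 2)
    stop("rho must lie in [0, pi/2)")
  if (any(!is.finite(thresholds))) stop("thresholds must be finite")
  structure(list(rho = rho, thresholds = as.numeric(thresholds),
                 act_pos = sin(rho), act_neg = -cos(rho)),
            class = "hopfield_params")
}

#' @export
print.hopfield_params <- function(x, ...) {
  cat(sprintf("hopfield_params: rho = %.4f (states %+0.4f / %+0.4f), %d threshold(s)\n",
              x$rho, x$act_pos, x$act_neg, length(x$thresholds)))
  invisible(x)
}

check_state <- function(graph, params, x) {
  if (length(x) != graph$n)
    stop("state length ", length(x), " does not match graph size ", graph$n)
  if (length(params$thresholds) == 1L)
    params$thresholds <- rep(params$thresholds, graph$n)
  if (length(params$thresholds) != graph$n)
    stop("thresholds length does not match graph size")
  params
}

#' Network energy
#'
#' The quadratic Lyapunov function
#' \deqn{E(x) = -\tfrac12 x^\top W x + x^\top \lambda,}
#' evaluated by sparse traversal (each undirected edge contributes
#' \eqn{-w_{ij} x_i x_j} once).  Non-increasing along asynchronous and
#' color-parallel trajectories, which is what guarantees convergence to a
#' fixed point.
#'
#' @param graph a \code{\link{weighted_graph}} (weights symmetric, zero
#'   diagonal).
#' @param params a \code{\link{hopfield_params}} supplying \eqn{\lambda}.
#' @param state numeric activation vector of length \code{n}.
#' @return The scalar energy.
#' @export
hopfield_energy <- function(graph, params, state) {
  params <- check_state(graph, params, state)
  Wt <- methods::as(graph$W, "TsparseMatrix")
  quad <- sum(Wt@x * state[Wt@i + 1L] * state[Wt@j + 1L])  # each edge once
  -quad + sum(state * params$thresholds)
}

#' Internal activation (input field) of one neuron
#'
#' \eqn{h_u = \sum_{v \in N(u)} w_{uv} x_v - \lambda_u} against the current
#' state vector.  The sequential dynamics' already-updated/not-yet-updated
#' split is realized by the caller updating the state in place between
#' calls.
#'
#' @inheritParams hopfield_energy
#' @param u node index.
#' @return Scalar field value.
#' @export
internal_activation <- function(graph, params, state, u) {
  params <- check_state(graph, params, state)
  nb <- csr_neighbors(graph_csr(graph), u)
  sum(nb$w * state[nb$nbr]) - params$thresholds[u]
}

new_dynamics_result <- function(state, energy_trace, sweeps, converged,
                                period = NA_integer_) {
  structure(list(state = state, energy_trace = energy_trace,
                 sweeps = sweeps, converged = converged, period = period),
            class = "hopfield_dynamics")
}

#' @export
print.hopfield_dynamics <- function(x, ...) {
  cat("hopfield_dynamics:", x$sweeps, "sweep(s),",
      if (isTRUE(x$converged)) "converged" else "NOT converged",
      if (!is.na(x$period)) paste0("(period ", x$period, ")") else "", "\n")
  invisible(x)
}

#' Sequential asynchronous dynamics
#'
#' Updates one neuron at a time, in place, in \code{permutation} order:
#' \eqn{x_u \leftarrow \sin\rho} if \eqn{h_u \ge 0}, else \eqn{-\cos\rho}
#' (the tie \eqn{h_u = 0} goes to the positive state).  Full sweeps over the
#' permutation repeat until a sweep changes no component (convergence to a
#' fixed point, guaranteed for symmetric weights by the energy function) or
#' \code{max_sweeps} is reached, in which case the result is flagged
#' not-converged with a warning rather than an error.
#'
#' Initial components may be 0 (the neutral third initial value); they
#' contribute nothing to neighbors' fields until first updated, after which
#' every component lies in \{\eqn{\sin\rho}, \eqn{-\cos\rho}\}.
#'
#' @inheritParams hopfield_energy
#' @param init numeric initial state; entries in
#'   \{\eqn{\sin\rho}, \eqn{-\cos\rho}, 0\}.
#' @param permutation a permutation of \code{1:n} giving the update order.
#' @param max_sweeps sweep budget (default 1000).
#' @return A \code{hopfield_dynamics} object: final \code{state},
#'   per-sweep \code{energy_trace} (starting at the initial state's energy),
#'   \code{sweeps}, \code{converged}.
#' @export
run_async <- function(graph, params, init, permutation = seq_len(graph$n),
                      max_sweeps = 1000L) {
  params <- check_state(graph, params, init)
  if (length(permutation) != graph$n || anyDuplicated(permutation) ||
      !all(sort(permutation) == seq_len(graph$n)))
    stop("permutation must be a permutation of 1..n")
  csr <- graph_csr(graph)
  x <- as.numeric(init)
  lam <- params$thresholds
  pos <- params$act_pos; neg <- params$act_neg
  trace <- hopfield_energy(graph, params, x)
  converged <- FALSE
  sweeps <- 0L
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    changed <- FALSE
    for (u in permutation) {
      nb <- csr_neighbors(csr, u)
      h <- sum(nb$w * x[nb$nbr]) - lam[u]
      xu <- if (h >= 0) pos else neg
      if (xu != x[u]) {
        x[u] <- xu
        changed <- TRUE
      }
    }
    trace <- c(trace, hopfield_energy(graph, params, x))
    if (!changed) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("asynchronous dynamics did not converge within ", max_sweeps,
            " sweeps")
  new_dynamics_result(x, trace, sweeps, converged)
}

#' Color-parallel dynamics
#'
#' The partially-parallel update: all nodes of one color class are updated
#' simultaneously from the same snapshot, and classes are processed
#' sequentially in the order given by \code{omega}.  Because a class is an
#' independent set (no intra-class edges), the simultaneous class update is
#' equivalent to updating its members one at a time, so the trajectory —
#' sweep by sweep — equals \code{\link{run_async}} under the induced
#' permutation \eqn{\pi(\omega)} = classes \eqn{\omega(1), \ldots,
#' \omega(k)} concatenated (ascending node index within each class).  This
#' is the equivalence that lets the dynamics run in parallel while keeping
#' the sequential attractor.
#'
#' @inheritParams run_async
#' @param partition a \code{coloring_partition} covering \code{1:n}; it is
#'   validated with \code{\link{verify_coloring}} before any update.
#' @param omega permutation of \code{1:k} fixing the class processing order
#'   for the whole run (default identity).
#' @return A \code{hopfield_dynamics} object.
#' @export
run_colored <- function(graph, params, init, partition,
                        omega = seq_len(partition$k), max_sweeps = 1000L) {
  params <- check_state(graph, params, init)
  chk <- verify_coloring(graph, partition)
  if (!chk$ok) stop("improper partition: ", chk$violation)
  covered <- sort(unlist(partition$classes, use.names = FALSE))
  if (!identical(covered, seq_len(graph$n)))
    stop("partition must cover exactly the graph's node set")
  if (length(omega) != partition$k ||
      !all(sort(omega) == seq_len(partition$k)))
    stop("omega must be a permutation of 1..k")
  csr <- graph_csr(graph)
  x <- as.numeric(init)
  lam <- params$thresholds
  pos <- params$act_pos; neg <- params$act_neg
  trace <- hopfield_energy(graph, params, x)
  converged <- FALSE
  sweeps <- 0L
  classes <- partition$classes[omega]
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    changed <- FALSE
    for (cls in classes) {
      # no intra-class edges: the in-place current state IS the class
      # snapshot, and the per-node kernel matches run_async exactly
      h <- vapply(cls, function(u) {
        nb <- csr_neighbors(csr, u)
        sum(nb$w * x[nb$nbr])
      }, numeric(1)) - lam[cls]
      xc <- ifelse(h >= 0, pos, neg)
      if (any(xc != x[cls])) changed <- TRUE
      x[cls] <- xc
    }
    trace <- c(trace, hopfield_energy(graph, params, x))
    if (!changed) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("color-parallel dynamics did not converge within ", max_sweeps,
            " sweeps")
  new_dynamics_result(x, trace, sweeps, converged)
}

#' Fully synchronous dynamics with cycle detection
#'
#' Updates all neurons simultaneously each iteration from the previous
#' state.  With a symmetric weight matrix this mode does not in general
#' reach a fixed point; it converges to a limit cycle of period at most 2.
#' Iteration stops when a previously visited state recurs; \code{period} is
#' the gap to the first visit of the recurring state.
#'
#' @inheritParams run_async
#' @param max_iters iteration budget.
#' @return A \code{hopfield_dynamics} object with \code{period} set
#'   (\code{NA} if \code{max_iters} was exhausted without recurrence, in
#'   which case \code{converged} is \code{FALSE}).
#' @export
run_synchronous <- function(graph, params, init, max_iters = 1000L) {
  params <- check_state(graph, params, init)
  G <- as_general(graph)
  lam <- params$thresholds
  pos <- params$act_pos; neg <- params$act_neg
  x <- as.numeric(init)
  state_key <- function(x) paste(ifelse(x == pos, "p", ifelse(x == neg, "n", "z")),
                                 collapse = "")
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(state_key(x), 0L, envir = seen)
  trace <- hopfield_energy(graph, params, x)
  for (it in seq_len(max_iters)) {
    h <- as.numeric(G %*% x) - lam
    x <- ifelse(h >= 0, pos, neg)
    trace <- c(trace, hopfield_energy(graph, params, x))
    key <- state_key(x)
    prev <- get0(key, envir = seen)
    if (!is.null(prev)) {
      return(new_dynamics_result(x, trace, it, TRUE, period = it - prev))
    }
    assign(key, it, envir = seen)
  }
  warning("synchronous dynamics found no recurrent state within ",
          max_iters, " iterations")
  new_dynamics_result(x, trace, max_iters, FALSE, period = NA_integer_)
}
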