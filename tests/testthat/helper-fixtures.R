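# Small graphs built in code, plus independent dense-matrix oracles.

path3 <- function() weighted_graph(c(1, 2), c(2, 3), c(1, 1), n = 3,
                                   node_ids = c("a", "b", "c"))

triangle <- function(w = c(1, 1, 1))
  weighted_graph(c(1, 1, 2), c(2, 3, 3), w, n = 3,
                 node_ids = c("a", "b", "c"))

cycle4 <- function(w = rep(1, 4))
  weighted_graph(c(1, 2, 3, 4), c(2, 3, 4, 1), w, n = 4)

# dense random symmetric graph -> weighted_graph (for oracle comparisons)
random_graph <- function(n, p, seed) {
  withr::with_seed(seed, {
    A <- matrix(0, n, n)
    up <- upper.tri(A)
    on <- up & matrix(runif(n * n) < p, n, n)
    A[on] <- runif(sum(on))
    A <- A + t(A)
    graph_from_dense(A)
  })
}

graph_from_dense <- function(A) {
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  weighted_graph(idx[, 1], idx[, 2], A[idx], n = nrow(A))
}

# Independent oracle: energy from the dense quadratic form
dense_energy <- function(A, lambda, x) -0.5 * drop(t(x) %*% A %*% x) + sum(x * lambda)

# Independent oracle: symmetric degree normalization on a dense matrix
dense_normalize <- function(A) {
  d <- rowSums(A)
  s <- ifelse(d > 0, 1 / sqrt(d), 0)
  diag(s) %*% A %*% diag(s)
}

# Independent oracle: exhaustive step-interpolated AUPRC (average precision),
# sweeping every distinct score as a threshold.
brute_auprc <- function(scores, y) {
  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(y)
  area <- 0
  prev_rec <- 0
  for (t in thr) {
    sel <- scores >= t
    prec <- sum(y[sel]) / sum(sel)
    rec <- sum(y[sel]) / npos
    area <- area + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  area
}

# All maximal independent sets of a small graph, by enumeration
all_mis <- function(g) {
  n <- graph_n(g)
  A <- as_dense(g) != 0
  subsets <- lapply(0:(2^n - 1), function(m) which(bitwAnd(m, 2^(0:(n - 1))) > 0))
  indep <- Filter(function(s) length(s) < 2 || !any(A[s, s]), subsets)
  Filter(function(s) {
    outside <- setdiff(seq_len(n), s)
    all(vapply(outside, function(v) any(A[v, s]), logical(1)))
  }, indep)
}

expect_same_run <- function(rc, ra) {
  expect_identical(rc$state, ra$state)
  expect_identical(rc$energy_trace, ra$energy_trace)
  expect_identical(rc$sweeps, ra$sweeps)
}
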