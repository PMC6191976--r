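test_that("energy matches hand values and the dense quadratic-form oracle", {
  two <- weighted_graph(1, 2, 1, n = 2)
  p <- hopfield_params(pi / 4, thresholds = 0)
  expect_equal(hopfield_energy(two, p, c(0, 0)), 0)
  s <- sin(pi / 4)
  expect_equal(hopfield_energy(two, p, c(s, s)), -0.5)

  for (seed in 1:5) {
    g <- random_graph(20, 0.3, seed = seed)
    lam <- withr::with_seed(seed, runif(20, -1, 1))
    pp <- hopfield_params(0.9, lam)
    x <- withr::with_seed(seed + 50,
                          sample(c(pp$act_pos, pp$act_neg), 20, replace = TRUE))
    expect_equal(hopfield_energy(g, pp, x),
                 dense_energy(as_dense(g), lam, x), tolerance = 1e-12)
  }
  expect_error(hopfield_energy(two, p, c(0, 0, 0)), "does not match")
})

test_that("internal activation is the weighted field minus the threshold", {
  # symmetric +/- neighborhood cancels exactly at rho = pi/4
  g <- weighted_graph(c(1, 1), c(2, 3), c(0.5, 0.5), n = 3)
  p <- hopfield_params(pi / 4, thresholds = c(0, 0, 0))
  x <- c(0, sin(pi / 4), -cos(pi / 4))
  expect_equal(internal_activation(g, p, x, 1), 0)

  iso <- weighted_graph(integer(), integer(), numeric(), n = 1)
  expect_equal(internal_activation(iso, hopfield_params(0.3, 0.3), 0, 1), -0.3)

  for (seed in 1:5) {
    g <- random_graph(15, 0.4, seed = seed + 10)
    lam <- withr::with_seed(seed, runif(15, -1, 1))
    pp <- hopfield_params(1.1, lam)
    x <- withr::with_seed(seed, runif(15, -1, 1))
    u <- (seed %% 15) + 1
    expect_equal(internal_activation(g, pp, x, u),
                 drop(as_dense(g)[u, ] %*% x) - lam[u], tolerance = 1e-12)
  }
})

test_that("hopfield_params validates rho and exposes the activation pair", {
  p <- hopfield_params(0.6, 0)
  expect_equal(p$act_pos, sin(0.6))
  expect_equal(p$act_neg, -cos(0.6))
  expect_error(hopfield_params(pi / 2, 0), "pi/2")
  expect_error(hopfield_params(-0.1, 0), "pi/2")
  expect_error(hopfield_params(0.5, c(1, NaN)), "finite")
})

test_that("asynchronous dynamics honors the stated single-step examples", {
  # a fixed point stays fixed in one sweep
  g <- cycle4()
  p <- hopfield_params(pi / 4, thresholds = rep(0, 4))
  neg <- rep(-cos(pi / 4), 4)
  r <- run_async(g, p, neg)
  expect_true(r$converged)
  expect_equal(r$sweeps, 1)
  expect_identical(r$state, neg)      # every field is -sqrt(2) < 0

  # single node: h = -lambda = 0.1 >= 0 -> positive state
  iso <- weighted_graph(integer(), integer(), numeric(), n = 1)
  ps <- hopfield_params(0.7, thresholds = -0.1)
  r1 <- run_async(iso, ps, 0)
  expect_equal(r1$state, sin(0.7))

  # tie h = 0 resolves to the positive state
  pz <- hopfield_params(0.7, thresholds = 0)
  expect_equal(run_async(iso, pz, 0)$state, sin(0.7))

  expect_error(run_async(g, p, neg, permutation = c(1, 1, 2, 3)),
               "permutation")
})

test_that("max_sweeps exhaustion flags non-convergence without error", {
  # two nodes with a negative-feedback threshold pattern cannot settle in 0 sweeps
  g <- weighted_graph(1, 2, 1, n = 2)
  p <- hopfield_params(pi / 4, thresholds = c(0, 0))
  expect_warning(r <- run_async(g, p, c(0, 0), max_sweeps = 0),
                 "did not converge")
  expect_false(r$converged)
  expect_equal(r$sweeps, 0)
})

test_that("energy is non-increasing and flips obey dE = -(x'-x) h", {
  for (seed in 1:10) {
    g <- random_graph(25, 0.2, seed = seed + 70)
    lam <- withr::with_seed(seed, runif(25, -0.5, 0.5))
    p <- hopfield_params(withr::with_seed(seed, runif(1, 0, pi / 2 - 0.01)), lam)
    init <- withr::with_seed(seed + 1,
                             sample(c(p$act_pos, p$act_neg, 0), 25, replace = TRUE))
    r <- run_async(g, p, init)
    expect_true(r$converged)
    expect_true(all(diff(r$energy_trace) <= 1e-9))

    # replay the first sweep manually: each accepted flip lowers energy by
    # exactly (x_new - x_old) * h (up to fp tolerance), and h drives the sign
    x <- init
    for (u in 1:25) {
      h <- internal_activation(g, p, x, u)
      xn <- if (h >= 0) p$act_pos else p$act_neg
      e_before <- hopfield_energy(g, p, x)
      x_old <- x[u]
      x[u] <- xn
      e_after <- hopfield_energy(g, p, x)
      expect_equal(e_after - e_before, -(xn - x_old) * h, tolerance = 1e-9)
      expect_lte(e_after - e_before, 1e-9)
    }
  }
})

test_that("converged states are single-flip local minima of the energy", {
  for (seed in 1:10) {
    g <- random_graph(20, 0.25, seed = seed + 90)
    lam <- withr::with_seed(seed, runif(20, -0.5, 0.5))
    p <- hopfield_params(1.0, lam)
    init <- withr::with_seed(seed,
                             sample(c(p$act_pos, p$act_neg), 20, replace = TRUE))
    r <- run_async(g, p, init)
    e_hat <- hopfield_energy(g, p, r$state)
    for (u in 1:20) {
      flipped <- r$state
      flipped[u] <- if (flipped[u] == p$act_pos) p$act_neg else p$act_pos
      expect_gte(hopfield_energy(g, p, flipped), e_hat - 1e-9)
    }
  }
})

test_that("colored dynamics equals sequential dynamics under pi(omega)", {
  # hand case: 4-cycle with classes {1,3}, {2,4}
  g <- cycle4(w = c(0.9, 0.4, 0.7, 0.2))
  p <- hopfield_params(0.8, thresholds = c(0.1, -0.2, 0.3, 0))
  part <- structure(list(classes = list(c(1L, 3L), c(2L, 4L)), k = 2L,
                         ordering = c(1L, 3L, 2L, 4L)),
                    class = "coloring_partition")
  init <- c(0, 0, 0, 0)
  rc <- run_colored(g, p, init, part)
  ra <- run_async(g, p, init, permutation = c(1L, 3L, 2L, 4L))
  expect_same_run(rc, ra)

  # degenerate partition: k = n singletons under omega is exactly run_async
  singles <- structure(list(classes = as.list(1:4), k = 4L, ordering = 1:4),
                       class = "coloring_partition")
  om <- c(3L, 1L, 4L, 2L)
  rc2 <- run_colored(g, p, init, singles, omega = om)
  ra2 <- run_async(g, p, init, permutation = om)
  expect_same_run(rc2, ra2)

  # random instances, random seeds and omega
  for (seed in 1:25) {
    ge <- generate_erdos(60, sigma = 6, seed = seed)
    lam <- withr::with_seed(seed, runif(60, -0.4, 0.4))
    pp <- hopfield_params(withr::with_seed(seed + 1, runif(1, 0, 1.5)), lam)
    init <- withr::with_seed(seed + 2,
                             sample(c(pp$act_pos, pp$act_neg, 0), 60, replace = TRUE))
    pc <- greedy_color(ge, seed = seed)
    omg <- withr::with_seed(seed + 3, sample.int(pc$k))
    rc <- run_colored(ge, pp, init, pc, omega = omg)
    ra <- run_async(ge, pp, init,
                    permutation = unlist(pc$classes[omg], use.names = FALSE))
    expect_same_run(rc, ra)
  }
})

test_that("permuting nodes inside one color class leaves the run unchanged", {
  ge <- generate_erdos(40, sigma = 5, seed = 17)
  p <- hopfield_params(0.9, withr::with_seed(17, runif(40, -0.3, 0.3)))
  pc <- greedy_color(ge, seed = 17)
  init <- numeric(40)
  base <- run_colored(ge, p, init, pc)
  # run sequentially with a class internally shuffled: attractor identical
  perm <- unlist(lapply(pc$classes, function(cl)
    withr::with_seed(99, cl[sample.int(length(cl))])), use.names = FALSE)
  shuf <- run_async(ge, p, init, permutation = perm)
  expect_identical(base$state, shuf$state)
})

test_that("run_colored rejects improper or incomplete partitions", {
  g <- path3()
  p <- hopfield_params(0.5, rep(0, 3))
  bad <- structure(list(classes = list(c(1L, 2L), 3L), k = 2L, ordering = 1:3),
                   class = "coloring_partition")
  expect_error(run_colored(g, p, numeric(3), bad), "improper")
  partial <- structure(list(classes = list(c(1L, 3L)), k = 1L,
                            ordering = c(1L, 3L)),
                       class = "coloring_partition")
  expect_error(run_colored(g, p, numeric(3), partial), "cover")
  ok <- greedy_color(g, seed = 1)
  expect_error(run_colored(g, p, numeric(3), ok, omega = rep(1L, ok$k)),
               "omega")
})

test_that("synchronous mode reaches a cycle of period at most 2", {
  # fixed point init: period 1
  g <- cycle4()
  p <- hopfield_params(pi / 4, rep(0, 4))
  r <- run_synchronous(g, p, rep(-cos(pi / 4), 4))
  expect_equal(r$period, 1)

  # two mutually coupled nodes started antisymmetrically swap forever
  two <- weighted_graph(1, 2, 1, n = 2)
  p2 <- hopfield_params(pi / 4, c(0, 0))
  r2 <- run_synchronous(two, p2, c(sin(pi / 4), -cos(pi / 4)))
  expect_equal(r2$period, 2)

  for (seed in 1:50) {
    ge <- generate_erdos(30, p = 0.2, seed = seed)
    lam <- withr::with_seed(seed, runif(30, -0.5, 0.5))
    pp <- hopfield_params(pi / 4, lam)
    init <- withr::with_seed(seed + 7,
                             sample(c(pp$act_pos, pp$act_neg), 30, replace = TRUE))
    rs <- run_synchronous(ge, pp, init)
    expect_true(rs$converged)
    expect_lte(rs$period, 2)
  }
})
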