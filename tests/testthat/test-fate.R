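test_that("harmonic potential solves the path toy and respects boundaries", {
  g <- path_graph(3)
  pot <- solve_potential(g, sources = 1, sinks = list(end = 3))
  expect_equal(unname(pot$V), c(1, 0.5, 0), tolerance = 1e-12)
  expect_lt(pot$residual, 1e-10)
})

test_that("harmonic potential obeys the maximum principle on random graphs", {
  for (seed in 1:5) {
    set.seed(seed)
    pts <- matrix(rnorm(25 * 2), 25, 2)
    g <- connect_components(knn_graph(pts, 3))
    pot <- solve_potential(g, sources = 1:2, sinks = list(f = 24:25))
    expect_equal(unname(pot$V[1:2]), c(1, 1))
    expect_equal(unname(pot$V[24:25]), c(0, 0))
    interior <- 3:23
    expect_true(all(pot$V[interior] >= -1e-12 & pot$V[interior] <= 1 + 1e-12))
    # V(i) is the probability of hitting a source before a sink, so it is
    # strictly positive iff i reaches a source with sinks deleted, and
    # strictly below 1 iff i reaches a sink with sources deleted
    reaches <- function(avoid, targets) {
      A2 <- as.matrix(g$adjacency)
      A2[avoid, ] <- 0; A2[, avoid] <- 0
      ig <- igraph::graph_from_adjacency_matrix(A2, mode = "undirected",
                                                weighted = TRUE)
      comp <- igraph::components(ig)$membership
      comp[interior] %in% comp[targets]
    }
    pos <- reaches(avoid = 24:25, targets = 1:2)
    sub1 <- reaches(avoid = 1:2, targets = 24:25)
    expect_true(all(pot$V[interior[pos]] > 0))
    expect_true(all(pot$V[interior[sub1]] < 1))
    expect_true(all(pot$V[interior[!pos]] == 0))
    expect_lt(pot$residual, 1e-10)
  }
})

test_that("solve_potential validates sources, sinks and connectivity", {
  g <- path_graph(4)
  expect_error(solve_potential(g, 1, list(f = 1)), "overlap")
  W <- matrix(0, 5, 5)
  W[1, 2] <- W[2, 1] <- 1   # node 3,4,5 disconnected from boundary
  W[3, 4] <- W[4, 3] <- 1; W[4, 5] <- W[5, 4] <- 1
  expect_error(solve_potential(graph_from_weights(W), 1, list(f = 2)),
               "disconnected")
})

test_that("build_chain produces Boltzmann rows with absorbing sinks", {
  g <- path_graph(3)
  pot <- solve_potential(g, 1, list(end = 3))
  # beta = 0: uniform over closed neighborhood
  ch0 <- build_chain(g, pot, beta = 0)
  expect_equal(as.numeric(ch0$P[2, ]), rep(1 / 3, 3))
  # large beta: from the middle, all mass goes downhill
  chL <- build_chain(g, pot, beta = 1e6)
  expect_equal(as.numeric(chL$P[2, 3]), 1, tolerance = 1e-12)
  # sinks are absorbing; sources still move
  expect_equal(as.numeric(chL$P[3, ]), c(0, 0, 1))
  expect_error(build_chain(g, pot, beta = -1), "nonnegative")

  # 4-node toy vs a hand-computed softmax
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 1
  W[2, 4] <- W[4, 2] <- 1
  gg <- graph_from_weights(W)
  pot2 <- structure(list(V = c(1, 0.6, 0, 0.9),
                         sources = 1L, sinks = list(f = 3L), residual = 0),
                    class = "potential_field")
  ch <- build_chain(gg, pot2, beta = 1)
  dV <- c(1, 0.6, 0, 0.9) - 0.6          # from node 2 over {1,2,3,4}
  p_hand <- exp(-dV) / sum(exp(-dV))
  expect_equal(as.numeric(ch$P[2, ]), p_hand, tolerance = 1e-12)
})

test_that("every chain row is stochastic to 1e-12", {
  for (seed in 1:5) {
    toy <- random_toy_chain(n = 25, beta = 3, seed = seed)
    expect_lt(max(abs(Matrix::rowSums(toy$chain$P) - 1)), 1e-12)
    P <- as.matrix(toy$chain$P)
    A <- as.matrix(toy$graph$adjacency) > 0
    diag(A) <- TRUE
    expect_true(all(P[!A] == 0))
  }
})

test_that("walk ensembles are reproducible and respect chain support", {
  toy <- random_toy_chain(n = 20, beta = 2, seed = 3)
  e1 <- simulate_walks(toy$chain, toy$transient, 200, seed = 5)
  e2 <- simulate_walks(toy$chain, toy$transient, 200, seed = 5)
  expect_identical(e1$paths, e2$paths)
  expect_identical(e1$fate, e2$fate)
  e3 <- simulate_walks(toy$chain, toy$transient, 200, seed = 6)
  expect_false(identical(e1$paths, e3$paths))
  # consecutive states are supported transitions; absorbed walks end in
  # their fate's sink set
  P <- as.matrix(toy$chain$P)
  sinks <- toy$potential$sinks
  for (w in sample(200, 20)) {
    path <- e1$paths[[w]]
    steps <- cbind(path[-length(path)], path[-1])
    expect_true(all(P[steps] > 0))
    f <- e1$fate[w]
    if (!is.na(f))
      expect_true(path[length(path)] %in% sinks[[as.character(f)]])
  }
})

test_that("a single reachable sink absorbs every walk", {
  g <- path_graph(5)
  pot <- solve_potential(g, 1, list(end = 5))
  ch <- build_chain(g, pot, beta = 2)
  ens <- simulate_walks(ch, 1:4, 500, max_steps = 10000, seed = 1)
  expect_true(all(!is.na(ens$fate)))
  # near-deterministic chain: walks go straight downhill
  chd <- build_chain(g, pot, beta = 1e6)
  ensd <- simulate_walks(chd, 1, 10, seed = 1)
  expect_true(all(vapply(ensd$paths, identical, logical(1), y = 1:5)))
})

test_that("absorption_exact solves sinks one-hot and symmetric splits", {
  # symmetric 3-node path, sinks at both ends, beta = 0
  g <- path_graph(3)
  pot <- structure(list(V = c(0, 1, 0), sources = 2L,
                        sinks = list(L = 1L, R = 3L), residual = 0),
                   class = "potential_field")
  ch <- build_chain(g, pot, beta = 0)
  B <- absorption_exact(ch)
  expect_equal(unname(B[2, ]), c(0.5, 0.5))
  expect_equal(unname(B[1, ]), c(1, 0))
  expect_equal(unname(B[3, ]), c(0, 1))
  expect_equal(unname(rowSums(B)), rep(1, 3), tolerance = 1e-10)
})

test_that("absorption_exact names unreachable transient cells", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 1
  g <- graph_from_weights(W)
  pot <- structure(list(V = c(1, 0, 0.5, 0.5), sources = 1L,
                        sinks = list(f = 2L), residual = 0),
                   class = "potential_field")
  ch <- build_chain(g, pot, beta = 1)
  expect_error(absorption_exact(ch), "cannot reach")
})

test_that("empirical fate frequencies agree with the exact solver", {
  toy <- random_toy_chain(n = 25, beta = 2, seed = 8)
  B <- absorption_exact(toy$chain)
  n_walks <- 20000
  ens <- simulate_walks(toy$chain, toy$transient, n_walks,
                        max_steps = 5000, seed = 2, keep_paths = FALSE)
  expect_true(all(!is.na(ens$fate)))
  p_exact <- colMeans(B[toy$transient, , drop = FALSE])
  p_emp <- as.numeric(table(ens$fate) / n_walks)
  se <- sqrt(p_exact * (1 - p_exact) / n_walks)
  expect_true(all(abs(p_emp - p_exact) <= 3 * se))
})

test_that("the visiting-walk estimator matches exact probabilities", {
  toy <- random_toy_chain(n = 15, beta = 2, seed = 4)
  B <- absorption_exact(toy$chain)
  ens <- simulate_walks(toy$chain, toy$transient, 30000,
                        max_steps = 5000, seed = 3)
  F <- fate_from_ensemble(ens, min_visits = 50)
  vis <- attr(F, "n_visits")
  for (i in toy$transient) {
    if (vis[i] < 50) next
    se <- sqrt(pmax(B[i, ] * (1 - B[i, ]), 1e-12) / vis[i])
    expect_true(all(abs(F[i, ] - B[i, ]) <= 3 * se + 1e-9))
  }
  # sink cells visited by walks are one-hot for their own fate
  sA <- toy$potential$sinks$A[1]
  if (vis[sA] > 0) expect_equal(unname(F[sA, ]), c(1, 0))
})

test_that("unvisited cells are flagged undefined, not zero", {
  g <- path_graph(4)
  pot <- solve_potential(g, 1, list(end = 4))
  ch <- build_chain(g, pot, beta = 1e6)  # deterministic downhill
  ens <- simulate_walks(ch, 2, 50, seed = 1)
  F <- fate_from_ensemble(ens, min_visits = 5)
  expect_true(all(is.na(F[1, ])))       # cell 1 never visited
  expect_equal(unname(F[2, "end"]), 1)
})

test_that("trajectory profiles average per-cell values over walk position", {
  toy <- random_toy_chain(n = 25, beta = 3, seed = 9)
  ens <- simulate_walks(toy$chain, toy$transient, 2000,
                        max_steps = 5000, seed = 4)
  # constant value: flat profile at that constant
  pc <- trajectory_profile(ens, rep(2.5, 25), "A", n_grid = 20)
  expect_equal(pc$mean, rep(2.5, 20), tolerance = 1e-12)
  # the potential itself: expected drop along absorbing walks
  pv <- trajectory_profile(ens, toy$potential$V, "A", n_grid = 20)
  expect_lt(pv$mean[20], pv$mean[1])
  expect_lt(mean(diff(pv$mean) > 0), 0.35)  # mostly decreasing bins
  expect_error(trajectory_profile(ens, rep(1, 25), "A", min_walks = 1e6),
               "absorbed")
})

test_that("increasing beta increases the mean per-step potential drop", {
  toy <- random_toy_chain(n = 30, beta = 1, seed = 10)
  drop_for <- function(beta) {
    ch <- build_chain(toy$graph, toy$potential, beta = beta)
    P <- as.matrix(ch$P)
    V <- toy$potential$V
    trans <- which(ch$fate_id == 0)
    mean(vapply(trans, function(i) sum(P[i, ] * (V[i] - V)), numeric(1)))
  }
  drops <- vapply(c(0, 2, 8, 32), drop_for, numeric(1))
  expect_true(all(diff(drops) > 0))
})

test_that("pseudotime_potential builds a monotone field", {
  pt <- c(0, 1, 2, 4, Inf)
  pot <- pseudotime_potential(pt, sources = 1, sinks = list(f = 4L))
  expect_equal(unname(pot$V), c(1, 0.75, 0.5, 0, 0))
  expect_s3_class(pot, "potential_field")
})
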