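test_that("select_hvg ranks by binned dispersion and shuns constant genes", {
  set.seed(1)
  n <- 40
  E <- rbind(flat = rep(3, n),
             lowvar = 3 + rnorm(n, sd = 0.1),
             hivar = 3 + rnorm(n, sd = 3))
  E <- pmax(E, 0)
  sce <- make_sce(E, log_layer = FALSE)
  expect_equal(select_hvg(sce, 2, n_bins = 1), c("hivar", "lowvar"))
  # a constant gene is never chosen over a gene with positive variance
  expect_false("flat" %in% select_hvg(sce, 2, n_bins = 1))
  expect_setequal(select_hvg(sce, 3, n_bins = 1), rownames(E))
  expect_error(select_hvg(sce, 10), "exceeds")
})

test_that("pca_embed matches a direct eigendecomposition oracle", {
  set.seed(2)
  X <- matrix(rnorm(12), 4, 3)  # 4 cells x 3 features
  p <- pca_embed(X, n_pcs = 3)
  ev_oracle <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(p$explained_variance, ev_oracle / sum(ev_oracle),
               tolerance = 1e-10)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  # full-rank reconstruction is exact
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(unname(p$coords %*% t(p$rotation)), Xc, tolerance = 1e-10)

  # data on a line: PC1 explains everything
  line <- outer(1:5, c(1, 2, -1))
  expect_equal(pca_embed(line, n_pcs = 2)$explained_variance[1], 1)
  # duplicated cells get identical coordinates
  dup <- rbind(X, X[1, ])
  cds <- pca_embed(dup, n_pcs = 2)$coords
  expect_equal(cds[5, ], cds[1, ])
  expect_error(pca_embed(X, n_pcs = 4), "rank")
})

test_that("knn_graph equals brute-force neighbor ranking", {
  # 3 collinear points, k = 1: middle point is everyone's neighbor
  g <- knn_graph(cbind(c(0, 1, 2)), k = 1)
  expect_equal(g$nn[[1]], 2L)
  expect_equal(g$nn[[3]], 2L)
  # k = n - 1: complete graph
  set.seed(3)
  pts <- matrix(rnorm(10), 5, 2)
  gc <- knn_graph(pts, k = 4)
  expect_equal(Matrix::nnzero(gc$adjacency), 5 * 4)

  for (seed in 1:3) {
    set.seed(seed)
    pts <- matrix(rnorm(20 * 3), 20, 3)
    g <- knn_graph(pts, k = 3)
    D <- as.matrix(dist(pts))
    for (i in seq_len(20)) {
      ord <- order(D[i, ], seq_len(20))
      expect_equal(sort(g$nn[[i]]), sort(setdiff(ord, i)[1:3]))
    }
    expect_true(all(g$adjacency@x > 0) && all(g$adjacency@x <= 1))
    expect_equal(as.matrix(g$adjacency), t(as.matrix(g$adjacency)))
    expect_equal(unname(Matrix::diag(g$adjacency)), rep(0, 20))
  }
})

test_that("batch_balanced_neighbors unions per-batch rankings", {
  set.seed(4)
  pts <- matrix(rnorm(12 * 2), 12, 2)
  batch <- rep(c("a", "b"), each = 6)
  g <- batch_balanced_neighbors(pts, batch, k_per_batch = 2)
  D <- as.matrix(dist(pts))
  for (i in 1:12) {
    expected <- unlist(lapply(split(1:12, batch), function(cand) {
      cand <- setdiff(cand, i)
      cand[order(D[i, cand], cand)][1:2]
    }), use.names = FALSE)
    expect_setequal(g$nn[[i]], expected)
    # every cell has cross-batch neighbors by construction
    expect_true(any(batch[g$nn[[i]]] != batch[i]))
  }
  # single batch: exact edge-set equality with knn_graph
  one <- batch_balanced_neighbors(pts, rep("a", 12), k_per_batch = 3)
  plain <- knn_graph(pts, k = 3)
  expect_equal(as.matrix(one$adjacency), as.matrix(plain$adjacency))
  expect_error(batch_balanced_neighbors(pts, c(rep("a", 10), "b", "b"), 2),
               "fewer")
})

test_that("cluster_graph finds planted structure deterministically", {
  # two disconnected cliques
  W <- matrix(0, 10, 10)
  W[1:5, 1:5] <- 1; W[6:10, 6:10] <- 1; diag(W) <- 0
  g <- graph_from_weights(W)
  labs <- cluster_graph(g, resolution = 1, seed = 1)
  expect_equal(length(unique(labs)), 2L)
  expect_equal(length(unique(labs[1:5])), 1L)
  expect_equal(sort(unique(labs)), c(0L, 1L))

  # planted 2-block SBM recovered exactly
  set.seed(5)
  n <- 60
  block <- rep(1:2, each = 30)
  P <- ifelse(outer(block, block, "=="), 0.5, 0.01)
  A <- matrix(rbinom(n * n, 1, P), n, n)
  A[lower.tri(A, diag = TRUE)] <- 0
  A <- A + t(A)
  labs <- cluster_graph(graph_from_weights(A), resolution = 1, seed = 1)
  expect_equal(adjusted_rand_index(labs, block), 1.0)

  # label partition is stable under cell permutation (same seed)
  perm <- sample(n)
  labs_p <- cluster_graph(graph_from_weights(A[perm, perm]),
                          resolution = 1, seed = 1)
  expect_equal(adjusted_rand_index(labs_p, labs[perm]), 1.0)
})

test_that("sub-clustering splices labels back contiguously", {
  W <- matrix(0, 12, 12)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1; W[9:12, 9:12] <- 1; diag(W) <- 0
  W[4, 5] <- W[5, 4] <- 0.01
  W[8, 9] <- W[9, 8] <- 0.01
  g <- graph_from_weights(W)
  labs <- cluster_graph(g, resolution = 1, seed = 1)
  sub <- which(labs == labs[1])
  labs2 <- cluster_graph(g, resolution = 1, seed = 1, subset = sub,
                         labels = labs)
  expect_equal(sort(unique(labs2)), seq(0L, max(labs2)))
  expect_equal(length(labs2), 12L)
  # cells outside the subset keep their partition
  outside <- setdiff(seq_len(12), sub)
  expect_equal(adjusted_rand_index(labs2[outside], labs[outside]), 1.0)
})

test_that("embed_2d backends are deterministic and separate blobs", {
  set.seed(6)
  blobs <- rbind(matrix(rnorm(40 * 12, 0), 40, 12),
                 matrix(rnorm(40 * 12, 12), 40, 12))
  a <- embed_2d(blobs, n_dims = 2, seed = 9)
  b <- embed_2d(blobs, n_dims = 2, seed = 9)
  expect_identical(a, b)
  cent1 <- colMeans(a[1:40, ]); cent2 <- colMeans(a[41:80, ])
  intra <- mean(dist(a[1:40, ]))
  expect_gt(sqrt(sum((cent1 - cent2)^2)), intra)
  # 10-dim layout feeds a k = 10 graph
  e10 <- embed_2d(blobs, n_dims = 10, seed = 9, backend = "pca")
  expect_silent(knn_graph(e10, 10))
})

test_that("summarize_by_cluster computes means, fractions and 0-1 scaling", {
  E <- rbind(zero = c(0, 0, 0, 0),
             only1 = c(2, 4, 0, 0),
             grad = c(1, 1, 3, 3))
  sce <- make_sce(E)
  s <- summarize_by_cluster(sce, c("a", "a", "b", "b"), scale01 = TRUE)
  g0 <- s[s$gene == "zero", ]
  expect_equal(g0$mean_expr, c(0, 0))
  expect_equal(g0$frac_expr, c(0, 0))
  g1 <- s[s$gene == "only1", ]
  expect_equal(g1$frac_expr[g1$cluster == "a"], 1)
  expect_equal(g1$frac_expr[g1$cluster == "b"], 0)
  expect_equal(g1$scaled, c(1, 0))
  g2 <- s[s$gene == "grad", ]  # means 1 and 3 -> scaled 0 and 1
  expect_equal(g2$scaled[order(g2$cluster)], c(0, 1))
})

test_that("connect_components bridges islands with single-linkage edges", {
  pts <- rbind(matrix(rnorm(10 * 2, 0, 0.1), 10, 2),
               matrix(rnorm(10 * 2, 50, 0.1), 10, 2))
  g <- knn_graph(pts, 3)
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected",
                                            weighted = TRUE)
  expect_equal(igraph::components(ig)$no, 2)
  gc <- connect_components(g)
  ig2 <- igraph::graph_from_adjacency_matrix(gc$adjacency,
                                             mode = "undirected",
                                             weighted = TRUE)
  expect_equal(igraph::components(ig2)$no, 1)
  expect_equal(gc$n_bridges, 1L)
})
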