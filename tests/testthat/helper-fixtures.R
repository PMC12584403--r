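# Fixture builders and independent brute-force oracles shared by the suite.

# SingleCellExperiment from a genes x cells value matrix; by default the
# values double as the normalized and log layers so statistics can be tested
# on exactly the numbers written down in the test.
make_sce <- function(E, normalized = TRUE, is_mito = NULL, is_ercc = NULL,
                     batch = NULL, log_layer = TRUE) {
  E <- as.matrix(E)
  if (is.null(rownames(E))) rownames(E) <- sprintf("g%03d", seq_len(nrow(E)))
  if (is.null(colnames(E))) colnames(E) <- sprintf("c%03d", seq_len(ncol(E)))
  assays <- list(counts = Matrix::Matrix(E, sparse = TRUE))
  if (normalized) {
    assays$normcounts <- assays$counts
    if (log_layer) assays$logcounts <- log1p(assays$counts)
  }
  rd <- S4Vectors::DataFrame(
    is_mito = if (is.null(is_mito)) rep(FALSE, nrow(E)) else is_mito,
    is_ercc = if (is.null(is_ercc)) rep(FALSE, nrow(E)) else is_ercc,
    row.names = rownames(E))
  cd <- S4Vectors::DataFrame(row.names = colnames(E))
  if (!is.null(batch)) cd$batch <- batch
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = assays, rowData = rd, colData = cd)
  S4Vectors::metadata(sce)$normalized <- normalized
  sce
}

# graph from an explicit symmetric weight matrix (bypasses kNN construction)
graph_from_weights <- function(W) {
  W <- methods::as(Matrix::Matrix(W, sparse = TRUE), "CsparseMatrix")
  structure(list(nn = NULL, adjacency = W, k = NA, mode = "explicit",
                 bandwidth = rep(1, nrow(W)),
                 dist = as.matrix(1 - W)), class = "neighbor_graph")
}

path_graph <- function(n) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) W[i, i + 1] <- W[i + 1, i] <- 1
  graph_from_weights(W)
}

# random connected geometric toy chain with two terminal fates
random_toy_chain <- function(n = 30, beta = 2, seed = 1, k = 4) {
  set.seed(seed)
  pts <- matrix(rnorm(2 * n), n, 2)
  g <- connect_components(knn_graph(pts, k))
  sinkA <- 1:2
  sinkB <- 3:4
  pot <- solve_potential(g, sources = n, sinks = list(A = sinkA, B = sinkB))
  list(graph = g, potential = pot,
       chain = build_chain(g, pot, beta = beta),
       transient = setdiff(seq_len(n), c(sinkA, sinkB, n)))
}

# textbook O(n^2) Benjamini-Hochberg: adj_i = min over {j: p_j >= p_i} of
# min(1, m p_j / rank_j)
bh_brute <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "min")
  vapply(seq_len(m), function(i) {
    j <- which(p >= p[i])
    min(1, min(m * p[j] / rank(p, ties.method = "max")[j]))
  }, numeric(1))
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (tie-free data), following the classic convention of doubling
# the smaller tail
wilcox_enum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  v <- c(x, y)
  r <- rank(v)
  U_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- utils::combn(nx + ny, nx)
  U_all <- apply(sets, 2, function(s) sum(r[s]) - nx * (nx + 1) / 2)
  p <- if (U_obs > nx * ny / 2) mean(U_all >= U_obs) else mean(U_all <= U_obs)
  min(1, 2 * p)
}
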