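#' @title Expression-manifold construction
#' @description Highly-variable-gene selection, PCA, nearest-neighbor graphs
#'   (plain and batch-balanced), modularity clustering, low-dimensional
#'   layouts, and per-cluster expression summaries.
#' @name manifold
NULL

# pick the working expression assay: log layer when present, else normalized
expr_assay <- function(sce, assay_name = NULL) {
  if (!is.null(assay_name)) return(assay(sce, assay_name))
  if ("logcounts" %in% assayNames(sce)) return(assay(sce, "logcounts"))
  if ("normcounts" %in% assayNames(sce)) return(assay(sce, "normcounts"))
  assay(sce, "counts")
}

#' Select highly variable genes by mean-binned normalized dispersion
#'
#' Genes are ranked by the z-score of their dispersion (variance/mean)
#' within `n_bins` equal-occupancy bins of mean expression, so that
#' variability is judged relative to genes of comparable abundance.
#' Zero-variance genes are never selected ahead of genes with positive
#' variance. Deterministic given the input.
#'
#' @param sce a normalized [SingleCellExperiment] (log layer used if present).
#' @param n_hvg number of genes to return.
#' @param n_bins number of mean-expression bins (default 20).
#' @param assay_name optional explicit assay.
#' @return character vector of gene ids, ranked by normalized dispersion.
#' @export
select_hvg <- function(sce, n_hvg, n_bins = 20, assay_name = NULL) {
  E <- expr_assay(sce, assay_name)
  if (n_hvg > nrow(E))
    stopf("n_hvg (%d) exceeds available genes (%d)", n_hvg, nrow(E))
  m <- Matrix::rowSums(E) / ncol(E)
  v <- Matrix::rowSums(E^2) / ncol(E) - m^2
  v <- v * ncol(E) / max(1, ncol(E) - 1)
  disp <- ifelse(m > 0, v / m, 0)
  n_bins <- max(1, min(n_bins, floor(nrow(E) / 2)))
  bins <- if (n_bins == 1) rep(1L, nrow(E)) else
    cut(rank(m, ties.method = "first"),
        breaks = n_bins, labels = FALSE, include.lowest = TRUE)
  z <- disp
  for (b in unique(bins)) {
    i <- which(bins == b)
    mu <- mean(disp[i]); s <- sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mu) / s
  }
  z[v <= 0] <- -Inf
  ord <- order(z, decreasing = TRUE)
  rownames(E)[ord[seq_len(n_hvg)]]
}

#' Principal component embedding
#'
#' Exact PCA (per-gene centering) of the cells over a gene subset. Column
#' signs are fixed so the loading with the largest magnitude is positive,
#' making the result fully deterministic.
#'
#' @param sce object or a cells x features numeric matrix.
#' @param genes gene subset (ignored when `sce` is a matrix).
#' @param n_pcs number of components.
#' @param assay_name optional explicit assay.
#' @return list with `coords` (cells x n_pcs), `explained_variance`
#'   (fractions, decreasing) and `rotation`.
#' @export
pca_embed <- function(sce, genes = NULL, n_pcs = 15, assay_name = NULL) {
  X <- if (is(sce, "SingleCellExperiment")) {
    E <- expr_assay(sce, assay_name)
    if (!is.null(genes)) E <- E[genes, , drop = FALSE]
    t(as.matrix(E))
  } else as.matrix(sce)
  r <- min(nrow(X) - 1, ncol(X))
  if (n_pcs > r) stopf("n_pcs (%d) exceeds matrix rank bound (%d)", n_pcs, r)
  p <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_pcs)
  flip <- apply(p$rotation, 2, function(u) sign(u[which.max(abs(u))]))
  flip[flip == 0] <- 1
  coords <- sweep(p$x, 2, flip, `*`)
  rownames(coords) <- rownames(X)
  list(coords = coords,
       explained_variance = (p$sdev^2 / sum(p$sdev^2))[seq_len(n_pcs)],
       rotation = sweep(p$rotation, 2, flip, `*`))
}

# Gaussian kernel edge weights with per-node adaptive bandwidth (distance to
# the furthest listed neighbor); weight 1 at zero distance.
kernel_weights <- function(d, si, sj) {
  s <- pmax(sqrt(si * sj), .Machine$double.eps)
  exp(-(d / s)^2)
}

build_graph <- function(nn, D, mode, k) {
  n <- length(nn)
  bw <- vapply(seq_len(n), function(i) {
    dd <- D[i, nn[[i]]]
    max(max(dd), .Machine$double.eps)
  }, numeric(1))
  ii <- rep(seq_len(n), lengths(nn))
  jj <- unlist(nn, use.names = FALSE)
  # undirected union of the directed lists; the kernel weight is symmetric in
  # (i, j) so deduplicating on the unordered pair loses nothing
  a <- pmin(ii, jj); b <- pmax(ii, jj)
  keep <- !duplicated(cbind(a, b))
  a <- a[keep]; b <- b[keep]
  w <- kernel_weights(D[cbind(a, b)], bw[a], bw[b])
  A <- sparseMatrix(i = c(a, b), j = c(b, a), x = c(w, w), dims = c(n, n))
  nms <- rownames(D)
  if (!is.null(nms)) dimnames(A) <- list(nms, nms)
  structure(list(nn = nn, adjacency = as(A, "CsparseMatrix"),
                 k = k, mode = mode, bandwidth = bw, dist = D),
            class = "neighbor_graph")
}

#' Connect the components of a neighbor graph
#'
#' A kNN graph over well-separated populations can fall apart into islands,
#' which breaks any computation that needs a path between progenitors and
#' every terminal fate. This adds single-linkage bridge edges: while more
#' than one component remains, the closest pair of cells in different
#' components is joined (kernel weight of their distance, floored at
#' `min_weight`).
#'
#' @param graph a `neighbor_graph`.
#' @param min_weight weight floor for bridge edges.
#' @return the graph with bridge edges added; bridge count in `n_bridges`.
#' @export
connect_components <- function(graph, min_weight = 1e-6) {
  A <- graph$adjacency
  D <- graph$dist
  n_bridges <- 0L
  repeat {
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE)
    comp <- igraph::components(g)$membership
    if (max(comp) == 1) break
    Dx <- D
    same <- outer(comp, comp, `==`)
    Dx[same] <- Inf
    hit <- which(Dx == min(Dx), arr.ind = TRUE)[1, ]
    i <- hit[1]; j <- hit[2]
    w <- max(kernel_weights(D[i, j], graph$bandwidth[i], graph$bandwidth[j]),
             min_weight)
    A[i, j] <- A[j, i] <- w
    n_bridges <- n_bridges + 1L
  }
  graph$adjacency <- A
  graph$n_bridges <- n_bridges
  graph
}

#' k-nearest-neighbor graph
#'
#' Euclidean kNN per cell with ties broken by cell index; the directed lists
#' are symmetrized into an undirected weighted graph with Gaussian-kernel
#' weights in (0, 1] using a per-node adaptive bandwidth (distance to the
#' k-th neighbor).
#'
#' @param coords cells x dims matrix.
#' @param k neighbors per cell (`k < n`).
#' @return a `neighbor_graph`: neighbor lists, sparse symmetric `adjacency`,
#'   provenance fields.
#' @export
knn_graph <- function(coords, k) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k < 1 || k >= n) stopf("need 1 <= k < n (k=%d, n=%d)", k, n)
  D <- as.matrix(dist(coords))
  nn <- lapply(seq_len(n), function(i) {
    ord <- order(D[i, ], seq_len(n))   # ties by index
    ord <- ord[ord != i]
    ord[seq_len(k)]
  })
  build_graph(nn, D, "plain", k)
}

#' Batch-balanced nearest neighbors
#'
#' Each cell's neighbor list is the union, over batches, of its
#' `k_per_batch` nearest cells within that batch, which forces cross-batch
#' edges and aligns batches that share populations. With a single batch this
#' is exactly [knn_graph()] with `k = k_per_batch`.
#'
#' @param coords cells x dims matrix.
#' @param batch per-cell batch labels.
#' @param k_per_batch neighbors per batch per cell.
#' @return a `neighbor_graph` with `mode = "batch_balanced"`.
#' @export
batch_balanced_neighbors <- function(coords, batch, k_per_batch) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  batch <- as.character(batch)
  stopifnot(length(batch) == n)
  sizes <- table(batch)
  small <- names(sizes)[sizes < k_per_batch + 1]
  if (length(small))
    stopf("batch(es) with fewer than k_per_batch+1 = %d cells: %s",
          k_per_batch + 1, paste(small, collapse = ", "))
  D <- as.matrix(dist(coords))
  idx_by_batch <- split(seq_len(n), batch)
  nn <- lapply(seq_len(n), function(i) {
    unlist(lapply(idx_by_batch, function(cand) {
      cand <- cand[cand != i]
      ord <- cand[order(D[i, cand], cand)]
      ord[seq_len(k_per_batch)]
    }), use.names = FALSE)
  })
  g <- build_graph(nn, D, "batch_balanced", k_per_batch)
  g$n_batches <- length(idx_by_batch)
  g
}

#' Graph community detection (modularity clustering)
#'
#' Louvain modularity clustering of the weighted neighbor graph at a given
#' resolution; deterministic given the seed. A cell subset can be
#' re-clustered on its induced subgraph and the labels spliced back
#' (sub-clustering different parts of the manifold).
#'
#' @param graph a `neighbor_graph`.
#' @param resolution resolution parameter (larger = more clusters).
#' @param seed RNG seed for the backend.
#' @param subset optional cell indices to re-cluster; requires `labels`.
#' @param labels existing labels when sub-clustering.
#' @return integer cluster labels, contiguous from 0.
#' @export
cluster_graph <- function(graph, resolution = 1, seed = 0,
                          subset = NULL, labels = NULL) {
  A <- graph$adjacency
  if (!is.null(subset)) {
    stopifnot(!is.null(labels))
    A <- A[subset, subset, drop = FALSE]
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  cl <- with_local_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(cl)
  if (is.null(subset)) {
    out <- as.integer(memb) - 1L
  } else {
    out <- as.integer(labels)
    out[subset] <- max(labels) + as.integer(memb)
    out <- as.integer(factor(out)) - 1L
  }
  names(out) <- rownames(graph$adjacency)
  out
}

#' Low-dimensional layout of the expression manifold
#'
#' Pluggable layout backend used both for 2-D viewing and for the
#' 10-dimensional space on which the fate-simulation graph is built. The
#' `"umap"` backend is the nonlinear default; `"pca"` is an exact linear
#' alternative. Both are deterministic given `seed`.
#'
#' @param coords cells x dims matrix (typically PCA coordinates).
#' @param n_dims output dimensionality (2 for viewing, 10 for the fate graph).
#' @param seed RNG seed.
#' @param backend `"umap"` or `"pca"`.
#' @param n_neighbors neighborhood size for the umap backend.
#' @return cells x n_dims matrix.
#' @export
embed_2d <- function(coords, n_dims = 2, seed = 0,
                     backend = c("umap", "pca"), n_neighbors = 15) {
  backend <- match.arg(backend)
  coords <- as.matrix(coords)
  if (backend == "pca") {
    out <- pca_embed(coords, n_pcs = n_dims)$coords
  } else {
    out <- with_local_seed(seed,
      uwot::umap(coords, n_components = n_dims,
                 n_neighbors = min(n_neighbors, nrow(coords) - 1),
                 n_threads = 1, n_sgd_threads = 0))
    rownames(out) <- rownames(coords)
  }
  out
}

#' Per-cluster expression summary
#'
#' Mean normalized expression and expressing fraction per (cluster, gene),
#' the quantities behind dot-plot and heatmap panels. With `scale01` the
#' means are min-max scaled to `[0, 1]` per gene across clusters
#' ("expression normalized between zero and one").
#'
#' @param sce a normalized [SingleCellExperiment].
#' @param labels per-cell cluster labels.
#' @param genes genes to summarize (default all).
#' @param scale01 add per-gene min-max scaling across clusters.
#' @param assay_name assay to average (default `normcounts`).
#' @return long data.frame: cluster, gene, mean_expr, frac_expr
#'   (and `scaled` when requested).
#' @export
summarize_by_cluster <- function(sce, labels, genes = NULL, scale01 = FALSE,
                                 assay_name = "normcounts") {
  E <- assay(sce, assay_name)
  if (!is.null(genes)) E <- E[genes, , drop = FALSE]
  stopifnot(length(labels) == ncol(E))
  labels <- as.character(labels)
  cl <- sort(unique(labels))
  res <- do.call(rbind, lapply(cl, function(g) {
    idx <- which(labels == g)
    if (!length(idx)) stopf("empty cluster: %s", g)
    sub <- E[, idx, drop = FALSE]
    data.frame(cluster = g, gene = rownames(E),
               mean_expr = Matrix::rowSums(sub) / length(idx),
               frac_expr = Matrix::rowSums(sub > 0) / length(idx),
               row.names = NULL)
  }))
  if (scale01) {
    res$scaled <- stats::ave(res$mean_expr, res$gene, FUN = function(x) {
      r <- range(x)
      if (diff(r) == 0) rep(0, length(x)) else (x - r[1]) / diff(r)
    })
  }
  res
}
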