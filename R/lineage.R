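#' Cluster-level lineage abstraction (connectivity confidence)
#'
#' For every cluster pair, the observed number of inter-cluster edges is
#' compared with its expectation under random edge allocation given the
#' cluster degree totals: `E[e_ab] = d_a d_b / (2E)`. The ratio, clipped to
#' `[0, 1]`, is the connectivity confidence; the raw ratio is kept alongside.
#' Zero confidence if and only if no edge connects the pair.
#'
#' @param graph a `neighbor_graph`.
#' @param labels per-cell cluster labels.
#' @return list with `confidence` (clusters x clusters symmetric matrix),
#'   `ratio` (unclipped), `n_edges` (inter-cluster edge counts) and an
#'   `edges` data.frame (cluster_a, cluster_b, confidence, n_edges).
#' @export
paga_connectivity <- function(graph, labels) {
  A <- graph$adjacency
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(A))
  cl <- sort(unique(labels))
  if (length(cl) < 2) stopf("need at least 2 clusters")
  # unweighted degree and edge counts on the symmetrized graph
  B <- A != 0
  memb <- factor(labels, levels = cl)
  M <- sparseMatrix(i = seq_along(labels), j = as.integer(memb), x = 1,
                    dims = c(length(labels), length(cl)))
  # inter-cluster block sums count each undirected edge once off-diagonal
  # and twice on the diagonal
  E2 <- as.matrix(Matrix::t(M) %*% B %*% M)
  deg_tot <- as.numeric(Matrix::t(M) %*% Matrix::rowSums(B))  # degree sum per cluster
  tot <- sum(deg_tot)                             # = 2E
  if (tot == 0) {
    warnf("graph has no edges; connectivity is all zero")
    Z <- matrix(0, length(cl), length(cl), dimnames = list(cl, cl))
    return(list(confidence = Z, ratio = Z, n_edges = Z,
                edges = data.frame(cluster_a = character(0),
                                   cluster_b = character(0),
                                   confidence = numeric(0),
                                   n_edges = numeric(0))))
  }
  expected <- outer(deg_tot, deg_tot) / tot
  ratio <- ifelse(expected > 0, E2 / expected, 0)
  diag(ratio) <- 0
  conf <- pmin(ratio, 1)
  dimnames(conf) <- dimnames(ratio) <- list(cl, cl)
  n_edges <- E2
  diag(n_edges) <- NA
  dimnames(n_edges) <- list(cl, cl)
  ut <- which(upper.tri(conf), arr.ind = TRUE)
  edges <- data.frame(cluster_a = cl[ut[, 1]], cluster_b = cl[ut[, 2]],
                      confidence = conf[ut], n_edges = n_edges[ut])
  list(confidence = conf, ratio = ratio, n_edges = n_edges, edges = edges)
}

#' Diffusion map of a cell graph
#'
#' Eigendecomposition of the symmetrically normalized transition kernel
#' `D^{-1/2} W D^{-1/2}` of the edge-weight matrix. Coordinates are the
#' random-walk right eigenvectors (`D^{-1/2}` times the symmetric
#' eigenvectors) of the top nontrivial eigenpairs, deterministic up to the
#' fixed sign convention.
#'
#' @param graph a `neighbor_graph` (or a symmetric weight matrix).
#' @param n_components number of nontrivial components to keep.
#' @return list with `coords` (cells x n_components), `eigenvalues`
#'   (decreasing, trivial pair dropped) and `n_components`.
#' @export
diffusion_map <- function(graph, n_components = 15) {
  W <- if (inherits(graph, "neighbor_graph")) graph$adjacency else
    as(graph, "CsparseMatrix")
  n <- nrow(W)
  if (n_components >= n) stopf("n_components must be < number of cells")
  d <- Matrix::rowSums(W)
  if (any(d <= 0)) stopf("isolated node(s): %s",
                         paste(head(which(d <= 0)), collapse = ", "))
  dm <- 1 / sqrt(d)
  S <- Diagonal(x = dm) %*% W %*% Diagonal(x = dm)
  # coordinates use the stationary distribution, so a positive rescaling of
  # every edge weight leaves the embedding (and pseudotime) unchanged
  pm <- 1 / sqrt(d / sum(d))
  S <- (S + Matrix::t(S)) / 2
  e <- eigen(as.matrix(S), symmetric = TRUE)
  # drop the trivial stationary pair (largest eigenvalue, = 1 per component;
  # one trivial vector overall: D^{1/2} 1)
  lam <- e$values[2:(n_components + 1)]
  phi <- e$vectors[, 2:(n_components + 1), drop = FALSE]
  psi <- phi * pm   # random-walk right eigenvectors, scale-free
  flip <- apply(psi, 2, function(u) sign(u[which.max(abs(u))]))
  flip[flip == 0] <- 1
  psi <- sweep(psi, 2, flip, `*`)
  rownames(psi) <- rownames(W)
  list(coords = psi, eigenvalues = lam, n_components = n_components)
}

#' Diffusion pseudotime from a root cell
#'
#' Distance from the root in eigenvalue-rescaled diffusion coordinates
#' (component `l` weighted by `lambda_l / (1 - lambda_l)`), the standard
#' pseudotemporal ordering given a root inside the starting population.
#' Cells in a different connected component than the root (eigenvalues
#' numerically at 1 beyond the trivial one) get infinite pseudotime.
#'
#' @param dmap result of [diffusion_map()].
#' @param root root cell (index or name).
#' @param graph optional `neighbor_graph` used to flag cells disconnected
#'   from the root.
#' @return list with `pseudotime` (root = 0), `root`.
#' @export
diffusion_pseudotime <- function(dmap, root, graph = NULL) {
  psi <- dmap$coords
  if (is.character(root)) root <- match(root, rownames(psi))
  if (is.na(root) || root < 1 || root > nrow(psi)) stopf("invalid root cell")
  lam <- dmap$eigenvalues
  usable <- lam < 1 - 1e-10   # component-indicator pairs carry no distance
  w <- ifelse(usable, lam / (1 - lam), 0)
  diffs <- sweep(psi, 2, psi[root, ], `-`)
  pt <- sqrt(rowSums(sweep(diffs, 2, w, `*`)^2))
  pt[root] <- 0
  if (!is.null(graph)) {
    g <- igraph::graph_from_adjacency_matrix(graph$adjacency,
                                             mode = "undirected",
                                             weighted = TRUE)
    comp <- igraph::components(g)$membership
    pt[comp != comp[root]] <- Inf
  }
  names(pt) <- rownames(psi)
  list(pseudotime = pt, root = root)
}

#' Choose a root cell inside the starting population
#'
#' The progenitor-cluster cell with maximal average edge weight to the other
#' cells of its cluster (the most central progenitor), a deterministic
#' data-driven stand-in for "a root cell within the starting population".
#'
#' @param graph a `neighbor_graph`.
#' @param labels per-cell cluster labels.
#' @param progenitor_label label of the starting population.
#' @return root cell index.
#' @export
select_root <- function(graph, labels, progenitor_label) {
  labels <- as.character(labels)
  idx <- which(labels == progenitor_label)
  if (!length(idx)) stopf("no cells labeled '%s'", progenitor_label)
  A <- graph$adjacency[idx, idx, drop = FALSE]
  idx[which.max(Matrix::rowSums(A) / max(1, length(idx) - 1))]
}
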