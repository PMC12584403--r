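#' Harmonic potential-energy field over the cell graph
#'
#' Solves the weighted graph-Laplace (harmonic) equation: every interior
#' cell's potential is the weighted mean of its neighbors', with boundary
#' values fixed at 1 on the source (progenitor) cells and 0 on every sink
#' (terminal fate) cell. The gradient of the resulting field runs from
#' progenitors down to the mature fates and is what biases the Markov chain.
#'
#' @param graph a `neighbor_graph`.
#' @param sources integer/character vector of progenitor cells (V = 1).
#' @param sinks named list of cell vectors, one entry per terminal fate
#'   (V = 0).
#' @return a `potential_field`: `V` (per-cell, in `[0, 1]`), `sources`,
#'   `sinks`, and the solver `residual`.
#' @export
solve_potential <- function(graph, sources, sinks) {
  W <- graph$adjacency
  n <- nrow(W)
  to_idx <- function(x) {
    if (is.character(x)) x <- match(x, rownames(W))
    x <- as.integer(x)
    stopifnot(!anyNA(x), all(x >= 1), all(x <= n))
    x
  }
  sources <- to_idx(sources)
  stopifnot(is.list(sinks), length(sinks) >= 1, !is.null(names(sinks)))
  sinks <- lapply(sinks, to_idx)
  sink_all <- unlist(sinks, use.names = FALSE)
  if (length(intersect(sources, sink_all)))
    stopf("source and sink sets overlap")
  if (anyDuplicated(sink_all)) stopf("sink sets overlap each other")
  boundary <- c(sources, sink_all)
  interior <- setdiff(seq_len(n), boundary)

  V <- numeric(n)
  V[sources] <- 1
  if (length(interior)) {
    # connectivity: every interior cell must reach the boundary
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    comp <- igraph::components(g)$membership
    ok_comp <- unique(comp[boundary])
    bad <- interior[!(comp[interior] %in% ok_comp)]
    if (length(bad))
      stopf("interior cell(s) disconnected from sources/sinks: %s",
            paste(head(bad, 10), collapse = ", "))
    d <- Matrix::rowSums(W)
    L_II <- Diagonal(x = d[interior]) - W[interior, interior, drop = FALSE]
    rhs <- W[interior, sources, drop = FALSE] %*% rep(1, length(sources))
    V[interior] <- as.numeric(Matrix::solve(L_II, rhs))
  }
  # residual of the harmonic equation on the interior
  resid <- if (length(interior)) {
    d <- Matrix::rowSums(W)
    max(abs(as.numeric(W[interior, , drop = FALSE] %*% V) -
              d[interior] * V[interior]) / pmax(d[interior], 1e-300))
  } else 0
  names(V) <- rownames(W)
  structure(list(V = V, sources = sources, sinks = sinks, residual = resid),
            class = "potential_field")
}

#' Pseudotime-derived potential field
#'
#' Builds the biasing potential directly from diffusion pseudotime:
#' `V = 1 - pt / max(pt)`, high at the root end and low at the mature ends.
#' On densely connected cell graphs the harmonic field of
#' [solve_potential()] degenerates into near-constant plateaus on either
#' side of the graph bottlenecks (almost no gradient along the branches),
#' whereas the pseudotime field keeps a usable gradient along every
#' lineage; it is therefore the default biasing field of the pipeline.
#'
#' @param pseudotime per-cell pseudotime (infinite values allowed for
#'   disconnected cells; they get V = 0).
#' @param sources,sinks as in [solve_potential()].
#' @return a `potential_field` (residual `NA`; no linear system is solved).
#' @export
pseudotime_potential <- function(pseudotime, sources, sinks) {
  fin <- is.finite(pseudotime)
  V <- 1 - pseudotime / max(pseudotime[fin])
  V[!fin] <- 0
  V <- pmin(pmax(V, 0), 1)
  stopifnot(is.list(sinks), !is.null(names(sinks)))
  structure(list(V = V, sources = sources, sinks = sinks, residual = NA),
            class = "potential_field")
}

#' Distance-to-sink potential for fate-committed trajectory ensembles
#'
#' For one terminal fate, the potential is the shortest-path graph distance
#' to that fate's sink cells (edge lengths = embedding distances),
#' normalized to `[0, 1]`. Walks on the resulting chain descend toward that
#' specific fate, which yields a committed trajectory ensemble of
#' controllable size for every lineage regardless of how often an
#' unconditioned walk would pick it.
#'
#' @param graph a `neighbor_graph` (needs the `dist` matrix).
#' @param sinks named list with exactly the fate's sink cells (a
#'   single-fate sink list).
#' @param sources progenitor cells (recorded; V is not forced to 1 there).
#' @return a `potential_field`.
#' @export
distance_potential <- function(graph, sinks, sources = integer(0)) {
  stopifnot(is.list(sinks), length(sinks) == 1, !is.null(names(sinks)))
  A <- as(as(graph$adjacency, "generalMatrix"), "TsparseMatrix")
  ig <- igraph::graph_from_data_frame(
    data.frame(from = A@i + 1L, to = A@j + 1L,
               weight = graph$dist[cbind(A@i + 1L, A@j + 1L)] +
                 .Machine$double.eps),
    directed = FALSE,
    vertices = data.frame(seq_len(nrow(graph$adjacency))))
  d <- suppressWarnings(
    igraph::distances(ig, to = as.character(sinks[[1]])))
  dmin <- apply(d, 1, min)[as.character(seq_len(nrow(graph$adjacency)))]
  dmin[!is.finite(dmin)] <- max(dmin[is.finite(dmin)])
  V <- dmin / max(dmin)
  names(V) <- rownames(graph$adjacency)
  structure(list(V = unname(V), sources = sources, sinks = sinks,
                 residual = NA),
            class = "potential_field")
}

#' Potential-biased Markov chain on the cell graph
#'
#' For every non-absorbing cell `i`, the transition probability to
#' `j` in its closed neighborhood `N(i) + {i}` is the Boltzmann weight
#' `exp(-beta (V_j - V_i))`, normalized per row; larger `beta` biases the
#' walk more strongly downhill in potential. Every sink cell is absorbing.
#'
#' @param graph a `neighbor_graph`.
#' @param potential a `potential_field` from [solve_potential()].
#' @param beta inverse temperature (>= 0; default 10).
#' @return a `markov_chain`: sparse row-stochastic `P`, `beta`, per-cell
#'   `fate_id` (0 transient, 1..K absorbing), `fates` (names).
#' @export
build_chain <- function(graph, potential, beta = 10) {
  if (beta < 0) stopf("beta must be nonnegative")
  W <- graph$adjacency
  n <- nrow(W)
  V <- potential$V
  fate_id <- integer(n)
  for (k in seq_along(potential$sinks)) fate_id[potential$sinks[[k]]] <- k
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  Wt <- as(as(W, "generalMatrix"), "TsparseMatrix")
  nbrs <- split(Wt@j + 1L, Wt@i + 1L)
  for (i in seq_len(n)) {
    if (fate_id[i] > 0) { # absorbing
      ii <- c(ii, i); jj <- c(jj, i); xx <- c(xx, 1)
      next
    }
    cand <- c(i, nbrs[[as.character(i)]])
    lw <- -beta * (V[cand] - V[i])
    p <- exp(lw - max(lw))
    p <- p / sum(p)
    ii <- c(ii, rep(i, length(cand))); jj <- c(jj, cand); xx <- c(xx, p)
  }
  P <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                    dimnames = dimnames(W))
  structure(list(P = P, beta = beta, fate_id = fate_id,
                 fates = names(potential$sinks)),
            class = "markov_chain")
}

chain_csr <- function(chain) {
  R <- as(as(chain$P, "RsparseMatrix"), "dgRMatrix")
  # cumulative probabilities within each row
  cum <- R@x
  for (i in seq_len(nrow(R))) {
    a <- R@p[i] + 1L; b <- R@p[i + 1L]
    if (b >= a) {
      cum[a:b] <- cumsum(cum[a:b])
      cum[b] <- 1  # guard against rounding at the row end
    }
  }
  list(rowptr = R@p, colind = R@j, cumprob = cum)
}

#' Monte Carlo simulation of differentiation walks
#'
#' Samples `n_iterations` absorbing random walks of the chain, each starting
#' from a uniformly drawn start cell and stepping until absorption in a
#' terminal fate or `max_steps`. Bit-reproducible given `seed`.
#'
#' @param chain a `markov_chain`.
#' @param start_cells start cell indices (typically the progenitor cluster).
#' @param n_iterations number of walks (1500-2000 in typical use).
#' @param max_steps step cap per walk (default 10x the number of cells).
#' @param seed RNG seed.
#' @param keep_paths store full state sequences (needed for fate estimation
#'   from visits and for trajectory profiles).
#' @return a `trajectory_ensemble`: `fate` (factor, `NA` = unabsorbed),
#'   `steps`, `start`, `last`, optional `paths`, plus the simulation
#'   parameters.
#' @export
simulate_walks <- function(chain, start_cells, n_iterations,
                           max_steps = 10 * nrow(chain$P), seed = 0,
                           keep_paths = TRUE) {
  stopifnot(n_iterations >= 1, length(start_cells) >= 1)
  if (is.character(start_cells))
    start_cells <- match(start_cells, rownames(chain$P))
  stopifnot(!anyNA(start_cells))
  csr <- chain_csr(chain)
  res <- with_local_seed(seed,
    cpp_simulate_walks(csr$rowptr, csr$colind, csr$cumprob,
                       as.integer(chain$fate_id),
                       as.integer(start_cells) - 1L,
                       as.integer(n_iterations), as.integer(max_steps),
                       isTRUE(keep_paths)))
  fate <- factor(ifelse(res$fate == 0, NA, chain$fates[res$fate]),
                 levels = chain$fates)
  structure(list(fate = fate, steps = res$steps, start = res$start,
                 last = res$last, paths = res$paths,
                 fates = chain$fates, n_cells = nrow(chain$P),
                 n_iterations = n_iterations, max_steps = max_steps,
                 seed = seed),
            class = "trajectory_ensemble")
}

#' Exact absorption (fate) probabilities
#'
#' Solves the absorbing-chain linear system `B = (I - Q)^{-1} R` (transient
#' block `Q`, transient-to-absorbing block `R`) with a sparse solver and
#' aggregates absorbing columns by fate. Sink cells are one-hot for their
#' own fate; transient rows sum to 1.
#'
#' @param chain a `markov_chain`.
#' @return a `fate_probabilities` matrix (cells x fates) with attributes
#'   `method = "exact"`.
#' @export
absorption_exact <- function(chain) {
  P <- chain$P
  n <- nrow(P)
  trans <- which(chain$fate_id == 0)
  absb <- which(chain$fate_id > 0)
  if (!length(absb)) stopf("chain has no absorbing cells")
  B <- matrix(0, n, length(chain$fates),
              dimnames = list(rownames(P), chain$fates))
  B[cbind(absb, chain$fate_id[absb])] <- 1
  if (length(trans)) {
    Q <- P[trans, trans, drop = FALSE]
    R <- P[trans, absb, drop = FALSE]
    M <- Diagonal(length(trans)) - Q
    # reachability check: transient cells with no path to any sink make the
    # system singular; name them rather than fail obscurely
    g <- igraph::graph_from_adjacency_matrix(P, mode = "directed",
                                             weighted = TRUE)
    reach <- igraph::distances(g, v = trans, to = absb, mode = "out")
    bad <- trans[apply(is.infinite(reach), 1, all)]
    if (length(bad))
      stopf("transient cell(s) cannot reach any sink: %s",
            paste(head(bad, 10), collapse = ", "))
    Bt <- as.matrix(Matrix::solve(M, R))
    # aggregate absorbing columns by fate
    fid <- chain$fate_id[absb]
    for (k in seq_along(chain$fates))
      B[trans, k] <- rowSums(Bt[, fid == k, drop = FALSE])
  }
  structure(B, method = "exact", class = c("fate_probabilities", "matrix"))
}

#' Empirical fate probabilities from a walk ensemble
#'
#' For every cell, the fraction of walks visiting it that end absorbed in
#' each fate; the Monte Carlo analogue of [absorption_exact()]. Cells
#' visited by fewer than `min_visits` absorbed walks are flagged low
#' confidence; unvisited cells are `NA`, not zero.
#'
#' @param ensemble a `trajectory_ensemble` with paths.
#' @param min_visits low-confidence threshold on visiting-walk count.
#' @return a `fate_probabilities` matrix (cells x fates) with attributes
#'   `method = "empirical"`, `n_visits`, `se` and `low_confidence`.
#' @export
fate_from_ensemble <- function(ensemble, min_visits = 10) {
  if (is.null(ensemble$paths))
    stopf("ensemble was simulated with keep_paths = FALSE")
  n <- ensemble$n_cells
  fates <- ensemble$fates
  counts <- matrix(0, n, length(fates), dimnames = list(NULL, fates))
  visits <- numeric(n)
  for (w in seq_along(ensemble$paths)) {
    f <- ensemble$fate[w]
    if (is.na(f)) next  # unabsorbed walks carry no fate information
    cells <- unique(ensemble$paths[[w]])
    visits[cells] <- visits[cells] + 1
    counts[cells, as.integer(f)] <- counts[cells, as.integer(f)] + 1
  }
  B <- counts / ifelse(visits > 0, visits, NA)
  se <- sqrt(B * (1 - B) / pmax(visits, 1))
  structure(B, method = "empirical", n_visits = visits, se = se,
            low_confidence = visits < min_visits,
            class = c("fate_probabilities", "matrix"))
}

#' Trajectory-averaged dynamic profile of a per-cell quantity
#'
#' Every walk absorbed in `fate` is rescaled to normalized trajectory
#' position `t` in `[0, 1]` (step index over walk length); the per-cell
#' values (gene expression or TF activity) visited at each position are
#' averaged within `n_grid` bins across walks, then smoothed with a centered
#' moving average.
#'
#' @param ensemble a `trajectory_ensemble` with paths.
#' @param values numeric per-cell vector (length = number of cells).
#' @param fate fate name.
#' @param n_grid number of position bins (default 50).
#' @param smooth_window moving-average width in bins (default 5).
#' @param min_walks minimum number of absorbed walks required.
#' @return a `dynamic_profile` data.frame: `t` (bin midpoints), `mean`,
#'   `se`, `n` (contributions per bin).
#' @export
trajectory_profile <- function(ensemble, values, fate, n_grid = 50,
                               smooth_window = 5, min_walks = 10) {
  if (is.null(ensemble$paths))
    stopf("ensemble was simulated with keep_paths = FALSE")
  stopifnot(length(values) == ensemble$n_cells)
  idx <- which(!is.na(ensemble$fate) & ensemble$fate == fate)
  if (length(idx) < min_walks)
    stopf("only %d walk(s) absorbed in fate '%s' (min %d)",
          length(idx), fate, min_walks)
  sums <- numeric(n_grid); sq <- numeric(n_grid); cnt <- numeric(n_grid)
  for (w in idx) {
    path <- ensemble$paths[[w]]
    L <- length(path)
    t <- if (L == 1) 0 else (seq_len(L) - 1) / (L - 1)
    bin <- pmin(floor(t * n_grid) + 1L, n_grid)
    v <- values[path]
    sums <- sums + tapply_sum(v, bin, n_grid)
    sq <- sq + tapply_sum(v^2, bin, n_grid)
    cnt <- cnt + tabulate(bin, n_grid)
  }
  mean_raw <- ifelse(cnt > 0, sums / cnt, NA)
  var_raw <- ifelse(cnt > 1, (sq - cnt * mean_raw^2) / (cnt - 1), NA)
  se <- sqrt(var_raw / pmax(cnt, 1))
  smooth <- moving_average(mean_raw, smooth_window)
  out <- data.frame(t = (seq_len(n_grid) - 0.5) / n_grid,
                    mean = smooth, mean_raw = mean_raw, se = se, n = cnt)
  structure(out, fate = fate, n_walks = length(idx),
            smooth_window = smooth_window,
            class = c("dynamic_profile", "data.frame"))
}

tapply_sum <- function(v, bin, n) {
  out <- numeric(n)
  agg <- rowsum(v, bin)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

moving_average <- function(x, window) {
  if (window <= 1) return(x)
  half <- floor(window / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    j <- max(1, i - half):min(n, i + half)
    mean(x[j], na.rm = TRUE)
  }, numeric(1))
}
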