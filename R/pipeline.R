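#' Pipeline configuration
#'
#' Assembles the per-stage parameters of the end-to-end analysis into one
#' validated list. Every stage seed is derived deterministically from
#' `seed`. Either a raw `sce` (with `motif_targets`/`tf_map` inputs) or a
#' `synthetic_config` must be supplied.
#'
#' @param sce optional raw [SingleCellExperiment] input.
#' @param synthetic optional [synthetic_config()]; when given, the simulate
#'   stage generates the input dataset.
#' @param qc a [qc_config()].
#' @param n_hvg,n_pcs,k_neighbors,cluster_resolution manifold parameters
#'   (defaults 1000 / 15 / 15 / 1). `cluster_resolution` may be a vector:
#'   the resolution whose cluster count is closest to `target_clusters`
#'   (when set) is used.
#' @param target_clusters optional expected number of populations.
#' @param batch_balanced use [batch_balanced_neighbors()] over batches.
#' @param fate_dims,fate_k embedding dimensionality and neighbors for the
#'   fate-simulation graph (defaults 10 / 10).
#' @param sink_quantile fraction of each terminal population's pseudotime
#'   distribution below the absorbing (mature) cells; sinks are the cells at
#'   or beyond this quantile (default 0.75).
#' @param fate_backend layout backend for the fate-graph embedding.
#'   `"pca"` (default) keeps the geometry linear and contiguous; `"umap"`
#'   mirrors analyses that build the fate graph on a 10-dimensional
#'   nonlinear layout, but can fragment sharply separated populations into
#'   islands whose bridge edges distort trajectory routing.
#' @param potential_method biasing field: `"pseudotime"`
#'   ([pseudotime_potential()], default) or `"harmonic"`
#'   ([solve_potential()]).
#' @param beta,n_iterations,max_steps Markov-chain parameters
#'   (defaults 10 / 2000 / NULL = 10x cells).
#' @param n_committed_walks walks per fate in the committed trajectory
#'   ensembles behind the dynamic profiles (default 500).
#' @param marker_sets named list (population -> marker genes) used to
#'   annotate clusters; `progenitor_label` names the source population.
#' @param motif_targets genes x motifs site matrix; `tf_map` named
#'   motif -> TF gene vector.
#' @param lambda ridge penalty for [fit_activities()] (NULL = default).
#' @param n_grid,smooth_window,min_walks trajectory-profile parameters.
#' @param z_min,std_min,cor_min differential-activity thresholds
#'   (defaults 1.4 / 0.004 / 0.7).
#' @param out_dir run directory (default a temp dir).
#' @param seed global seed.
#' @param stages character vector of stages to run.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sce = NULL, synthetic = NULL,
                            qc = qc_config(), n_hvg = 1000, n_pcs = 15,
                            k_neighbors = 15, cluster_resolution = 1,
                            target_clusters = NULL, batch_balanced = FALSE,
                            fate_dims = 10, fate_k = 10,
                            fate_backend = c("pca", "umap"),
                            sink_quantile = 0.75,
                            potential_method = c("pseudotime", "harmonic"),
                            beta = 10,
                            n_iterations = 2000, max_steps = NULL,
                            n_committed_walks = 500,
                            marker_sets = NULL, progenitor_label = "progenitor",
                            motif_targets = NULL, tf_map = NULL,
                            lambda = NULL, n_grid = 50, smooth_window = 5,
                            min_walks = 10, z_min = 1.4, std_min = 0.004,
                            cor_min = 0.7, out_dir = NULL, seed = 1,
                            stages = c("simulate", "qc", "manifold",
                                       "lineage", "fate", "motifs")) {
  if (is.null(sce) && is.null(synthetic))
    stopf("supply either a raw sce or a synthetic_config")
  if (is.null(out_dir)) out_dir <- tempfile("eecfate_run_")
  potential_method <- match.arg(potential_method)
  fate_backend <- match.arg(fate_backend)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Build a pipeline configuration from a YAML file
#'
#' Reads a YAML mapping whose keys are [pipeline_config()] arguments
#' (nested `qc:` and `synthetic:` mappings are passed to [qc_config()] and
#' [synthetic_config()]). Arguments supplied directly override the file.
#'
#' @param path YAML file.
#' @param ... overrides passed on to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path, ...) {
  conf <- yaml::read_yaml(path)
  if (!is.null(conf$qc)) conf$qc <- do.call(qc_config, conf$qc)
  if (!is.null(conf$synthetic))
    conf$synthetic <- do.call(synthetic_config, conf$synthetic)
  overrides <- list(...)
  conf[names(overrides)] <- overrides
  do.call(pipeline_config, conf)
}

stage_seed <- function(seed, stage) {
  # deterministic per-stage seeds, kept inside 32-bit integer range
  (seed * 101 + match(stage, c("simulate", "qc", "manifold", "lineage",
                               "fate", "motifs"))) %% .Machine$integer.max
}

write_manifest <- function(dir, stage, params_hash, files) {
  jsonlite::write_json(
    list(stage = stage, hash = params_hash, files = files,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(dir, paste0(stage, ".manifest.json")), auto_unbox = TRUE)
}

stage_cached <- function(dir, stage, params_hash) {
  mf <- file.path(dir, paste0(stage, ".manifest.json"))
  rds <- file.path(dir, paste0(stage, ".rds"))
  if (!file.exists(mf) || !file.exists(rds)) return(FALSE)
  m <- try(jsonlite::read_json(mf), silent = TRUE)
  !inherits(m, "try-error") && identical(m$hash, params_hash)
}

#' Annotate clusters by marker-program expression
#'
#' Assigns every cluster the population whose marker program has the
#' highest standardized mean expression in that cluster, the in-silico
#' analogue of annotating cell types from known marker genes.
#'
#' @param sce a normalized [SingleCellExperiment].
#' @param labels per-cell cluster labels.
#' @param marker_sets named list population -> marker gene ids.
#' @return named character vector cluster -> population.
#' @export
annotate_clusters <- function(sce, labels, marker_sets) {
  E <- expr_assay(sce)
  labels <- as.character(labels)
  cl <- sort(unique(labels))
  score <- sapply(names(marker_sets), function(p) {
    genes <- intersect(marker_sets[[p]], rownames(E))
    if (!length(genes)) return(rep(NA_real_, length(cl)))
    prog <- Matrix::colSums(E[genes, , drop = FALSE]) / length(genes)
    vapply(cl, function(g) mean(prog[labels == g]), numeric(1))
  })
  score <- scale(score)  # per program across clusters
  setNames(colnames(score)[apply(score, 1, which.max)], cl)
}

run_stage <- function(cfg, stage, compute) {
  h <- digest::digest(list(stage, cfg[setdiff(names(cfg), c("out_dir"))],
                           stage_seed(cfg$seed, stage)))
  rds <- file.path(cfg$out_dir, paste0(stage, ".rds"))
  if (stage_cached(cfg$out_dir, stage, h)) return(readRDS(rds))
  res <- compute()
  saveRDS(res, rds)
  write_manifest(cfg$out_dir, stage, h, basename(rds))
  res
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in order — simulate (optional), QC and
#' normalization, manifold (HVG, PCA, neighbor graph, clustering,
#' annotation), lineage (connectivity, diffusion pseudotime), fate
#' (potential, Markov chain, walks, absorption probabilities), motifs
#' (activities, profiles, lagged correlations, differential selection) —
#' writing each stage's result plus a JSON manifest into the run directory.
#' A stage whose parameter hash matches an existing manifest is reloaded,
#' not recomputed.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list of stage results (`dataset`, `qc`, `manifold`,
#'   `lineage`, `fate`, `motifs`) with `out_dir` attached.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(is(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(out_dir = cfg$out_dir)
  st <- cfg$stages

  ds <- NULL
  if ("simulate" %in% st && !is.null(cfg$synthetic)) {
    ds <- run_stage(cfg, "simulate", function() generate_dataset(cfg$synthetic))
    res$dataset <- ds
    sce <- ds$sce
    if (is.null(cfg$marker_sets)) cfg$marker_sets <- ds$truth$markers
    if (is.null(cfg$motif_targets)) cfg$motif_targets <- ds$truth$site_matrix
    if (is.null(cfg$tf_map)) cfg$tf_map <- ds$truth$tf_map
  } else sce <- cfg$sce
  if (is.null(sce)) stopf("no input data for the qc stage")

  if (!"qc" %in% st) return(invisible(res))
  qc <- run_stage(cfg, "qc", function() {
    fl <- filter_cells(sce, cfg$qc)
    fl$sce <- log_transform(normalize_total(fl$sce, cfg$qc$target_total))
    fl
  })
  res$qc <- qc
  sce <- qc$sce

  if (!"manifold" %in% st) return(invisible(res))
  man <- run_stage(cfg, "manifold", function() {
    hvg <- select_hvg(sce, min(cfg$n_hvg, nrow(sce)))
    pca <- pca_embed(sce, hvg, n_pcs = cfg$n_pcs)
    graph <- if (cfg$batch_balanced)
      batch_balanced_neighbors(pca$coords, colData(sce)$batch, cfg$k_neighbors)
    else knn_graph(pca$coords, cfg$k_neighbors)
    graph <- connect_components(graph)
    seed_m <- stage_seed(cfg$seed, "manifold")
    resolutions <- cfg$cluster_resolution
    labs <- lapply(resolutions, function(r)
      cluster_graph(graph, resolution = r, seed = seed_m))
    pick <- if (!is.null(cfg$target_clusters) && length(resolutions) > 1) {
      which.min(abs(vapply(labs, function(l) length(unique(l)), numeric(1)) -
                      cfg$target_clusters))
    } else 1L
    labels <- labs[[pick]]
    annotation <- if (!is.null(cfg$marker_sets))
      annotate_clusters(sce, labels, cfg$marker_sets) else NULL
    layout <- embed_2d(pca$coords, n_dims = 2, seed = seed_m)
    list(hvg = hvg, pca = pca, graph = graph, labels = labels,
         resolution = resolutions[pick], annotation = annotation,
         layout = layout)
  })
  res$manifold <- man

  if (!"lineage" %in% st) return(invisible(res))
  lin <- run_stage(cfg, "lineage", function() {
    pops <- man$annotation[as.character(man$labels)]
    conn <- paga_connectivity(man$graph, man$labels)
    dmap <- diffusion_map(man$graph,
                          n_components = min(15, nrow(man$pca$coords) - 2))
    root <- select_root(man$graph, pops, cfg$progenitor_label)
    dpt <- diffusion_pseudotime(dmap, root, graph = man$graph)
    list(connectivity = conn, dmap = dmap, root = root,
         pseudotime = dpt$pseudotime, populations = pops)
  })
  res$lineage <- lin

  if (!"fate" %in% st) return(invisible(res))
  fate <- run_stage(cfg, "fate", function() {
    seed_f <- stage_seed(cfg$seed, "fate")
    fate_coords <- embed_2d(man$pca$coords, n_dims = cfg$fate_dims,
                            seed = seed_f, backend = cfg$fate_backend)
    graph <- connect_components(knn_graph(fate_coords, cfg$fate_k))
    pops <- lin$populations
    fates <- setdiff(unique(man$annotation), cfg$progenitor_label)
    sources <- which(pops == cfg$progenitor_label)
    # sinks are the mature end of each lineage: the cells of the fate
    # population beyond the sink_quantile of its pseudotime distribution,
    # so walks traverse the branch instead of being absorbed at its mouth
    sinks <- lapply(setNames(fates, fates), function(f) {
      i <- which(pops == f & is.finite(lin$pseudotime))
      q <- quantile(lin$pseudotime[i], cfg$sink_quantile)
      i[lin$pseudotime[i] >= q]
    })
    pot <- if (identical(cfg$potential_method, "harmonic"))
      solve_potential(graph, sources, sinks)
    else pseudotime_potential(lin$pseudotime, sources, sinks)
    chain <- build_chain(graph, pot, beta = cfg$beta)
    max_steps <- if (is.null(cfg$max_steps)) 10 * nrow(chain$P) else
      cfg$max_steps
    ens <- simulate_walks(chain, sources, cfg$n_iterations,
                          max_steps = max_steps, seed = seed_f)
    # committed trajectory ensembles, one per fate: walks biased by the
    # distance-to-sink potential of that fate, so every lineage gets a
    # profile ensemble of controlled size
    committed <- lapply(seq_along(sinks), function(k) {
      pot_k <- distance_potential(graph, sinks[k], sources = sources)
      chain_k <- build_chain(graph, pot_k, beta = cfg$beta)
      simulate_walks(chain_k, sources, cfg$n_committed_walks,
                     max_steps = max_steps, seed = seed_f + k)
    })
    names(committed) <- names(sinks)
    list(graph = graph, potential = pot, chain = chain, ensemble = ens,
         committed = committed,
         probabilities = absorption_exact(chain),
         empirical = fate_from_ensemble(ens, min_visits = cfg$min_walks),
         sources = sources, sinks = sinks)
  })
  res$fate <- fate

  if (!"motifs" %in% st) return(invisible(res))
  mot <- run_stage(cfg, "motifs", function() {
    N <- cfg$motif_targets
    if (is.null(N)) stopf("motif stage needs a motif_targets matrix")
    N <- N[rownames(sce)[rownames(sce) %in% rownames(N)], , drop = FALSE]
    E <- as.matrix(assay(sce, "logcounts")[rownames(N), , drop = FALSE])
    am <- fit_activities(E, N, lambda = cfg$lambda)
    z <- activity_zscores(am)
    fates <- names(fate$sinks)
    # fates with too few absorbed walks get no profile and fail selection
    # closed inside select_differential
    prof_or_null <- function(values, f)
      tryCatch(trajectory_profile(fate$committed[[f]], values, f,
                                  n_grid = cfg$n_grid,
                                  smooth_window = cfg$smooth_window,
                                  min_walks = cfg$min_walks),
               error = function(e) NULL)
    profiles <- lapply(setNames(rownames(am$A), rownames(am$A)), function(m)
      lapply(setNames(fates, fates), function(f) prof_or_null(am$A[m, ], f)))
    correlations <- lapply(setNames(rownames(am$A), rownames(am$A)),
                           function(m) {
      tf <- cfg$tf_map[[m]]
      if (is.null(tf) || is.na(tf) || !(tf %in% rownames(sce))) return(NULL)
      expr <- as.numeric(assay(sce, "logcounts")[tf, ])
      lapply(setNames(fates, fates), function(f) {
        ep <- prof_or_null(expr, f)
        if (is.null(ep) || is.null(profiles[[m]][[f]])) return(NULL)
        lagged_correlation(ep, profiles[[m]][[f]],
                           role_threshold = cfg$cor_min)
      })
    })
    report <- select_differential(z, profiles, correlations,
                                  z_min = cfg$z_min, std_min = cfg$std_min,
                                  cor_min = cfg$cor_min)
    list(activities = am, z = z, profiles = profiles,
         correlations = correlations, report = report)
  })
  res$motifs <- mot
  invisible(res)
}

#' Summarize a completed run
#'
#' Tabulates the run: QC counts, cluster sizes and annotations, fate
#' probability means per population, and the differential-motif category
#' table (motif counts per specificity set, which always sum to the number
#' of selected motifs).
#'
#' @param res result of [run_pipeline()].
#' @return a list of summary tables of class `pipeline_report`.
#' @export
pipeline_report <- function(res) {
  out <- list()
  if (!is.null(res$qc))
    out$qc <- res$qc$report[c("n_cells_in", "n_cells_kept", "n_genes_kept",
                              "removed_mito", "removed_ercc",
                              "removed_min_genes")]
  if (!is.null(res$manifold)) {
    sizes <- table(res$manifold$labels)
    out$clusters <- data.frame(
      cluster = names(sizes), n_cells = as.integer(sizes),
      population = if (!is.null(res$manifold$annotation))
        unname(res$manifold$annotation[names(sizes)]) else NA)
  }
  if (!is.null(res$fate)) {
    pops <- res$lineage$populations
    B <- res$fate$probabilities
    out$fate_summary <- do.call(rbind, lapply(sort(unique(pops)), function(p)
      data.frame(population = p, t(colMeans(B[pops == p, , drop = FALSE])))))
  }
  if (!is.null(res$motifs)) {
    cats <- attr(res$motifs$report, "categories")
    out$motif_categories <- data.frame(
      specificity = names(cats), n_motifs = as.integer(cats))
    out$n_selected_motifs <- sum(cats)
  }
  structure(out, class = c("pipeline_report", "list"))
}

#' Totals and percentages of a labeled composition
#'
#' Small arithmetic helper behind the report tables: given labeled counts
#' (cells per stage, cells per cluster, motifs per category), returns each
#' count with its percentage of the total.
#'
#' @param counts named numeric vector of nonnegative counts.
#' @return data.frame with label, n, percent; total in attribute `total`.
#' @export
composition_summary <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  total <- sum(counts)
  structure(data.frame(label = if (is.null(names(counts)))
                         as.character(seq_along(counts)) else names(counts),
                       n = as.numeric(counts),
                       percent = if (total > 0) 100 * counts / total else 0,
                       row.names = NULL),
            total = total)
}
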