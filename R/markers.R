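#' Marker-filter configuration
#'
#' Thresholds of the marker filter cascade: Benjamini-Hochberg FDR at most
#' `max_fdr`, log2 fold change at least `min_lfc`, expressed in at least
#' `min_frac_in` of the cells inside the group and in at most `max_frac_out`
#' of the cells outside. Defaults take the permissive ends of the commonly
#' used 15-20% / 60-65% envelopes.
#'
#' @param max_fdr,min_lfc,min_frac_in,max_frac_out thresholds.
#' @return a list of class `marker_filter_config`.
#' @export
marker_filter_config <- function(max_fdr = 0.05, min_lfc = 1.0,
                                 min_frac_in = 0.15, max_frac_out = 0.65) {
  stopifnot(max_fdr > 0, max_fdr < 1,
            min_frac_in >= 0, min_frac_in <= 1,
            max_frac_out >= 0, max_frac_out <= 1)
  structure(list(max_fdr = max_fdr, min_lfc = min_lfc,
                 min_frac_in = min_frac_in, max_frac_out = max_frac_out),
            class = "marker_filter_config")
}

# two-sided Wilcoxon rank-sum p-value; exact for small tie-free groups,
# normal approximation with tie correction otherwise
wilcox_p <- function(x, y) {
  if (max(c(x, y)) == min(c(x, y))) return(1)  # no variation at all
  exact <- length(x) <= 10 && length(y) <= 10 &&
    !anyDuplicated(c(x, y))
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value)
}

#' Rank marker genes for a group
#'
#' Two-sided Wilcoxon rank-sum test per gene of a group against the rest (or
#' against one other group) on normalized log expression, with BH FDR across
#' genes, a pseudocounted log2 fold change of group means on the normalized
#' scale, expressing fractions, and the pass/fail flag of the filter cascade.
#'
#' @param sce a normalized [SingleCellExperiment] (log layer used for the
#'   test; `normcounts` for fold changes).
#' @param labels per-cell group labels.
#' @param group label of the group of interest.
#' @param reference `"rest"` or a specific other label.
#' @param cfg a [marker_filter_config()].
#' @return data.frame with gene, group, p_value, fdr, log_fold_change,
#'   frac_in, frac_out, passed.
#' @export
rank_markers <- function(sce, labels, group, reference = "rest",
                         cfg = marker_filter_config()) {
  labels <- as.character(labels)
  in_idx <- which(labels == group)
  out_idx <- if (identical(reference, "rest")) which(labels != group)
             else which(labels == reference)
  if (length(in_idx) < 2) stopf("group '%s' has fewer than 2 cells", group)
  if (length(out_idx) < 2) stopf("reference has fewer than 2 cells")
  Elog <- as.matrix(expr_assay(sce))
  Enorm <- as.matrix(expr_assay(sce, if ("normcounts" %in% assayNames(sce))
                                       "normcounts" else NULL))
  p <- vapply(seq_len(nrow(Elog)), function(g)
    wilcox_p(Elog[g, in_idx], Elog[g, out_idx]), numeric(1))
  mean_in <- rowMeans(Enorm[, in_idx, drop = FALSE])
  mean_out <- rowMeans(Enorm[, out_idx, drop = FALSE])
  s <- mean(Enorm)  # global-scale pseudocount keeps ratios finite
  lfc <- log2((mean_in + 1e-9 * s) / (mean_out + 1e-9 * s))
  lfc <- pmin(pmax(lfc, -10), 10)
  frac_in <- rowMeans(Enorm[, in_idx, drop = FALSE] > 0)
  frac_out <- rowMeans(Enorm[, out_idx, drop = FALSE] > 0)
  fdr <- p.adjust(p, method = "BH")
  passed <- fdr <= cfg$max_fdr & lfc >= cfg$min_lfc &
    frac_in >= cfg$min_frac_in & frac_out <= cfg$max_frac_out
  data.frame(gene = rownames(Elog), group = group, p_value = p, fdr = fdr,
             log_fold_change = lfc, frac_in = frac_in, frac_out = frac_out,
             passed = passed, row.names = NULL)
}

#' Pairwise differential expression across a condition, per population
#'
#' For each population, tests one condition against the other within that
#' population (e.g. organoid versus transplanted-organoid cells of the same
#' cell type), with the same statistics and filter semantics as
#' [rank_markers()].
#'
#' @param sce a normalized [SingleCellExperiment].
#' @param labels per-cell population labels.
#' @param condition per-cell condition labels (exactly 2 levels used).
#' @param populations populations to test (default all).
#' @param cfg a [marker_filter_config()].
#' @return data.frame as [rank_markers()] plus `population` and `condition`
#'   columns (the condition whose enrichment the row reports).
#' @export
pairwise_de <- function(sce, labels, condition, populations = NULL,
                        cfg = marker_filter_config()) {
  labels <- as.character(labels)
  condition <- as.character(condition)
  lev <- sort(unique(condition))
  if (length(lev) != 2) stopf("condition must have exactly 2 levels")
  if (is.null(populations)) populations <- sort(unique(labels))
  do.call(rbind, lapply(populations, function(pop) {
    idx <- which(labels == pop)
    cond_pop <- condition[idx]
    for (l in lev)
      if (sum(cond_pop == l) < 2)
        stopf("population '%s' has < 2 cells in condition '%s'", pop, l)
    sub <- sce[, idx]
    do.call(rbind, lapply(lev, function(l) {
      tab <- rank_markers(sub, cond_pop, group = l,
                          reference = setdiff(lev, l), cfg = cfg)
      tab$population <- pop
      tab$condition <- l
      tab$group <- NULL
      tab
    }))
  }))
}

#' Score cells for a gene program against a matched background
#'
#' Per cell: mean expression over `gene_set` minus mean expression over a
#' background set sampled from expression-level bins matched to the set
#' (`ctrl_size` background genes per set member), so the score is centered
#' for programs with no coordinated deviation.
#'
#' @param sce a normalized [SingleCellExperiment].
#' @param gene_set character vector of gene ids.
#' @param n_bins number of average-expression bins (default 25).
#' @param ctrl_size background genes drawn per set gene (default 50).
#' @param seed RNG seed for the background draw.
#' @return named numeric vector of per-cell scores.
#' @export
score_gene_set <- function(sce, gene_set, n_bins = 25, ctrl_size = 50,
                           seed = 0) {
  if (!length(gene_set)) stopf("gene_set is empty")
  E <- expr_assay(sce)
  gene_set <- intersect(gene_set, rownames(E))
  if (!length(gene_set)) stopf("no gene_set members found in the data")
  avg <- Matrix::rowSums(E) / ncol(E)
  bins <- cut(rank(avg, ties.method = "first"),
              breaks = min(n_bins, nrow(E)), labels = FALSE,
              include.lowest = TRUE)
  names(bins) <- rownames(E)
  ctrl <- with_local_seed(seed, {
    unique(unlist(lapply(gene_set, function(g) {
      pool <- names(bins)[bins == bins[g]]
      pool_bg <- setdiff(pool, gene_set)
      if (!length(pool_bg)) pool_bg <- pool  # set covers the whole bin
      sample(pool_bg, min(ctrl_size, length(pool_bg)))
    })))
  })
  set_mean <- Matrix::colSums(E[gene_set, , drop = FALSE]) / length(gene_set)
  ctrl_mean <- Matrix::colSums(E[ctrl, , drop = FALSE]) / length(ctrl)
  setNames(as.numeric(set_mean - ctrl_mean), colnames(E))
}

#' Assign a cell-cycle phase from S and G2/M scores
#'
#' S when the S score is the strictly larger positive score, G2M when the
#' G2/M score is positive and at least the S score (ties go to G2M), else G1.
#'
#' @param s_score,g2m_score numeric vectors of program scores.
#' @return character vector in `{"S", "G2M", "G1"}`.
#' @export
assign_phase <- function(s_score, g2m_score) {
  stopifnot(length(s_score) == length(g2m_score),
            all(is.finite(s_score)), all(is.finite(g2m_score)))
  ifelse(s_score > g2m_score & s_score > 0, "S",
         ifelse(g2m_score >= s_score & g2m_score > 0, "G2M", "G1"))
}

#' Classify cells into cell-cycle phases
#'
#' Convenience wrapper: scores the S and G2/M gene programs with
#' [score_gene_set()] and applies [assign_phase()]. The gene lists are user
#' input (published cycle gene lists, one symbol per line).
#'
#' @param sce a normalized [SingleCellExperiment].
#' @param s_genes,g2m_genes gene id vectors (or files, one id per line).
#' @param ... passed to [score_gene_set()].
#' @return data.frame with s_score, g2m_score, phase per cell.
#' @export
cell_cycle_phase <- function(sce, s_genes, g2m_genes, ...) {
  read_set <- function(x) if (length(x) == 1 && file.exists(x)) readLines(x)
                          else x
  s <- score_gene_set(sce, read_set(s_genes), ...)
  g <- score_gene_set(sce, read_set(g2m_genes), ...)
  data.frame(cell = colnames(sce), s_score = s, g2m_score = g,
             phase = assign_phase(s, g), row.names = NULL)
}
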