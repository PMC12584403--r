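#' Load a raw count matrix with cell and gene annotations
#'
#' Reads a cell x gene raw count table, either as a MatrixMarket triplet file
#' with accompanying gene/cell id files or as a delimited (TSV/CSV) table with
#' cell ids in the first column and gene ids as the header. Mitochondrial
#' genes are flagged by a case-insensitive `mt-` prefix and spike-ins by an
#' `ERCC-` prefix. The result is a [SingleCellExperiment] with genes as rows
#' (the Bioconductor convention), a raw integer `counts` assay, and
#' `is_mito` / `is_ercc` columns in `rowData`.
#'
#' @param path path to the matrix file (`.mtx` triplet or delimited table).
#' @param format `"mtx_triplet"` or `"delimited"`.
#' @param genes_file,cells_file id files for the triplet format (one id per
#'   line); default `genes.tsv` / `cells.tsv` next to the matrix.
#' @param cell_meta optional path to a TSV of per-cell metadata with a
#'   `batch` column (row order = cell order), or a data.frame.
#' @param sep field separator for `format = "delimited"`.
#' @param mito_regex regular expression flagging mitochondrial gene ids.
#' @param ercc_regex regular expression flagging spike-in ids.
#' @return a [SingleCellExperiment] with raw counts.
#' @export
load_counts <- function(path, format = c("mtx_triplet", "delimited"),
                        genes_file = NULL, cells_file = NULL,
                        cell_meta = NULL, sep = "\t",
                        mito_regex = "^(mt|MT|Mt)-", ercc_regex = "^ERCC-") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("matrix file not found: %s", path)
  if (format == "mtx_triplet") {
    if (is.null(genes_file)) genes_file <- file.path(dirname(path), "genes.tsv")
    if (is.null(cells_file)) cells_file <- file.path(dirname(path), "cells.tsv")
    for (f in c(genes_file, cells_file))
      if (!file.exists(f)) stopf("id file not found: %s", f)
    m <- Matrix::readMM(path)
    genes <- readLines(genes_file)
    cells <- readLines(cells_file)
    # accept either orientation; resolve against the id files
    if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
      m <- Matrix::t(m)
    } else if (!(nrow(m) == length(genes) && ncol(m) == length(cells))) {
      stopf(paste0("matrix dimensions %dx%d match neither %s (%d genes) ",
                   "nor %s (%d cells)"), nrow(m), ncol(m),
            genes_file, length(genes), cells_file, length(cells))
    }
    counts <- as(m, "CsparseMatrix")
    dimnames(counts) <- list(genes, cells)
  } else {
    tab <- read.delim(path, sep = sep, row.names = 1, check.names = FALSE)
    counts <- Matrix::t(Matrix(as.matrix(tab), sparse = TRUE))  # genes x cells
  }
  x <- counts@x
  if (any(x < 0) || any(x != round(x)))
    stopf("raw counts in %s must be nonnegative integers", path)
  if (anyDuplicated(rownames(counts))) stopf("duplicate gene ids in %s", path)
  if (anyDuplicated(colnames(counts))) stopf("duplicate cell ids in %s", path)

  rd <- DataFrame(is_mito = grepl(mito_regex, rownames(counts)),
                  is_ercc = grepl(ercc_regex, rownames(counts)),
                  row.names = rownames(counts))
  cd <- DataFrame(row.names = colnames(counts))
  if (!is.null(cell_meta)) {
    meta <- if (is.character(cell_meta)) read.delim(cell_meta, sep = "\t")
            else as.data.frame(cell_meta)
    if (nrow(meta) != ncol(counts))
      stopf("cell metadata has %d rows but matrix has %d cells",
            nrow(meta), ncol(counts))
    if (!"batch" %in% colnames(meta))
      stopf("cell metadata must contain a 'batch' column")
    cd <- DataFrame(meta, row.names = colnames(counts))
  }
  sce <- SingleCellExperiment(assays = list(counts = counts),
                              rowData = rd, colData = cd)
  metadata(sce)$normalized <- FALSE
  sce
}

#' Quality-control configuration
#'
#' Thresholds for [filter_cells()]. Defaults follow common plate-based
#' practice for mouse data: cells are removed when the mitochondrial count
#' fraction is strictly above `max_mito_fraction` (0.20 mouse, 0.50 human),
#' when the spike-in fraction is at or above `max_ercc_fraction` (0.50), or
#' when fewer than `min_genes` non-spike-in genes are detected (500 for
#' late-stage mouse plates, 3000 for E15.5, 1000 for human).
#'
#' @param max_mito_fraction remove cells with mito fraction `>` this value.
#' @param max_ercc_fraction remove cells with spike-in fraction `>=` this value.
#' @param min_genes remove cells detecting `<` this many non-spike-in genes;
#'   either a single number or a named vector keyed by batch label.
#' @param target_total normalization target; `NULL` = median per-cell total.
#' @param drop_zero_genes drop genes with zero counts in all kept cells.
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(max_mito_fraction = 0.20, max_ercc_fraction = 0.50,
                      min_genes = 500, target_total = NULL,
                      drop_zero_genes = FALSE) {
  stopifnot(max_mito_fraction >= 0, max_mito_fraction <= 1,
            max_ercc_fraction >= 0, max_ercc_fraction <= 1,
            all(min_genes >= 0))
  structure(list(max_mito_fraction = max_mito_fraction,
                 max_ercc_fraction = max_ercc_fraction,
                 min_genes = min_genes, target_total = target_total,
                 drop_zero_genes = drop_zero_genes),
            class = "qc_config")
}

qc_stats <- function(sce) {
  counts <- assay(sce, "counts")
  ercc <- rowData(sce)$is_ercc
  mito <- rowData(sce)$is_mito
  total_all <- Matrix::colSums(counts)
  total_bio <- Matrix::colSums(counts[!ercc, , drop = FALSE])
  mito_counts <- Matrix::colSums(counts[mito & !ercc, , drop = FALSE])
  ercc_counts <- Matrix::colSums(counts[ercc, , drop = FALSE])
  list(
    mito_fraction = ifelse(total_bio > 0, mito_counts / total_bio, 0),
    ercc_fraction = ifelse(total_all > 0, ercc_counts / total_all, 0),
    n_detected = Matrix::colSums(counts[!ercc, , drop = FALSE] > 0),
    total_bio = total_bio
  )
}

#' Filter low-quality cells
#'
#' Applies the three plate-based QC rules: mitochondrial fraction strictly
#' above threshold, spike-in fraction at or above threshold, and detected
#' (nonzero, non-spike-in) genes below threshold. The mitochondrial fraction
#' is computed over non-spike-in counts; the spike-in fraction over all
#' counts. Gene set is unchanged unless `drop_zero_genes` is set in `cfg`.
#'
#' @param sce a raw [SingleCellExperiment] from [load_counts()].
#' @param cfg a [qc_config()].
#' @return a list with `sce` (the filtered object) and `report` (a
#'   `qc_report` list of per-filter removal counts).
#' @export
filter_cells <- function(sce, cfg = qc_config()) {
  stopifnot(is(cfg, "qc_config"))
  if (isTRUE(metadata(sce)$normalized))
    stopf("filter_cells expects raw counts (object is already normalized)")
  st <- qc_stats(sce)
  min_genes <- cfg$min_genes
  if (length(min_genes) > 1 || !is.null(names(min_genes))) {
    batch <- as.character(colData(sce)$batch)
    if (is.null(batch)) stopf("per-batch min_genes needs a 'batch' column")
    missing <- setdiff(unique(batch), names(min_genes))
    if (length(missing))
      stopf("min_genes has no entry for batch(es): %s",
            paste(missing, collapse = ", "))
    min_genes <- unname(min_genes[batch])
  }
  fail_mito <- st$mito_fraction > cfg$max_mito_fraction
  fail_ercc <- st$ercc_fraction >= cfg$max_ercc_fraction
  fail_genes <- st$n_detected < min_genes
  keep <- !(fail_mito | fail_ercc | fail_genes)

  report <- structure(list(
    n_cells_in = ncol(sce), n_cells_kept = sum(keep),
    n_genes_kept = nrow(sce),
    removed_mito = sum(fail_mito), removed_ercc = sum(fail_ercc),
    removed_min_genes = sum(fail_genes),
    removed_cells = colnames(sce)[!keep]), class = "qc_report")
  if (!any(keep))
    stop(structure(class = c("eecfate_empty_qc", "error", "condition"),
                   list(message = "all cells removed by QC filters",
                        call = sys.call(-1), report = report)))
  out <- sce[, keep]
  if (isTRUE(cfg$drop_zero_genes)) {
    nz <- Matrix::rowSums(assay(out, "counts")) > 0
    out <- out[nz, ]
    report$n_genes_kept <- sum(nz)
  }
  list(sce = out, report = report)
}

#' Normalize each cell to an equal total count
#'
#' Scales every cell so that its total count over non-spike-in genes equals
#' `target_total` (default: the median per-cell total), the standard
#' equal-depth normalization for plate-based data. Spike-in rows are excluded
#' from the total but scaled by the same per-cell factor. The raw `counts`
#' assay is preserved; the scaled values are stored as `normcounts`.
#'
#' @param sce a [SingleCellExperiment] with raw counts.
#' @param target_total positive target; `NULL` = median non-spike-in total.
#' @return the object with a `normcounts` assay and
#'   `metadata(sce)$normalized = TRUE`.
#' @export
normalize_total <- function(sce, target_total = NULL) {
  counts <- assay(sce, "counts")
  ercc <- rowData(sce)$is_ercc
  if (is.null(ercc)) ercc <- rep(FALSE, nrow(sce))
  totals <- Matrix::colSums(counts[!ercc, , drop = FALSE])
  if (any(totals <= 0))
    stopf("cell(s) with zero non-spike-in total: %s",
          paste(head(colnames(sce)[totals <= 0]), collapse = ", "))
  if (is.null(target_total)) target_total <- median(totals)
  stopifnot(target_total > 0)
  f <- target_total / totals
  nc <- counts %*% Diagonal(x = f)
  dimnames(nc) <- dimnames(counts)
  assay(sce, "normcounts") <- nc
  metadata(sce)$normalized <- TRUE
  metadata(sce)$target_total <- target_total
  sce
}

#' Add a log1p layer of the normalized counts
#'
#' Rank-based tests are transform-invariant but PCA is not, so the log layer
#' is an explicit recorded step: used for embedding and marker statistics,
#' not for the "mean normalized expression" dot-plot summaries.
#'
#' @param sce a normalized [SingleCellExperiment].
#' @return the object with a `logcounts` assay.
#' @export
log_transform <- function(sce) {
  if (!isTRUE(metadata(sce)$normalized))
    stopf("log_transform expects a normalized object; run normalize_total()")
  assay(sce, "logcounts") <- log1p(assay(sce, "normcounts"))
  sce
}
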