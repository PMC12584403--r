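#' Configuration of the synthetic branching-lineage generator
#'
#' Defaults emulate a plate-based (SORT-seq-like) experiment on a
#' differentiating endocrine population: a progenitor pool branching at
#' pseudotime `t_branch` into three terminal fates, negative-binomial counts
#' with log-normal library sizes, ERCC spike-ins, mitochondrial genes with a
#' planted subpopulation of damaged high-mito cells, two batches, and gene
#' expression driven by a known motif-target matrix with known time-varying
#' TF activities (3 driver motifs per fate plus inactive null motifs).
#'
#' @param n_cells,n_genes,n_motifs problem size (defaults 800 / 2000 / 25).
#' @param n_driver_per_fate planted driver motifs per fate (default 3).
#' @param fates terminal fate names.
#' @param t_branch branch-point pseudotime in (0, 1) (default 0.3).
#' @param branch_props terminal-branch proportions (default equal).
#' @param nb_dispersion negative-binomial size parameter (default 2).
#' @param libsize_sdlog log-normal sd of library-size factors (default 0.3).
#' @param n_batches,batch_effect batches and per-gene batch shift sd.
#' @param frac_mito fraction of genes flagged mitochondrial (default 0.02).
#' @param n_ercc number of spike-in genes (default 20).
#' @param n_high_mito planted damaged cells (default 10).
#' @param high_mito_fraction expected mito count fraction of damaged cells
#'   (default 0.75, far enough above the QC thresholds that negative-binomial
#'   count noise cannot pull a damaged cell back under them).
#' @param snr scale of the regulatory signal in gene log-means (default 1).
#' @param targets_per_motif Poisson mean of targets per motif (default 40).
#' @param n_markers_per_pop planted marker genes per population (default 40).
#' @param total_counts expected biological counts per cell (default 5000).
#' @param driver_amplitude activity amplitude of driver motifs (default 1).
#' @param seed generator seed.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cells = 800, n_genes = 2000, n_motifs = 25,
                             n_driver_per_fate = 3,
                             fates = c("EC", "XMD", "LINKSD"),
                             t_branch = 0.3,
                             branch_props = rep(1 / 3, 3),
                             nb_dispersion = 2, libsize_sdlog = 0.3,
                             n_batches = 2, batch_effect = 0.1,
                             frac_mito = 0.02, n_ercc = 20,
                             n_high_mito = 10, high_mito_fraction = 0.75,
                             snr = 1,
                             targets_per_motif = 40,
                             n_markers_per_pop = 40,
                             total_counts = 5000,
                             driver_amplitude = 1, seed = 1) {
  stopifnot(t_branch > 0, t_branch < 1, n_cells > 0, n_genes > 0,
            length(branch_props) == length(fates),
            n_motifs >= n_driver_per_fate * length(fates))
  structure(as.list(environment()), class = "synthetic_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Simulate the planted lineage (branch and pseudotime per cell)
#'
#' Pseudotime is uniform on (0, 1); cells before `t_branch` are progenitors,
#' cells after are assigned to a terminal branch with the configured
#' proportions.
#'
#' @param cfg a [synthetic_config()].
#' @return data.frame with `cell`, `t`, `branch` ("progenitor" or a fate).
#' @export
simulate_lineage <- function(cfg) {
  n <- cfg$n_cells
  t <- runif(n)
  branch <- rep("progenitor", n)
  late <- which(t >= cfg$t_branch)
  if (length(late))
    branch[late] <- sample(cfg$fates, length(late), replace = TRUE,
                           prob = cfg$branch_props)
  data.frame(cell = sprintf("cell%04d", seq_len(n)), t = t, branch = branch,
             stringsAsFactors = FALSE)
}

# driver activation midpoints are staggered within each fate so that
# "which was active first" has a planted ground truth
driver_onsets <- function(cfg) {
  seq(0.4, 0.7, length.out = cfg$n_driver_per_fate)
}

#' Simulate the planted regulatory layer
#'
#' Builds the motif-target site matrix `N*` (targets per motif ~ Poisson,
#' site counts >= 1), the true activity curves `A*` (steep sigmoidal rise on
#' the driver's own branch, low-amplitude white noise for null motifs), a
#' dedicated TF gene per motif whose expression tracks its activity, planted
#' population marker programs, a planted proliferation program, batch
#' shifts, and the resulting per-cell gene log-means.
#'
#' @param cfg a [synthetic_config()].
#' @param lineage result of [simulate_lineage()].
#' @return list with `gene_ids`, `N` (genes x motifs), `A` (motifs x cells),
#'   `log_means` (genes x cells, biological genes), `tf_map`, `markers`,
#'   `drivers` (motif/fate/onset table), `batch`, `cycle_cells`, `is_mito`.
#' @export
simulate_regulation <- function(cfg, lineage) {
  n <- cfg$n_cells
  ng <- cfg$n_genes
  fates <- cfg$fates
  motifs <- sprintf("motif%02d", seq_len(cfg$n_motifs))

  # gene universe: TF genes, marker programs, cycle program, background
  tf_genes <- sprintf("TF.%s", motifs)
  n_mark <- cfg$n_markers_per_pop
  pops <- c("progenitor", fates)
  marker_genes <- lapply(setNames(pops, pops), function(p)
    sprintf("MK.%s.%03d", p, seq_len(n_mark)))
  cycle_genes <- sprintf("CYC.%03d", seq_len(30))
  n_special <- length(tf_genes) + n_mark * length(pops) + length(cycle_genes)
  if (ng <= n_special) stopf("n_genes too small for the planted programs")
  bg_genes <- sprintf("G%04d", seq_len(ng - n_special))
  gene_ids <- c(tf_genes, unlist(marker_genes, use.names = FALSE),
                cycle_genes, bg_genes)

  # mitochondrial flags live on background genes; rename with the mt- prefix
  n_mito <- max(1, round(cfg$frac_mito * ng))
  mito_idx <- length(gene_ids) - seq_len(n_mito) + 1  # last background genes
  gene_ids[mito_idx] <- sub("^G", "mt-G", gene_ids[mito_idx])
  is_mito <- seq_along(gene_ids) %in% mito_idx

  # planted activities
  n_driver <- cfg$n_driver_per_fate
  drivers <- data.frame(
    motif = motifs[seq_len(n_driver * length(fates))],
    fate = rep(fates, each = n_driver),
    onset = rep(driver_onsets(cfg), length(fates)))
  A <- matrix(0, cfg$n_motifs, n, dimnames = list(motifs, lineage$cell))
  for (r in seq_len(nrow(drivers))) {
    on_branch <- lineage$branch == drivers$fate[r]
    A[drivers$motif[r], on_branch] <-
      cfg$driver_amplitude *
      sigmoid((lineage$t[on_branch] - drivers$onset[r]) / 0.04)
  }
  null_motifs <- setdiff(motifs, drivers$motif)
  A[null_motifs, ] <- rnorm(length(null_motifs) * n, sd = 0.05)

  # motif-target matrix over background genes only, so marker and TF
  # programs stay clean readouts
  N <- matrix(0, length(gene_ids), cfg$n_motifs,
              dimnames = list(gene_ids, motifs))
  bg_pool <- which(startsWith(gene_ids, "G") | startsWith(gene_ids, "mt-"))
  for (m in seq_len(cfg$n_motifs)) {
    k <- 0
    while (k == 0) k <- rpois(1, cfg$targets_per_motif)
    tgt <- sample(bg_pool, min(k, length(bg_pool)))
    N[tgt, m] <- rpois(length(tgt), 1) + 1
  }

  # gene log-means: baseline + regulation + markers + cycle + batch
  baseline <- rnorm(length(gene_ids), 0, 1)
  log_means <- matrix(baseline, length(gene_ids), n,
                      dimnames = list(gene_ids, lineage$cell))
  log_means <- log_means + cfg$snr * (N %*% A)
  # TF gene expression tracks its motif's activity (concurrent, scale 2)
  log_means[tf_genes, ] <- log_means[tf_genes, ] + 2 * A
  ramp_on <- function(t, mid, slope = 0.03) sigmoid((t - mid) / slope)
  for (f in fates) {
    on_branch <- as.numeric(lineage$branch == f) *
      ramp_on(lineage$t, cfg$t_branch + 0.075)
    log_means[marker_genes[[f]], ] <-
      log_means[marker_genes[[f]], ] +
      2 * rep(on_branch, each = n_mark)
  }
  prog_prof <- 1 - ramp_on(lineage$t, cfg$t_branch + 0.05)
  log_means[marker_genes[["progenitor"]], ] <-
    log_means[marker_genes[["progenitor"]], ] + 2 * rep(prog_prof, each = n_mark)
  prog_cells <- which(lineage$branch == "progenitor")
  cycle_cells <- sample(prog_cells, max(1, round(0.1 * length(prog_cells))))
  log_means[cycle_genes, cycle_cells] <-
    log_means[cycle_genes, cycle_cells] + 1.5
  batch <- sample(rep_len(sprintf("batch%d", seq_len(cfg$n_batches)), n))
  bshift <- matrix(rnorm(length(gene_ids) * cfg$n_batches,
                         sd = cfg$batch_effect),
                   length(gene_ids), cfg$n_batches)
  log_means <- log_means + bshift[, match(batch, sort(unique(batch)))]

  list(gene_ids = gene_ids, N = N, A = A, log_means = log_means,
       tf_map = setNames(tf_genes, motifs), markers = marker_genes,
       drivers = drivers, batch = batch,
       cycle_cells = lineage$cell[cycle_cells], is_mito = is_mito)
}

#' Sample negative-binomial counts from planted log-means
#'
#' Converts gene log-means to per-cell expected counts (proportions times
#' the expected library), applies log-normal library-size factors, appends
#' ERCC spike-in genes at fixed means independent of cell biology, inflates
#' the mitochondrial proportion of the planted damaged cells to ~60%, and
#' samples `NB(mu, size = nb_dispersion)` counts.
#'
#' @param reg result of [simulate_regulation()].
#' @param cfg a [synthetic_config()].
#' @param lib_factors optional per-cell library factors (default sampled
#'   log-normal; a factor of 0 yields an all-zero cell).
#' @return list with `counts` (genes x cells, spike-ins appended),
#'   `is_mito`, `is_ercc`, `high_mito_cells`, `lib_factors`.
#' @export
sample_counts <- function(reg, cfg, lib_factors = NULL) {
  mu_log <- reg$log_means
  n <- ncol(mu_log)
  stopifnot(all(is.finite(mu_log)))
  prop <- exp(sweep(mu_log, 2, apply(mu_log, 2, max)))
  prop <- sweep(prop, 2, colSums(prop), `/`)
  if (is.null(lib_factors))
    lib_factors <- rlnorm(n, 0, cfg$libsize_sdlog)
  mu <- sweep(prop * cfg$total_counts, 2, lib_factors, `*`)

  # damaged cells: inflate mito means to the configured expected fraction
  high_mito <- character(0)
  if (cfg$n_high_mito > 0) {
    hm <- sample(n, min(cfg$n_high_mito, n))
    high_mito <- colnames(mu_log)[hm]
    hf <- cfg$high_mito_fraction
    for (c in hm) {
      q <- sum(mu[reg$is_mito, c]) / sum(mu[, c])
      if (q > 0 && q < 1) {
        f <- (hf / (1 - hf)) * (1 - q) / q
        mu[reg$is_mito, c] <- mu[reg$is_mito, c] * f
      }
    }
  }
  counts <- matrix(rnbinom(length(mu), mu = mu, size = cfg$nb_dispersion),
                   nrow(mu), ncol(mu), dimnames = dimnames(mu))

  # spike-ins: fixed input amounts, independent of cell size and biology
  ercc_ids <- sprintf("ERCC-%04d", seq_len(cfg$n_ercc))
  ercc_mu <- 0.08 * cfg$total_counts *
    (0.7^(seq_len(cfg$n_ercc) - 1)) / sum(0.7^(seq_len(cfg$n_ercc) - 1))
  ercc <- matrix(rnbinom(cfg$n_ercc * n,
                         mu = rep(ercc_mu, n), size = cfg$nb_dispersion),
                 cfg$n_ercc, n, dimnames = list(ercc_ids, colnames(mu)))
  list(counts = rbind(counts, ercc),
       is_mito = c(reg$is_mito, rep(FALSE, cfg$n_ercc)),
       is_ercc = c(rep(FALSE, nrow(counts)), rep(TRUE, cfg$n_ercc)),
       high_mito_cells = high_mito, lib_factors = lib_factors)
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Composes [simulate_lineage()], [simulate_regulation()] and
#' [sample_counts()] under one seeded generator; the same config and seed
#' reproduce the dataset bit for bit.
#'
#' @param cfg a [synthetic_config()].
#' @return a `synthetic_dataset`: `sce` (raw counts with batch/stage
#'   metadata and mito/spike-in flags), `truth` (branch, pseudotime, fate,
#'   activities, site matrix, TF map, markers, drivers, damaged and cycling
#'   cells), and `cfg`.
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  with_local_seed(cfg$seed, {
    lineage <- simulate_lineage(cfg)
    reg <- simulate_regulation(cfg, lineage)
    cnt <- sample_counts(reg, cfg)
    sce <- SingleCellExperiment(
      assays = list(counts = Matrix(cnt$counts, sparse = TRUE)),
      rowData = DataFrame(is_mito = cnt$is_mito, is_ercc = cnt$is_ercc,
                          row.names = rownames(cnt$counts)),
      colData = DataFrame(batch = reg$batch, row.names = lineage$cell))
    metadata(sce)$normalized <- FALSE
    # transcriptional discretization: a committed cell reads as its branch
    # only once its marker program is at least half induced (the ramp
    # midpoint sits 0.075 past the branch point); before that it is
    # indistinguishable from a progenitor by construction
    expressed <- ifelse(lineage$branch != "progenitor" &
                          lineage$t >= cfg$t_branch + 0.075,
                        lineage$branch, "progenitor")
    truth <- list(
      branch = setNames(lineage$branch, lineage$cell),
      expressed_branch = setNames(expressed, lineage$cell),
      pseudotime = setNames(lineage$t, lineage$cell),
      fate = setNames(ifelse(lineage$branch == "progenitor", NA,
                             lineage$branch), lineage$cell),
      activities = reg$A, site_matrix = reg$N, tf_map = reg$tf_map,
      markers = reg$markers, drivers = reg$drivers,
      high_mito_cells = cnt$high_mito_cells,
      cycle_cells = reg$cycle_cells, lib_factors = cnt$lib_factors)
    structure(list(sce = sce, truth = truth, cfg = cfg),
              class = "synthetic_dataset")
  })
}
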