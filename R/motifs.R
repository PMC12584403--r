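#' Infer per-cell TF (motif) activities by a ridge linear model
#'
#' Models the gene-centered expression of every cell as a linear combination
#' of motif target-site profiles: `E_gc ~ sum_m N_gm A_mc`, solved per cell
#' by ridge-regularized least squares. This evaluates whether a motif's
#' target genes deviate from average expression in a coordinated way while
#' disentangling motifs that share targets. Site columns are standardized
#' (zero mean, unit variance over genes) so activities are on comparable
#' scales; activities are centered per motif across cells. Standard errors
#' come from the per-cell residual variance through the sandwich form
#' `sigma_c^2 (N'N + lambda I)^{-1} N'N (N'N + lambda I)^{-1}`.
#'
#' @param E genes x cells normalized log expression (dense or sparse).
#' @param N genes x motifs nonnegative site-count matrix, gene order
#'   aligned with `E`. All-zero motif columns are dropped with a warning.
#' @param lambda ridge penalty; default `0.1 *` mean eigenvalue of `N'N`
#'   (after standardization). `lambda = 0` requires full column rank.
#' @return an `activity_matrix`: `A` (motifs x cells, centered), `se`
#'   (matching standard errors), `lambda`, `sigma2` (per-cell residual
#'   variance).
#' @export
fit_activities <- function(E, N, lambda = NULL) {
  E <- as.matrix(E)
  N <- as.matrix(N)
  stopifnot(nrow(E) == nrow(N))
  zero <- colSums(N != 0) == 0
  if (any(zero)) {
    warnf("dropping %d all-zero motif column(s)", sum(zero))
    N <- N[, !zero, drop = FALSE]
  }
  m <- ncol(N)
  # standardize site columns; center expression per gene across cells
  N <- scale(N)
  Ec <- E - rowMeans(E)
  G <- crossprod(N)                       # N'N, m x m
  if (is.null(lambda)) lambda <- 0.1 * sum(diag(G)) / m
  if (lambda < 0) stopf("lambda must be nonnegative")
  M <- G + diag(lambda, m)
  if (lambda == 0 && rcond(M) < 1e-12)
    stopf("N'N is rank deficient; use lambda > 0")
  Minv <- solve(M)
  A <- Minv %*% crossprod(N, Ec)          # m x cells
  resid <- Ec - N %*% A
  df <- max(nrow(E) - m, 1)
  sigma2 <- colSums(resid^2) / df
  v <- diag(Minv %*% G %*% Minv)          # per-motif variance factor
  se <- sqrt(outer(pmax(v, 0), sigma2))
  A <- A - rowMeans(A)
  dimnames(A) <- dimnames(se) <- list(colnames(N), colnames(E))
  structure(list(A = A, se = se, lambda = lambda, sigma2 = sigma2),
            class = "activity_matrix")
}

#' Per-motif activity z-scores
#'
#' `z_m = sqrt(mean_c (A_mc / dA_mc)^2)`: the root-mean-square of the
#' error-standardized activities, large when a motif's activity varies
#' across cells well beyond its estimation error.
#'
#' @param am an `activity_matrix`.
#' @return named numeric vector of nonnegative z-scores.
#' @export
activity_zscores <- function(am) {
  sqrt(rowMeans((am$A / am$se)^2))
}

#' Variability of a dynamic profile
#'
#' Population standard deviation of the binned mean-activity values across
#' the trajectory-position grid; flat profiles score 0.
#'
#' @param profile a `dynamic_profile` (or numeric vector of bin means).
#' @return a single nonnegative number.
#' @export
profile_std <- function(profile) {
  x <- if (is.data.frame(profile)) profile$mean else as.numeric(profile)
  x <- x[is.finite(x)]
  if (length(x) < 2) stopf("profile needs at least 2 bins")
  sqrt(mean((x - mean(x))^2))
}

#' Lagged Pearson correlation between expression and activity profiles
#'
#' Pearson correlation between the TF's expression profile and its activity
#' profile at every integer bin shift in `[-max_lag, max_lag]` (positive lag
#' = activity delayed relative to expression), accommodating regulatory
#' delay in either direction. The peak is the largest `|rho|` over the
#' window; its sign calls the role: activator if `rho >= role_threshold`,
#' repressor if `rho <= -role_threshold`, else none. Lags with fewer than
#' `min_overlap` overlapping bins are excluded.
#'
#' @param expr_profile,act_profile equal-length numeric vectors (or
#'   `dynamic_profile`s) on the same fate and grid.
#' @param max_lag largest shift in bins (default 25% of the grid).
#' @param role_threshold `|rho|` needed for an activator/repressor call.
#' @param min_overlap minimum overlapping bins per lag (default 5).
#' @return a `lagged_correlation`: data.frame `lag`/`rho`, plus `peak_rho`,
#'   `peak_lag`, `role`.
#' @export
lagged_correlation <- function(expr_profile, act_profile, max_lag = NULL,
                               role_threshold = 0.7, min_overlap = 5) {
  ex <- if (is.data.frame(expr_profile)) expr_profile$mean
        else as.numeric(expr_profile)
  ac <- if (is.data.frame(act_profile)) act_profile$mean
        else as.numeric(act_profile)
  stopifnot(length(ex) == length(ac))
  n <- length(ex)
  if (is.null(max_lag)) max_lag <- max(1L, floor(0.25 * n))
  lags <- -max_lag:max_lag
  rho <- vapply(lags, function(tau) {
    if (tau >= 0) { a <- ex[seq_len(n - tau)]; b <- ac[seq_len(n - tau) + tau] }
    else { a <- ex[seq_len(n + tau) - tau]; b <- ac[seq_len(n + tau)] }
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < min_overlap) return(NA_real_)
    if (sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
    cor(a[ok], b[ok])
  }, numeric(1))
  valid <- which(!is.na(rho))
  if (!length(valid)) stopf("no lag has enough overlapping bins")
  # peak |rho|; ties broken toward the smallest |lag|
  best <- valid[order(-abs(rho[valid]), abs(lags[valid]))][1]
  peak_rho <- rho[best]
  role <- if (peak_rho >= role_threshold) "activator"
          else if (peak_rho <= -role_threshold) "repressor" else "none"
  structure(list(table = data.frame(lag = lags, rho = rho),
                 peak_rho = peak_rho, peak_lag = lags[best], role = role),
            class = "lagged_correlation")
}

#' Select lineage-specific regulators (differential motif activity)
#'
#' A motif passes a fate when all three criteria hold: activity z-score at
#' least `z_min`, standard deviation of its activity profile over that
#' fate's trajectories at least `std_min`, and peak `|rho|` of the lagged
#' expression-activity correlation at least `cor_min` (defaults 1.4, 0.004,
#' 0.7). The specificity label is the exact set of passing fates; within a
#' fate, motifs are ordered by activation onset (first grid bin where the
#' profile exceeds half its range), so earlier-acting regulators rank first.
#'
#' @param z named per-motif z-score vector ([activity_zscores()]).
#' @param profiles nested list `profiles[[motif]][[fate]]` of
#'   `dynamic_profile`s of motif activity.
#' @param correlations nested list `correlations[[motif]][[fate]]` of
#'   [lagged_correlation()] results (may omit motifs with no mapped TF).
#' @param z_min,std_min,cor_min selection thresholds.
#' @return a `differential_motif_report` data.frame: one row per selected
#'   (motif, fate) with z, profile_std, peak_rho, peak_lag, role, onset bin
#'   and onset rank, plus a `specificity` label per motif; attribute
#'   `categories` tabulates motifs per specificity set.
#' @export
select_differential <- function(z, profiles, correlations,
                                z_min = 1.4, std_min = 0.004, cor_min = 0.7) {
  motifs <- names(z)
  stopifnot(!is.null(motifs))
  rows <- list()
  for (m in motifs) {
    for (f in names(profiles[[m]])) {
      prof <- profiles[[m]][[f]]
      lc <- correlations[[m]][[f]]
      if (is.null(prof) || is.null(lc)) {
        warnf("missing profile or correlation for motif %s, fate %s", m, f)
        next
      }
      ps <- profile_std(prof)
      pass <- z[[m]] >= z_min && ps >= std_min && abs(lc$peak_rho) >= cor_min
      if (!pass) next
      x <- if (is.data.frame(prof)) prof$mean else as.numeric(prof)
      half <- min(x, na.rm = TRUE) + 0.5 * diff(range(x, na.rm = TRUE))
      onset <- which(x > half)[1]
      rows[[length(rows) + 1]] <- data.frame(
        motif = m, fate = f, z = z[[m]], profile_std = ps,
        peak_rho = lc$peak_rho, peak_lag = lc$peak_lag, role = lc$role,
        onset_bin = onset)
    }
  }
  rep_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif = character(0), fate = character(0), z = numeric(0),
               profile_std = numeric(0), peak_rho = numeric(0),
               peak_lag = integer(0), role = character(0),
               onset_bin = integer(0))
  if (nrow(rep_df)) {
    spec <- tapply(rep_df$fate, rep_df$motif,
                   function(f) paste(sort(unique(f)), collapse = "+"))
    rep_df$specificity <- unname(spec[rep_df$motif])
    rep_df <- rep_df[order(rep_df$fate, rep_df$onset_bin, rep_df$motif), ]
    rep_df$onset_rank <- stats::ave(rep_df$onset_bin, rep_df$fate,
                                    FUN = function(x) rank(x, ties.method = "first"))
  } else {
    rep_df$specificity <- character(0)
    rep_df$onset_rank <- integer(0)
  }
  cats <- if (nrow(rep_df))
    table(vapply(split(rep_df$fate, rep_df$motif),
                 function(f) paste(sort(unique(f)), collapse = "+"),
                 character(1)))
  else table(character(0))
  structure(rep_df, categories = cats,
            thresholds = c(z = z_min, std = std_min, cor = cor_min),
            class = c("differential_motif_report", "data.frame"))
}

#' Read a motif-target matrix from a long-format TSV
#'
#' Expects columns `gene`, `motif`, `count` (nonnegative site counts) and
#' returns a genes x motifs matrix aligned to `gene_ids`, with an optional
#' motif-to-TF-gene map (columns `motif`, `tf_gene`).
#'
#' @param path TSV with gene, motif, count columns.
#' @param gene_ids gene universe to align rows to.
#' @param tf_map_path optional TSV mapping motifs to TF gene ids.
#' @return list with `N` (genes x motifs) and `tf_map` (named character).
#' @export
read_motif_targets <- function(path, gene_ids, tf_map_path = NULL) {
  tab <- read.delim(path)
  stopifnot(all(c("gene", "motif", "count") %in% colnames(tab)))
  if (any(tab$count < 0)) stopf("negative site counts in %s", path)
  motifs <- sort(unique(tab$motif))
  N <- matrix(0, length(gene_ids), length(motifs),
              dimnames = list(gene_ids, motifs))
  keep <- tab$gene %in% gene_ids
  N[cbind(match(tab$gene[keep], gene_ids),
          match(tab$motif[keep], motifs))] <- tab$count[keep]
  tf_map <- NULL
  if (!is.null(tf_map_path)) {
    mp <- read.delim(tf_map_path)
    tf_map <- setNames(mp$tf_gene, mp$motif)
  }
  list(N = N, tf_map = tf_map)
}
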