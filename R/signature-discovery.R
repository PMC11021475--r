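#' PCA of a log expression matrix
#'
#' Singular value decomposition of the gene-centered matrix (samples as
#' observations, genes as variables; no scaling to unit variance). A
#' deterministic sign convention is applied: within each component the
#' largest-magnitude gene loading is made positive, removing the arbitrary
#' sign freedom of the decomposition.
#'
#' @param x An `expr_matrix` with `unit = "log"`, typically restricted to
#'   the top-variance genes (see [select_top_variance_genes()]).
#' @param n_components Number of components to retain; at most
#'   `min(n_genes, n_samples - 1)`.
#' @return A list of class `pca_result`: `scores` (samples x PCs),
#'   `loadings` (genes x PCs, orthonormal columns),
#'   `explained_variance_fraction` (per retained PC, of total variance).
#' @export
run_pca <- function(x, n_components = 3) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$unit != "log") stop("PCA expects log-transformed data")
  n_max <- min(nrow(x$values), ncol(x$values) - 1)
  if (n_components > n_max)
    stop("n_components must be <= min(n_genes, n_samples - 1) = ", n_max)
  obs <- t(x$values)                      # samples x genes
  pc <- stats::prcomp(obs, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  loadings <- pc$rotation[, k, drop = FALSE]
  scores <- pc$x[, k, drop = FALSE]
  # sign convention: dominant loading positive per PC
  flip <- vapply(k, function(j) {
    l <- loadings[, j]
    sign(l[which.max(abs(l))]) < 0
  }, logical(1))
  loadings[, flip] <- -loadings[, flip]
  scores[, flip] <- -scores[, flip]
  evf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_fraction = evf[k]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d genes, %d PCs (var: %s)\n",
              nrow(x$scores), nrow(x$loadings), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
                    collapse = ", ")))
  invisible(x)
}

#' Per-sample enrichment of a gene-set collection
#'
#' Scores every set of a collection in every sample with the
#' unidirectional rank score ([singscore_up()]); each sample is scored
#' independently of the rest of the cohort. Sets with no genes in the
#' universe yield an `NA` column with a warning.
#'
#' @param tpm An `expr_matrix` with `unit = "tpm"`.
#' @param sets A `geneset_collection`.
#' @param centered Passed to [singscore_up()].
#' @return Numeric matrix, samples x sets.
#' @export
score_genesets_per_sample <- function(tpm, sets, centered = FALSE) {
  stopifnot(inherits(tpm, "expr_matrix"), inherits(sets, "geneset_collection"))
  out <- matrix(NA_real_, nrow = ncol(tpm$values), ncol = length(sets),
                dimnames = list(colnames(tpm$values), names(sets)))
  for (nm in names(sets)) {
    up <- sets[[nm]]$up
    if (!any(up %in% rownames(tpm$values))) {
      warning("gene set '", nm, "' has no genes in the universe; scores set to NA")
      next
    }
    out[, nm] <- vapply(colnames(tpm$values), function(s)
      singscore_up(tpm$values[, s], up, centered = centered)$score,
      numeric(1))
  }
  out
}

#' Spearman correlation of PC coordinates with gene-set enrichment
#'
#' @param pca A `pca_result`.
#' @param set_scores Samples x sets score matrix from
#'   [score_genesets_per_sample()] (same samples as the PCA).
#' @param pcs Integer vector of PC indices to correlate; default `1:3`.
#' @return A list of class `pc_geneset_correlation` with `rho` (sets x
#'   PCs Spearman matrix; `NA` where a score vector is constant) and
#'   `cluster_labels` (filled by [cluster_genesets()]).
#' @export
correlate_pcs_with_genesets <- function(pca, set_scores, pcs = 1:3) {
  stopifnot(inherits(pca, "pca_result"))
  if (!identical(rownames(pca$scores), rownames(set_scores)))
    stop("PCA and score matrix must cover the same samples in the same order")
  if (any(pcs > ncol(pca$scores))) stop("requested PC beyond retained components")
  rho <- matrix(NA_real_, nrow = ncol(set_scores), ncol = length(pcs),
                dimnames = list(colnames(set_scores), paste0("PC", pcs)))
  for (j in seq_along(pcs)) {
    pc_coord <- pca$scores[, pcs[j]]
    for (i in seq_len(ncol(set_scores))) {
      y <- set_scores[, i]
      if (any(is.na(y)) || stats::sd(y) == 0 || stats::sd(pc_coord) == 0) next
      rho[i, j] <- stats::cor(pc_coord, y, method = "spearman")
    }
  }
  structure(list(rho = rho, pcs = pcs, cluster_labels = NULL),
            class = "pc_geneset_correlation")
}

#' Hierarchical clustering of gene sets by PC-correlation profile
#'
#' Agglomerative clustering (complete linkage) of gene-set rows of the
#' correlation matrix on Euclidean distance, with the tree cut at `k`
#' clusters. Deterministic for fixed input.
#'
#' @param corr A `pc_geneset_correlation`.
#' @param k Number of clusters; default 4.
#' @return The input with `cluster_labels` filled (named integer vector).
#' @export
cluster_genesets <- function(corr, k = 4) {
  stopifnot(inherits(corr, "pc_geneset_correlation"))
  rho <- corr$rho
  if (any(is.na(rho))) stop("missing correlations among clustered sets")
  if (k > nrow(rho)) stop("k exceeds the number of gene sets")
  hc <- stats::hclust(stats::dist(rho, method = "euclidean"),
                      method = "complete")
  corr$cluster_labels <- stats::cutree(hc, k = k)
  corr
}

#' Identify the immune axis among candidate PCs
#'
#' Over the PCs of the correlation matrix, returns the PC maximizing the
#' absolute mean Spearman rho across the named immune/inflammatory sets,
#' with direction the sign of that mean. Ties in the absolute mean are
#' broken toward the lowest PC index. An exclusivity diagnostic (ratio of
#' the winning absolute mean to the runner-up) is reported.
#'
#' @param corr A `pc_geneset_correlation`.
#' @param immune_set_names Character vector naming the immune probe sets
#'   (must all be rows of the correlation matrix).
#' @return A list: `pc_index` (integer, in the PC numbering of `corr`),
#'   `direction` (`"positive"` or `"negative"`), `mean_rho` (per PC),
#'   `exclusivity`.
#' @export
identify_immune_axis <- function(corr, immune_set_names) {
  stopifnot(inherits(corr, "pc_geneset_correlation"))
  missing <- setdiff(immune_set_names, rownames(corr$rho))
  if (length(missing))
    stop("immune sets not scored: ", paste(missing, collapse = ", "))
  sub <- corr$rho[immune_set_names, , drop = FALSE]
  mean_rho <- colMeans(sub)
  if (all(is.na(mean_rho) | mean_rho == 0))
    stop("no immune axis detected (all mean correlations zero or missing)")
  abs_mean <- abs(mean_rho)
  abs_mean[is.na(abs_mean)] <- -Inf
  best <- which.max(abs_mean)              # which.max takes the first on ties
  runner_up <- max(abs_mean[-best])
  exclusivity <- if (is.finite(runner_up) && runner_up > 0)
    abs_mean[best] / runner_up else Inf
  list(pc_index = corr$pcs[best],
       direction = if (mean_rho[best] >= 0) "positive" else "negative",
       mean_rho = mean_rho, exclusivity = unname(exclusivity))
}

#' Select signature genes by loading sign
#'
#' Returns all PCA-input genes whose loading on the identified immune PC
#' has the sign matching `direction` (strictly; zero loadings excluded).
#' This is the unsupervised rule that turns the immune axis into a gene
#' signature: no supervised filtering, the full sign-consistent gene list
#' is kept.
#'
#' @param pca A `pca_result`.
#' @param pc_index Index of the immune PC.
#' @param direction `"positive"` or `"negative"`.
#' @return A list of class `signature`: `gene_ids`, `source_pc`,
#'   `direction`, `provenance` (counts of positive/negative/zero loadings).
#' @export
select_signature <- function(pca, pc_index, direction = c("positive", "negative")) {
  stopifnot(inherits(pca, "pca_result"))
  direction <- match.arg(direction)
  if (pc_index > ncol(pca$loadings)) stop("pc_index beyond retained components")
  l <- pca$loadings[, pc_index]
  genes <- if (direction == "positive") names(l)[l > 0] else names(l)[l < 0]
  if (!length(genes)) stop("no genes with ", direction, " loading on PC", pc_index)
  structure(list(gene_ids = genes, source_pc = pc_index, direction = direction,
                 provenance = list(n_positive = sum(l > 0),
                                   n_negative = sum(l < 0),
                                   n_zero = sum(l == 0),
                                   n_pca_genes = length(l))),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("signature: %d genes (%s loadings on PC%d)\n",
              length(x$gene_ids), x$direction, x$source_pc))
  invisible(x)
}

#' Unsupervised immune-signature discovery pipeline
#'
#' Runs the full discovery chain on raw counts: median-of-ratios
#' normalization, log transform, top-variance gene selection, PCA,
#' per-sample gene-set enrichment on TPM, PC-gene-set Spearman
#' correlation, immune-axis identification from named immune probe sets,
#' and loading-sign gene selection.
#'
#' @param counts An `expr_matrix` of counts with gene lengths.
#' @param sets A `geneset_collection` of probe sets (hallmark-like).
#' @param immune_set_names Names of the immune/inflammatory probe sets.
#' @param fraction Top-variance fraction for the PCA gene set; default 0.10.
#' @param n_components PCs to retain; default 3 (candidate axes 1-3).
#' @param k Clusters for the gene-set dendrogram; default 4.
#' @return A list with `signature`, `axis`, `pca`, `correlation`,
#'   `set_scores`, `pca_genes`, `tpm`.
#' @export
discover_signature <- function(counts, sets, immune_set_names,
                               fraction = 0.10, n_components = 3, k = 4) {
  stopifnot(inherits(counts, "expr_matrix"))
  norm <- normalize_counts(counts)
  logm <- log_stabilize(norm)
  pca_genes <- select_top_variance_genes(logm, fraction = fraction)
  pca <- run_pca(subset_genes(logm, pca_genes), n_components = n_components)
  tpm <- compute_tpm(counts)
  set_scores <- score_genesets_per_sample(tpm, sets)
  corr <- correlate_pcs_with_genesets(pca, set_scores,
                                      pcs = seq_len(n_components))
  corr <- cluster_genesets(corr, k = min(k, nrow(corr$rho)))
  axis <- identify_immune_axis(corr, immune_set_names)
  sig <- select_signature(pca, axis$pc_index, axis$direction)
  list(signature = sig, axis = axis, pca = pca, correlation = corr,
       set_scores = set_scores, pca_genes = pca_genes, tpm = tpm)
}
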