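#' Default marker sets for bucket cataloging
#'
#' Immune cells are flagged by PTPRC (CD45); tumor cells by a melanoma
#' marker panel (SOX10, S100A1, MITF, MLANA, PMEL, TYR).
#'
#' @return Named list with `immune` and `tumor` character vectors.
#' @export
default_marker_sets <- function() {
  list(immune = "PTPRC",
       tumor = c("SOX10", "S100A1", "MITF", "MLANA", "PMEL", "TYR"))
}

#' Assign one cell to a broad bucket
#'
#' Two-gate rule with fixed precedence: a cell is `immune` if its
#' capped-rank score ([ucell_score()]) for the immune marker set is
#' positive; otherwise `tumor` if the tumor marker-set score is positive;
#' otherwise `stroma`. Precedence means a cell coexpressing immune and
#' tumor markers is called immune.
#'
#' @param cell_values Named numeric vector of one cell's expression.
#' @param marker_sets List with `immune` and `tumor` gene vectors;
#'   default [default_marker_sets()].
#' @param r_max Rank cap for the per-cell score; default 1500.
#' @return One of `"immune"`, `"tumor"`, `"stroma"`.
#' @export
assign_bucket <- function(cell_values, marker_sets = default_marker_sets(),
                          r_max = 1500) {
  for (set_name in c("immune", "tumor")) {
    genes <- marker_sets[[set_name]]
    if (!any(genes %in% names(cell_values)))
      stop("marker set '", set_name, "' absent from the gene universe")
  }
  if (ucell_score(cell_values, marker_sets$immune, r_max = r_max) > 0)
    return("immune")
  if (ucell_score(cell_values, marker_sets$tumor, r_max = r_max) > 0)
    return("tumor")
  "stroma"
}

#' Catalog all cells of a count matrix into broad buckets
#'
#' @param counts Gene-by-cell matrix (dense or `Matrix` sparse) with gene
#'   rownames and cell-barcode colnames.
#' @param sample_ids Per-cell sample labels (one per column).
#' @param marker_sets,r_max Passed to [assign_bucket()].
#' @return Data frame: `cell_id`, `sample_id`, `bucket`.
#' @export
catalog_cells <- function(counts, sample_ids,
                          marker_sets = default_marker_sets(), r_max = 1500) {
  if (length(sample_ids) != ncol(counts))
    stop("one sample id per cell is required")
  genes <- rownames(counts)
  for (set_name in c("immune", "tumor"))
    if (!any(marker_sets[[set_name]] %in% genes))
      stop("marker set '", set_name, "' absent from the gene universe")
  buckets <- vapply(seq_len(ncol(counts)), function(j) {
    v <- as.numeric(counts[, j])
    names(v) <- genes
    assign_bucket(v, marker_sets = marker_sets, r_max = r_max)
  }, character(1))
  data.frame(cell_id = colnames(counts), sample_id = sample_ids,
             bucket = buckets, stringsAsFactors = FALSE)
}

#' Per-sample cell-type proportions
#'
#' @param annotations Data frame with `sample_id` and `bucket` (or any
#'   cell-type column named by `type_col`).
#' @param type_col Column holding the cell-type label; default
#'   `"bucket"`.
#' @return Numeric matrix, samples x cell types; rows sum to 1.
#' @export
proportions_per_sample <- function(annotations, type_col = "bucket") {
  if (!nrow(annotations)) stop("no cells")
  tab <- table(annotations$sample_id, annotations[[type_col]])
  if (any(rowSums(tab) == 0)) stop("sample with no cells")
  prop <- sweep(unclass(tab), 1, rowSums(tab), "/")
  prop
}

#' Composition test between score groups
#'
#' For each cell type, per-sample proportions are variance-stabilized
#' with the arcsin square root transform and compared between the high
#' and low groups with a two-sample t-test. Fold enrichment is the ratio
#' of mean (untransformed) proportions, high over low. P-values are
#' FDR-adjusted across cell types. Degenerate cases (zero variance in
#' the transformed values) yield `p = 1` when the group means agree and
#' `NA` with a warning otherwise.
#'
#' @param proportions Samples x cell-types matrix (rows sum to 1), as
#'   from [proportions_per_sample()].
#' @param group_labels Per-sample `"high"` / `"low"` labels (named or in
#'   row order); each group needs >= 2 samples.
#' @return Data frame: `cell_type`, `fold_enrichment`, `p_value`, `fdr`.
#' @export
proportion_test <- function(proportions, group_labels) {
  if (!is.null(names(group_labels)))
    group_labels <- group_labels[rownames(proportions)]
  if (length(group_labels) != nrow(proportions))
    stop("one group label per sample is required")
  high <- group_labels == "high"
  low <- group_labels == "low"
  if (sum(high) < 2 || sum(low) < 2)
    stop("each group requires at least two samples")
  rows <- lapply(colnames(proportions), function(ct) {
    p <- proportions[, ct]
    t_high <- asin(sqrt(p[high])); t_low <- asin(sqrt(p[low]))
    fold <- if (mean(p[low]) > 0) mean(p[high]) / mean(p[low]) else NA_real_
    pv <- if (stats::sd(c(t_high, t_low)) == 0) {
      1
    } else if (stats::sd(t_high) == 0 && stats::sd(t_low) == 0) {
      warning("degenerate variance for cell type '", ct, "'; p set to NA")
      NA_real_
    } else {
      stats::t.test(t_high, t_low)$p.value
    }
    data.frame(cell_type = ct, fold_enrichment = fold, p_value = pv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "fdr")
  out
}

#' Rank-sum differential expression between score groups
#'
#' Per gene: two-sided Wilcoxon rank-sum test of high versus low cells,
#' with `log2fc = log2((mean_high + 1) / (mean_low + 1))` on the supplied
#' (normalized) expression; positive log2fc means higher in the high
#' group. P-values are FDR-adjusted across genes and the table is
#' filtered to `|log2fc| >= lfc_min` and `fdr < fdr_max`.
#'
#' @param expression Gene-by-cell matrix of normalized expression.
#' @param group_labels Per-cell `"high"` / `"low"` labels.
#' @param lfc_min Absolute log2 fold-change filter; default 0.5.
#' @param fdr_max FDR filter; default 0.05.
#' @param return_all If `TRUE`, return the unfiltered table with a
#'   `retained` flag instead.
#' @return Data frame: `gene_id`, `log2fc`, `p_value`, `fdr` (and
#'   `retained` when `return_all = TRUE`), ordered by `fdr`.
#' @export
wilcoxon_de <- function(expression, group_labels, lfc_min = 0.5,
                        fdr_max = 0.05, return_all = FALSE) {
  if (length(group_labels) != ncol(expression))
    stop("one group label per cell is required")
  high <- group_labels == "high"
  low <- group_labels == "low"
  if (!any(high) || !any(low)) stop("both groups must be non-empty")
  expression <- as.matrix(expression)
  rows <- lapply(seq_len(nrow(expression)), function(i) {
    x <- expression[i, high]; y <- expression[i, low]
    pv <- if (length(unique(c(x, y))) == 1) 1 else
      suppressWarnings(stats::wilcox.test(x, y)$p.value)
    data.frame(gene_id = rownames(expression)[i],
               log2fc = log2((mean(x) + 1) / (mean(y) + 1)),
               p_value = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "fdr")
  out$retained <- abs(out$log2fc) >= lfc_min & out$fdr < fdr_max
  out <- out[order(out$fdr, -abs(out$log2fc)), ]
  rownames(out) <- NULL
  if (return_all) out else {
    res <- out[out$retained, setdiff(colnames(out), "retained")]
    rownames(res) <- NULL
    res
  }
}
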