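#' Construct an expression matrix
#'
#' Light container for a gene-by-sample expression matrix with an explicit
#' unit and optional gene lengths. Rows are genes, columns are samples.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). Values must be finite and,
#'   for non-log units, non-negative.
#' @param unit One of `"counts"`, `"normalized_counts"`, `"tpm"`, `"log"`.
#' @param gene_lengths Optional positive integer vector of gene lengths in
#'   base pairs, one per row (named or in row order). Required for
#'   [compute_tpm()].
#'
#' @details Duplicate gene ids are tolerated only for `unit = "counts"`
#'   (raw count tables routinely carry duplicates after identifier
#'   conversion); collapse them with [aggregate_duplicate_genes()] before
#'   any downstream step. Sample ids must always be unique.
#'
#' @return An object of class `expr_matrix`: a list with elements
#'   `values`, `unit` and `gene_lengths`.
#' @export
expr_matrix <- function(values,
                        unit = c("counts", "normalized_counts", "tpm", "log"),
                        gene_lengths = NULL) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (anyDuplicated(rownames(values)) && unit != "counts")
    stop("duplicate gene ids are only allowed for unit = 'counts'")
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (unit != "log" && any(values < 0))
    stop("expression values must be >= 0 for unit '", unit, "'")
  if (!is.null(gene_lengths)) {
    if (!is.null(names(gene_lengths))) {
      missing <- setdiff(rownames(values), names(gene_lengths))
      if (length(missing))
        stop("gene_lengths missing for ", length(missing), " genes")
      gene_lengths <- gene_lengths[rownames(values)]
    }
    if (length(gene_lengths) != nrow(values))
      stop("gene_lengths must have one entry per gene")
    if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0))
      stop("gene lengths must be positive")
    gene_lengths <- stats::setNames(as.numeric(gene_lengths), rownames(values))
  }
  structure(list(values = values, unit = unit, gene_lengths = gene_lengths),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [unit: %s]%s\n",
              nrow(x$values), ncol(x$values), x$unit,
              if (is.null(x$gene_lengths)) "" else " (+lengths)"))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Sum counts of rows sharing a gene identifier
#'
#' Rows with the same gene id (e.g. after identifier conversion) are
#' collapsed by summation, keeping first-appearance order. Gene lengths, if
#' present, keep the first value observed for each id.
#'
#' @param x An `expr_matrix` with `unit = "counts"`.
#' @return An `expr_matrix` of counts with unique gene ids.
#' @export
aggregate_duplicate_genes <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$unit != "counts") stop("aggregation is defined on raw counts")
  ids <- rownames(x$values)
  if (!anyDuplicated(ids)) return(x)
  agg <- rowsum(x$values, group = ids, reorder = FALSE)
  lengths <- x$gene_lengths
  if (!is.null(lengths)) lengths <- lengths[!duplicated(ids)]
  expr_matrix(agg, unit = "counts", gene_lengths = lengths)
}

#' Transcripts per million
#'
#' Standard length-normalized within-sample unit: per sample,
#' `rate_g = count_g / (length_g / 1000)` and
#' `TPM_g = 1e6 * rate_g / sum(rates)`. Columns of the result sum to 1e6
#' for every sample with at least one nonzero count.
#'
#' @param x An `expr_matrix` of counts with gene lengths.
#' @return An `expr_matrix` with `unit = "tpm"`.
#' @export
compute_tpm <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$unit != "counts") stop("TPM is computed from raw counts")
  if (is.null(x$gene_lengths)) stop("gene lengths are required for TPM")
  if (anyDuplicated(rownames(x$values)))
    stop("aggregate duplicate gene ids before computing TPM")
  rates <- x$values / (x$gene_lengths / 1000)
  totals <- colSums(rates)
  zero <- totals == 0
  if (any(zero)) {
    warning("sample(s) with all-zero counts: ",
            paste(colnames(x$values)[zero], collapse = ", "))
    totals[zero] <- 1  # leaves those columns all-zero
  }
  tpm <- sweep(rates, 2, totals, "/") * 1e6
  expr_matrix(tpm, unit = "tpm", gene_lengths = x$gene_lengths)
}

#' Median-of-ratios size factors
#'
#' Per-sample size factors computed with the median-of-ratios rule: a
#' reference pseudo-sample is built as the per-gene geometric mean over
#' samples (using genes with positive counts in every sample) and each
#' sample's factor is the median of its count-to-reference ratios over
#' those genes.
#'
#' @param x An `expr_matrix` of counts with at least two samples.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors_median_of_ratios <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$unit != "counts") stop("size factors are estimated from raw counts")
  if (ncol(x$values) < 2) stop("at least two samples are required")
  all_pos <- rowSums(x$values > 0) == ncol(x$values)
  if (!any(all_pos))
    stop("no gene has nonzero counts in all samples")
  v <- x$values[all_pos, , drop = FALSE]
  log_ref <- rowMeans(log(v))
  sf <- apply(v, 2, function(col) exp(stats::median(log(col) - log_ref)))
  sf
}

#' Normalize counts by size factors
#'
#' @param x An `expr_matrix` of counts.
#' @param size_factors Optional precomputed factors; estimated with
#'   [size_factors_median_of_ratios()] when omitted.
#' @return An `expr_matrix` with `unit = "normalized_counts"`.
#' @export
normalize_counts <- function(x, size_factors = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.null(size_factors)) size_factors <- size_factors_median_of_ratios(x)
  if (length(size_factors) != ncol(x$values))
    stop("one size factor per sample is required")
  norm <- sweep(x$values, 2, size_factors, "/")
  expr_matrix(norm, unit = "normalized_counts", gene_lengths = x$gene_lengths)
}

#' Log transformation of normalized counts
#'
#' Applies `log2(x + 1)`, a monotone variance-dampening transform used as
#' the substrate for PCA. Rank order within every sample is preserved, so
#' all downstream rank-based scores are unaffected by the choice.
#'
#' @param x An `expr_matrix` with `unit = "normalized_counts"`.
#' @return An `expr_matrix` with `unit = "log"`.
#' @export
log_stabilize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$unit != "normalized_counts")
    stop("log_stabilize expects median-of-ratios normalized counts")
  expr_matrix(log2(x$values + 1), unit = "log", gene_lengths = x$gene_lengths)
}

#' Select the most variant genes
#'
#' Returns the `ceiling(fraction * n_genes)` genes with the largest
#' variance across samples; ties are broken by input row order.
#'
#' @param x An `expr_matrix` with `unit = "log"`.
#' @param fraction Fraction of genes to keep, in (0, 1]; default 0.10.
#' @return Character vector of gene ids.
#' @export
select_top_variance_genes <- function(x, fraction = 0.10) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$unit != "log") stop("variance selection expects log-transformed data")
  if (!(fraction > 0 && fraction <= 1)) stop("'fraction' must be in (0, 1]")
  if (ncol(x$values) < 2) stop("variance requires at least two samples")
  v <- apply(x$values, 1, stats::var)
  n_keep <- ceiling(fraction * nrow(x$values))
  rownames(x$values)[order(-v)[seq_len(n_keep)]]  # stable order breaks ties
}

#' Subset an expression matrix by gene ids
#'
#' @param x An `expr_matrix`.
#' @param genes Character vector of gene ids to keep (order preserved).
#' @return An `expr_matrix` restricted to `genes`.
#' @export
subset_genes <- function(x, genes) {
  stopifnot(inherits(x, "expr_matrix"))
  missing <- setdiff(genes, rownames(x$values))
  if (length(missing))
    stop("genes absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  expr_matrix(x$values[genes, , drop = FALSE], unit = x$unit,
              gene_lengths = x$gene_lengths[genes])
}

#' Read / write a genes-by-samples TSV
#'
#' The TSV carries a header row of sample ids and gene ids in the first
#' column (named `gene_id`).
#'
#' @param path File path.
#' @param unit Expression unit of the stored values.
#' @param gene_lengths Optional lengths passed through to [expr_matrix()].
#' @return `read_expression_tsv` returns an `expr_matrix`;
#'   `write_expression_tsv` returns `path` invisibly.
#' @export
read_expression_tsv <- function(path, unit = "counts", gene_lengths = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "gene_id") stop("first column must be 'gene_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  expr_matrix(m, unit = unit, gene_lengths = gene_lengths)
}

#' @rdname read_expression_tsv
#' @param x An `expr_matrix` to write.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a gene-lengths TSV (columns gene_id, length_bp)
#'
#' @param path File path.
#' @return `read_gene_lengths_tsv` returns a named numeric vector.
#' @export
read_gene_lengths_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$length_bp), df$gene_id)
}

#' @rdname read_gene_lengths_tsv
#' @param lengths Named vector of gene lengths in base pairs.
#' @export
write_gene_lengths_tsv <- function(lengths, path) {
  utils::write.table(
    data.frame(gene_id = names(lengths), length_bp = as.integer(lengths)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
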