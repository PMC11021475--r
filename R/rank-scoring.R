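#' Rank genes within one sample
#'
#' Ascending ranks 1..N with average ranks on ties: the substrate of all
#' cohort-independent single-sample scores in this package.
#'
#' @param values Numeric vector of per-gene expression for one sample.
#' @return Numeric vector of ranks (same names as `values`).
#' @export
rank_within_sample <- function(values) {
  if (!length(values)) stop("at least one gene is required")
  rank(values, ties.method = "average")
}

#' Unidirectional single-sample gene-set score
#'
#' Rank-based expected-upregulated score of a gene set within one sample's
#' transcriptome. Set genes are ranked ascending within the sample; the
#' mean rank is rescaled so that a set occupying the top ranks scores 1
#' and a set occupying the bottom ranks scores 0:
#' \deqn{score = \frac{\bar r - (n_s + 1)/2}{(2N - n_s + 1)/2 - (n_s + 1)/2}}
#' where \eqn{\bar r} is the mean rank of the \eqn{n_s} set genes among
#' \eqn{N} universe genes. The score depends on expression only through
#' ranks, so it is invariant under any strictly monotone within-sample
#' transform and needs no cohort context.
#'
#' @param sample_values Named numeric vector: one sample's expression over
#'   the gene universe (e.g. a TPM column).
#' @param up_set Character vector of expected-upregulated gene ids. Genes
#'   absent from the universe are dropped (count recorded in the result).
#' @param centered If `TRUE` subtract 0.5, mapping the score to
#'   \eqn{[-0.5, 0.5]}; default `FALSE` (score in \eqn{[0, 1]}).
#' @return A list of class `sample_score`: `score`, `mode`, `centered`,
#'   `set_size_used`, `n_dropped`.
#' @export
singscore_up <- function(sample_values, up_set, centered = FALSE) {
  if (is.null(names(sample_values)))
    stop("'sample_values' must be named by gene id")
  up_set <- unique(up_set)
  in_universe <- up_set[up_set %in% names(sample_values)]
  n_dropped <- length(up_set) - length(in_universe)
  n_s <- length(in_universe)
  if (n_s == 0) stop("gene set has empty intersection with the universe")
  N <- length(sample_values)
  if (N <= n_s) stop("gene universe must be larger than the set")
  r <- rank_within_sample(sample_values)
  score <- .singscore_from_ranks(r[in_universe], N)
  if (centered) score <- score - 0.5
  structure(list(score = unname(score), mode = "unidirectional",
                 centered = centered, set_size_used = n_s,
                 n_dropped = n_dropped),
            class = "sample_score")
}

.singscore_from_ranks <- function(set_ranks, N) {
  n_s <- length(set_ranks)
  min_mean <- (n_s + 1) / 2
  max_mean <- (2 * N - n_s + 1) / 2
  (mean(set_ranks) - min_mean) / (max_mean - min_mean)
}

#' Bidirectional single-sample gene-set score
#'
#' For signatures with expected-upregulated and expected-downregulated
#' components. The up component is scored as in [singscore_up()]; the down
#' component is scored identically on reversed ranks (`rank -> N + 1 -
#' rank`, i.e. low expression of a down gene counts as concordant). The
#' total is the sum of the two components; with `centered = TRUE` it lies
#' in \eqn{[-1, 1]}.
#'
#' @inheritParams singscore_up
#' @param down_set Character vector of expected-downregulated gene ids;
#'   must be non-empty and disjoint from `up_set` (use [singscore_up()]
#'   for unidirectional signatures - an empty down set is rejected, not
#'   silently reduced).
#' @return A `sample_score` with components `score` (total), `up_score`,
#'   `down_score`.
#' @export
singscore_bidirectional <- function(sample_values, up_set, down_set,
                                    centered = FALSE) {
  if (is.null(names(sample_values)))
    stop("'sample_values' must be named by gene id")
  if (!length(down_set))
    stop("bidirectional mode requires a non-empty down set")
  if (length(intersect(up_set, down_set)))
    stop("up and down sets must be disjoint")
  up <- unique(up_set); down <- unique(down_set)
  up_in <- up[up %in% names(sample_values)]
  down_in <- down[down %in% names(sample_values)]
  if (!length(up_in) || !length(down_in))
    stop("both set components must intersect the universe")
  N <- length(sample_values)
  if (N <= max(length(up_in), length(down_in)))
    stop("gene universe must be larger than each set component")
  r <- rank_within_sample(sample_values)
  up_score <- .singscore_from_ranks(r[up_in], N)
  down_score <- .singscore_from_ranks(N + 1 - r[down_in], N)
  if (centered) { up_score <- up_score - 0.5; down_score <- down_score - 0.5 }
  structure(list(score = unname(up_score + down_score),
                 up_score = unname(up_score), down_score = unname(down_score),
                 mode = "bidirectional", centered = centered,
                 set_size_used = length(up_in) + length(down_in),
                 n_dropped = length(up) - length(up_in) +
                   length(down) - length(down_in)),
            class = "sample_score")
}

#' @export
print.sample_score <- function(x, ...) {
  cat(sprintf("sample_score [%s%s]: %.4f (n_set = %d)\n", x$mode,
              if (x$centered) ", centered" else "", x$score, x$set_size_used))
  invisible(x)
}

#' Score an immune signature across samples (UMIS-style)
#'
#' Applies the unidirectional rank score of a discovered signature to every
#' sample of a TPM matrix, yielding one continuous immune score per sample.
#' Each sample is scored independently, so scores are stable under cohort
#' composition changes and monotone per-sample transforms.
#'
#' @param tpm An `expr_matrix` with `unit = "tpm"`.
#' @param signature A `signature` object (see [select_signature()]) or a
#'   character vector of gene ids.
#' @param centered Passed to [singscore_up()].
#' @return A data.frame with columns `sample_id`, `score`,
#'   `set_size_used`.
#' @export
umis_score <- function(tpm, signature, centered = FALSE) {
  stopifnot(inherits(tpm, "expr_matrix"))
  if (tpm$unit != "tpm")
    warning("signature scoring is defined on TPM input; got unit '",
            tpm$unit, "'")
  genes <- if (inherits(signature, "signature")) signature$gene_ids
           else as.character(signature)
  res <- lapply(colnames(tpm$values), function(s) {
    sc <- singscore_up(tpm$values[, s], genes, centered = centered)
    data.frame(sample_id = s, score = sc$score,
               set_size_used = sc$set_size_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Split scores into high and low groups at the median
#'
#' `high` means strictly above the cohort median; scores at or below the
#' median (including median ties) are `low`.
#'
#' @param scores Numeric vector of per-sample scores (names preserved).
#' @return Character vector of `"high"` / `"low"` labels.
#' @export
dichotomize_by_median <- function(scores) {
  if (length(scores) < 2) stop("at least two samples are required")
  m <- stats::median(scores)
  stats::setNames(ifelse(scores > m, "high", "low"), names(scores))
}

#' Capped-rank per-cell gene-set score
#'
#' Mann-Whitney-style signature score for a single cell: genes are ranked
#' descending by expression (average ranks on ties), ranks beyond `r_max`
#' are capped at `r_max + 1`, and
#' \deqn{U = \sum_i r'_i - n(n+1)/2, \qquad score = 1 - U / (n \cdot r_{max})}
#' over the \eqn{n} set genes with capped ranks \eqn{r'_i}. A set whose
#' genes all fall beyond the cap is clamped to exactly 0 (the raw formula
#' would leave a small positive artifact of \eqn{(n-1)/(2 r_{max})}),
#' which makes "score > 0" mean "at least one signature gene inside the
#' rank cap".
#'
#' @param cell_values Named numeric vector of one cell's expression.
#' @param gene_set Character vector of signature gene ids.
#' @param r_max Rank cap; default 1500.
#' @return Numeric score in \eqn{[0, 1]}.
#' @export
ucell_score <- function(cell_values, gene_set, r_max = 1500) {
  if (is.null(names(cell_values)))
    stop("'cell_values' must be named by gene id")
  genes <- unique(gene_set)
  genes <- genes[genes %in% names(cell_values)]
  if (!length(genes)) stop("gene set has empty intersection with the universe")
  if (r_max < length(genes))
    stop("r_max must be at least the gene set size")
  r <- rank(-cell_values, ties.method = "average")
  set_r <- r[genes]
  if (all(set_r > r_max)) return(0)
  set_r[set_r > r_max] <- r_max + 1
  n <- length(genes)
  u <- sum(set_r) - n * (n + 1) / 2
  max(0, min(1, 1 - u / (n * r_max)))
}
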