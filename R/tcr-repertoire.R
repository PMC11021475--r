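#' Tabulate clonotypes by chain and amino-acid CDR3
#'
#' A clonotype is identified by (sample, chain, amino-acid CDR3); V/J
#' gene usage is ignored. Duplicate rows are summed. Rows whose CDR3
#' contains characters outside the 20 standard amino acids are rejected
#' with a warning. AIRR-style column aliases are accepted
#' (`junction_aa` for `cdr3_aa`, `duplicate_count` for `count`).
#'
#' @param rows Data frame with columns `sample_id`, `chain` (`TRA` /
#'   `TRB`), `cdr3_aa`, `count` (positive integers).
#' @return Tabulated data frame with unique (sample, chain, cdr3_aa)
#'   rows.
#' @export
tabulate_clonotypes <- function(rows) {
  alias <- c(junction_aa = "cdr3_aa", duplicate_count = "count")
  for (a in names(alias))
    if (a %in% colnames(rows) && !(alias[[a]] %in% colnames(rows)))
      colnames(rows)[colnames(rows) == a] <- alias[[a]]
  need <- c("sample_id", "chain", "cdr3_aa", "count")
  missing <- setdiff(need, colnames(rows))
  if (length(missing))
    stop("clonotype table lacks columns: ", paste(missing, collapse = ", "))
  if (!nrow(rows))
    return(rows[, need])
  if (any(rows$count < 1)) stop("clone counts must be positive")
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", rows$cdr3_aa)
  if (any(!ok)) {
    warning(sum(!ok), " row(s) with malformed CDR3 rejected")
    rows <- rows[ok, , drop = FALSE]
  }
  agg <- stats::aggregate(count ~ sample_id + chain + cdr3_aa, data = rows,
                          FUN = sum)
  agg <- agg[order(agg$sample_id, agg$chain, agg$cdr3_aa), need]
  rownames(agg) <- NULL
  agg
}

#' Shannon diversity of clone counts
#'
#' `H = -sum(p_i * ln(p_i))` with clone frequencies `p_i`; natural-log
#' units. Scale-invariant in counts and permutation-invariant in clone
#' order.
#'
#' @param counts Positive clone counts of one repertoire.
#' @return Non-negative numeric `H` (0 for a single clone).
#' @export
shannon_diversity <- function(counts) {
  if (!length(counts)) stop("at least one clone is required")
  if (any(counts <= 0)) stop("clone counts must be positive")
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Clonality (one minus Pielou's evenness)
#'
#' `1 - H / ln(S)` for richness `S >= 2`; 0 for a perfectly even
#' repertoire, approaching 1 as a single clone dominates. Undefined
#' (`NA`) for `S <= 1`; such samples are excluded upstream (see
#' [filter_low_richness()]).
#'
#' @param counts Positive clone counts of one repertoire.
#' @return Numeric in \eqn{[0, 1]}, or `NA` if fewer than two clonotypes.
#' @export
clonality <- function(counts) {
  if (length(counts) < 2) return(NA_real_)
  1 - shannon_diversity(counts) / log(length(counts))
}

#' Per-sample, per-chain repertoire metrics
#'
#' @param table A tabulated clonotype table (see
#'   [tabulate_clonotypes()]).
#' @return Data frame with columns `sample_id`, `chain`, `richness`,
#'   `shannon`, `clonality`, `excluded` (`TRUE` when richness <= 1 makes
#'   clonality undefined).
#' @export
repertoire_metrics <- function(table) {
  if (!nrow(table))
    return(data.frame(sample_id = character(), chain = character(),
                      richness = integer(), shannon = numeric(),
                      clonality = numeric(), excluded = logical()))
  key <- interaction(table$sample_id, table$chain, drop = TRUE)
  rows <- lapply(split(table, key), function(d) {
    s <- nrow(d)
    data.frame(sample_id = d$sample_id[1], chain = d$chain[1],
               richness = s, shannon = shannon_diversity(d$count),
               clonality = clonality(d$count), excluded = s <= 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$chain), ]
  rownames(out) <- NULL
  out
}

#' Exclude samples with undefinable clonality
#'
#' Samples with one or zero detected unique clonotypes for a chain are
#' excluded from that chain's diversity/clonality analysis; exclusion is
#' per chain, so a sample dropped for TRA can be kept for TRB.
#'
#' @param metrics Output of [repertoire_metrics()].
#' @return List with `kept` and `excluded` data frames
#'   (kept + excluded = input, per chain).
#' @export
filter_low_richness <- function(metrics) {
  list(kept = metrics[!metrics$excluded, , drop = FALSE],
       excluded = metrics[metrics$excluded, , drop = FALSE])
}

#' Public/private clonotype sharing across samples
#'
#' A clonotype is public when present in at least two samples, private
#' otherwise.
#'
#' @param table A tabulated clonotype table covering >= 2 samples.
#' @param chain Chain to analyze (`"TRA"` or `"TRB"`).
#' @return List with `clonotypes` (data.frame: `cdr3_aa`, `n_samples`,
#'   `status`) and `occurrence_histogram` (table of clonotype counts by
#'   number of samples shared).
#' @export
sharing_summary <- function(table, chain = "TRB") {
  d <- table[table$chain == chain, , drop = FALSE]
  if (length(unique(table$sample_id)) < 2)
    stop("sharing requires at least two samples")
  occ <- tapply(d$sample_id, d$cdr3_aa, function(s) length(unique(s)))
  df <- data.frame(cdr3_aa = names(occ), n_samples = as.integer(occ),
                   status = ifelse(occ >= 2, "public", "private"),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  list(clonotypes = df, occurrence_histogram = table(df$n_samples))
}

#' Paired pre/post repertoire differences
#'
#' Per-sample (post - pre) differences of Shannon diversity and
#' clonality, e.g. source metastasis versus post-expansion TIL product;
#' the output feeds a paired signed-rank test.
#'
#' @param pre,post Outputs of [repertoire_metrics()] on the same samples
#'   and chain(s).
#' @return Data frame: `sample_id`, `chain`, `delta_shannon`,
#'   `delta_clonality`.
#' @export
diversity_delta <- function(pre, post) {
  key_pre <- paste(pre$sample_id, pre$chain)
  key_post <- paste(post$sample_id, post$chain)
  if (!setequal(key_pre, key_post))
    stop("pre and post metrics must cover the same (sample, chain) pairs")
  post <- post[match(key_pre, key_post), ]
  data.frame(sample_id = pre$sample_id, chain = pre$chain,
             delta_shannon = post$shannon - pre$shannon,
             delta_clonality = post$clonality - pre$clonality,
             stringsAsFactors = FALSE)
}

#' Read / write a clonotype TSV (sample_id, chain, cdr3_aa, count)
#'
#' @param path File path.
#' @return `read_clonotype_tsv` returns a tabulated clonotype table.
#' @export
read_clonotype_tsv <- function(path) {
  tabulate_clonotypes(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_clonotype_tsv
#' @param table Clonotype table to write.
#' @export
write_clonotype_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
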