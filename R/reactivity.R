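#' Effective assay background from the two control conditions
#'
#' A reactivity readout is compared against two controls: TIL cultured
#' alone (spontaneous activation) and TIL cocultured with autologous
#' antigen-presenting cells (non-specific reactivity). The effective
#' background combines the two; the default takes their maximum, the
#' conservative choice. `"sum"` and `"apc_only"` are provided as
#' alternatives since the combination rule is an assay-design choice.
#'
#' @param til_alone,til_apc Non-negative control measurements.
#' @param rule Combination rule: `"max"` (default), `"sum"`, `"apc_only"`.
#' @return Numeric effective background (vectorized).
#' @export
effective_background <- function(til_alone, til_apc,
                                 rule = c("max", "sum", "apc_only")) {
  rule <- match.arg(rule)
  if (any(til_alone < 0) || any(til_apc < 0)) stop("controls must be >= 0")
  switch(rule,
         max = pmax(til_alone, til_apc),
         sum = til_alone + til_apc,
         apc_only = til_apc)
}

#' Classify a TIL culture as tumor reactive
#'
#' A culture is tumor reactive if its 4-1BB expression exceeds 1% of CD3+
#' cells and is at least twice the effective background, or its IFN-gamma
#' release exceeds 100 pg/ml and is at least twice the effective
#' background. The absolute gates are strict (`>`); the twice-background
#' comparisons are inclusive (`>=`), so a zero background leaves only the
#' absolute gate binding.
#'
#' @param p41bb 4-1BB+ percentage of CD3+ cells after tumor coculture.
#' @param p41bb_bg Effective 4-1BB background (see
#'   [effective_background()]).
#' @param ifng IFN-gamma release in pg/ml after tumor coculture.
#' @param ifng_bg Effective IFN-gamma background.
#' @param p41bb_min,ifng_min Absolute gates; defaults 1 (%) and 100
#'   (pg/ml).
#' @param fold Background multiple required; default 2.
#' @return Logical (vectorized): `TRUE` = reactive.
#' @export
classify_culture <- function(p41bb, p41bb_bg, ifng, ifng_bg,
                             p41bb_min = 1, ifng_min = 100, fold = 2) {
  if (any(c(p41bb, p41bb_bg, ifng, ifng_bg) < 0))
    stop("measurements must be >= 0")
  (p41bb > p41bb_min & p41bb >= fold * p41bb_bg) |
    (ifng > ifng_min & ifng >= fold * ifng_bg)
}

#' Classify every culture of a reactivity table
#'
#' @param table Data frame with columns `sample_id`, `culture_id`,
#'   `p41bb`, `p41bb_til_alone`, `p41bb_til_apc`, `ifng`,
#'   `ifng_til_alone`, `ifng_til_apc`.
#' @param background_rule Passed to [effective_background()].
#' @return The table with added columns `p41bb_bg`, `ifng_bg`,
#'   `reactive`.
#' @export
classify_reactivity_table <- function(table, background_rule = "max") {
  need <- c("sample_id", "culture_id", "p41bb", "p41bb_til_alone",
            "p41bb_til_apc", "ifng", "ifng_til_alone", "ifng_til_apc")
  missing <- setdiff(need, colnames(table))
  if (length(missing))
    stop("reactivity table lacks columns: ", paste(missing, collapse = ", "))
  table$p41bb_bg <- effective_background(table$p41bb_til_alone,
                                         table$p41bb_til_apc,
                                         rule = background_rule)
  table$ifng_bg <- effective_background(table$ifng_til_alone,
                                        table$ifng_til_apc,
                                        rule = background_rule)
  table$reactive <- classify_culture(table$p41bb, table$p41bb_bg,
                                     table$ifng, table$ifng_bg)
  table
}

#' Percent tumor-reactive TIL cultures per metastasis
#'
#' `100 * (reactive cultures) / (total cultures)` for each sample.
#'
#' @param table A classified reactivity table (see
#'   [classify_reactivity_table()]); must contain a logical `reactive`
#'   column.
#' @param sample_id Optional single sample to evaluate; default all.
#' @return Named numeric vector of percentages in \eqn{[0, 100]}.
#' @export
percent_reactive <- function(table, sample_id = NULL) {
  if (!"reactive" %in% colnames(table))
    stop("classify the table first (no 'reactive' column)")
  if (!is.null(sample_id)) {
    table <- table[table$sample_id %in% sample_id, , drop = FALSE]
    if (!nrow(table)) stop("no cultures for sample ", sample_id)
  }
  out <- tapply(table$reactive, table$sample_id,
                function(r) 100 * mean(r))
  stats::setNames(as.numeric(out), names(out))
}

#' Spearman correlation of a predictor with an outcome
#'
#' @param scores,outcomes Paired per-sample numeric vectors, `n >= 3`.
#' @return List with `rho` and two-sided `p` (both `NA` if either vector
#'   is constant).
#' @export
spearman_predictor <- function(scores, outcomes) {
  if (length(scores) != length(outcomes)) stop("inputs must be paired")
  if (length(scores) < 3) stop("at least 3 pairs are required")
  if (stats::sd(scores) == 0 || stats::sd(outcomes) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  ct <- suppressWarnings(
    stats::cor.test(scores, outcomes, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' ROC curve and trapezoid AUC
#'
#' The curve sweeps all distinct score thresholds (equal scores grouped),
#' which for a single continuous predictor is equivalent to the ROC of a
#' univariate logistic model since the logistic map is monotone in the
#' predictor. AUC is the trapezoid-rule area, identical to the fraction
#' of concordant positive/negative pairs with ties counted one half.
#'
#' @param scores Numeric predictor values.
#' @param labels Logical (or coercible 0/1) outcome labels; both classes
#'   must be present.
#' @return List with `points` (data.frame of `fpr`, `tpr`, one row per
#'   threshold plus the (0,0) origin) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("inputs must be paired")
  if (any(is.na(scores)) || any(is.na(labels))) stop("missing values")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & !labels), numeric(1))
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Benchmark biomarkers against TIL reactivity
#'
#' For each candidate predictor: Spearman rho (with two-sided p) against
#' the continuous percent-reactive outcome, and trapezoid AUC for
#' classifying samples at the percent-reactive threshold (default >=
#' 33%). P-values are FDR-adjusted across predictors.
#'
#' @param predictors Named list of per-sample numeric vectors (all over
#'   the same samples as `outcomes`).
#' @param outcomes Per-sample percent-reactive values.
#' @param reactive_threshold Percent-reactive cutoff defining the
#'   positive class; default 33.
#' @return Data frame with one row per predictor: `predictor`,
#'   `spearman_rho`, `spearman_p`, `spearman_fdr`, `auc`,
#'   `threshold_used`, `n_samples`.
#' @export
benchmark_predictors <- function(predictors, outcomes,
                                 reactive_threshold = 33) {
  if (is.null(names(predictors)) || any(names(predictors) == ""))
    stop("predictors must be named")
  labels <- outcomes >= reactive_threshold
  rows <- lapply(names(predictors), function(nm) {
    x <- predictors[[nm]]
    if (length(x) != length(outcomes))
      stop("predictor '", nm, "' not aligned with outcomes")
    sp <- spearman_predictor(x, outcomes)
    data.frame(predictor = nm, spearman_rho = sp$rho, spearman_p = sp$p,
               auc = roc_auc(x, labels)$auc,
               threshold_used = reactive_threshold,
               n_samples = length(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$spearman_fdr <- stats::p.adjust(out$spearman_p, method = "fdr")
  out[, c("predictor", "spearman_rho", "spearman_p", "spearman_fdr",
          "auc", "threshold_used", "n_samples")]
}

#' Clinical response threshold from nonresponder scores
#'
#' Returns the median score of the nonresponder group, the cutoff used to
#' dichotomize scores for outcome analyses.
#'
#' @param scores Per-sample numeric scores.
#' @param responder_flags Logical vector, `TRUE` = responder; at least
#'   one nonresponder required.
#' @return Numeric threshold.
#' @export
select_response_threshold <- function(scores, responder_flags) {
  if (length(scores) != length(responder_flags)) stop("inputs must be paired")
  nr <- scores[!responder_flags]
  if (!length(nr)) stop("no nonresponders")
  stats::median(nr)
}
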