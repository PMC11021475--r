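#' Configuration of the synthetic cohort generator
#'
#' The generator plants a latent per-sample inflammation level `theta` in
#' [0, 1] that drives (i) a program of immune genes in the bulk counts,
#' (ii) the probability that a TIL culture is tumor reactive through a
#' logistic link, (iii) repertoire richness, and (iv) the immune cell
#' fraction of the single-cell compartment. Decoy covariance programs
#' (metabolic / liver-like) are planted alongside so that signature
#' discovery has to find the immune axis rather than merely the dominant
#' one. All effect sizes are artifact choices with documented defaults;
#' see the package vignette.
#'
#' @param n_samples Cohort size; default 60.
#' @param n_genes Gene universe size; default 2000. The universe always
#'   contains the seven bucket marker genes (PTPRC and the melanoma
#'   panel).
#' @param n_immune_genes Planted immune program size; default 150.
#' @param n_decoy_programs,decoy_program_size Number and size of decoy
#'   programs; defaults 2 and 100.
#' @param immune_effect Log2-scale mean shift of immune genes at
#'   `theta = 1`; default 2.
#' @param decoy_effect Log2-scale shift of decoy programs at latent
#'   factor 1; default 1 (weaker than the immune program).
#' @param nb_dispersion Negative-binomial dispersion (`size =
#'   1/dispersion`); default 0.1.
#' @param baseline_log_mean_range Range of per-gene baseline log2 means;
#'   default `c(3, 8)`.
#' @param n_cultures_per_sample TIL cultures per metastasis; default 24.
#' @param reactivity_slope,reactivity_intercept Logistic link from theta
#'   to the per-culture reactivity probability; defaults 6 and -3.
#' @param repertoire_clones_range Range of unique clonotype numbers;
#'   default `c(2, 150)`.
#' @param repertoire_decay Geometric clone-size decay probability;
#'   default 0.15.
#' @param n_cells_per_sample Cells per profiled sample; default 300.
#' @param seed Global integer seed; per-component substreams are derived
#'   from it so every stage can be regenerated independently.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 60, n_genes = 2000,
                          n_immune_genes = 150, n_decoy_programs = 2,
                          decoy_program_size = 100, immune_effect = 2,
                          decoy_effect = 1, nb_dispersion = 0.1,
                          baseline_log_mean_range = c(3, 8),
                          n_cultures_per_sample = 24,
                          reactivity_slope = 6, reactivity_intercept = -3,
                          repertoire_clones_range = c(2, 150),
                          repertoire_decay = 0.15,
                          n_cells_per_sample = 300, seed = 1) {
  cfg <- list(n_samples = n_samples, n_genes = n_genes,
              n_immune_genes = n_immune_genes,
              n_decoy_programs = n_decoy_programs,
              decoy_program_size = decoy_program_size,
              immune_effect = immune_effect, decoy_effect = decoy_effect,
              nb_dispersion = nb_dispersion,
              baseline_log_mean_range = baseline_log_mean_range,
              n_cultures_per_sample = n_cultures_per_sample,
              reactivity_slope = reactivity_slope,
              reactivity_intercept = reactivity_intercept,
              repertoire_clones_range = repertoire_clones_range,
              repertoire_decay = repertoire_decay,
              n_cells_per_sample = n_cells_per_sample, seed = seed)
  with(cfg, {
    stopifnot(n_samples >= 1, n_genes >= 1, n_immune_genes >= 1,
              n_decoy_programs >= 0, decoy_program_size >= 1,
              immune_effect >= 0, nb_dispersion > 0,
              n_cultures_per_sample >= 1, repertoire_decay > 0,
              repertoire_decay < 1, n_cells_per_sample >= 1)
    if (length(baseline_log_mean_range) != 2 ||
        baseline_log_mean_range[1] > baseline_log_mean_range[2])
      stop("baseline_log_mean_range must be an ordered pair")
    if (length(repertoire_clones_range) != 2 ||
        repertoire_clones_range[1] > repertoire_clones_range[2])
      stop("repertoire_clones_range must be an ordered pair")
    n_markers <- length(unlist(default_marker_sets()))
    if (n_immune_genes + n_decoy_programs * decoy_program_size >
        n_genes - n_markers)
      stop("planted program sizes exceed the available gene universe")
  })
  structure(cfg, class = "cohort_config")
}

# Independent per-component RNG substreams derived from the global seed,
# kept below 2^31 for R's integer seeds.
.substream <- function(seed, component) {
  offsets <- c(bulk = 101, reactivity = 211, repertoire = 307,
               cells = 401, genesets = 503)
  if (!component %in% names(offsets)) stop("unknown substream: ", component)
  (abs(seed) %% 1000003L) * 2017L + offsets[[component]]
}

.syn_gene_ids <- function(n_genes) {
  markers <- unlist(default_marker_sets(), use.names = FALSE)
  c(markers, sprintf("SYN%04d", seq_len(n_genes - length(markers))))
}

#' Simulate bulk counts with a planted immune program
#'
#' Per-gene baseline log2 means are uniform in
#' `baseline_log_mean_range`; immune genes are shifted by
#' `immune_effect * theta_j` in sample `j`, and each decoy program by
#' `decoy_effect` times its own independent latent factor. Counts are
#' negative binomial around the resulting means. Output is bit-identical
#' for identical config and seed.
#'
#' @param config A `cohort_config`.
#' @return List with `counts` (an `expr_matrix` of counts with gene
#'   lengths) and `truth` (list: `theta`, `immune_gene_ids`,
#'   `decoy_gene_ids`, `tmb` - an inflammation-independent covariate for
#'   benchmarking).
#' @export
simulate_bulk_counts <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(.substream(config$seed, "bulk"))
  n <- config$n_samples
  genes <- .syn_gene_ids(config$n_genes)
  markers <- unlist(default_marker_sets(), use.names = FALSE)
  samples <- sprintf("S%02d", seq_len(n))
  theta <- stats::setNames(stats::runif(n), samples)

  assignable <- setdiff(genes, markers)
  immune_genes <- sample(assignable, config$n_immune_genes)
  remaining <- setdiff(assignable, immune_genes)
  decoy_genes <- list()
  if (config$n_decoy_programs > 0) {
    for (p in seq_len(config$n_decoy_programs)) {
      decoy_genes[[p]] <- sample(remaining, config$decoy_program_size)
      remaining <- setdiff(remaining, decoy_genes[[p]])
    }
  }

  baseline <- stats::runif(config$n_genes,
                           config$baseline_log_mean_range[1],
                           config$baseline_log_mean_range[2])
  names(baseline) <- genes
  log_mu <- matrix(baseline, nrow = config$n_genes, ncol = n,
                   dimnames = list(genes, samples))
  log_mu[immune_genes, ] <- log_mu[immune_genes, ] +
    rep(config$immune_effect * theta, each = length(immune_genes))
  for (p in seq_along(decoy_genes)) {
    z <- stats::runif(n)
    log_mu[decoy_genes[[p]], ] <- log_mu[decoy_genes[[p]], ] +
      rep(config$decoy_effect * z, each = length(decoy_genes[[p]]))
  }
  counts <- matrix(stats::rnbinom(length(log_mu), mu = 2^log_mu,
                                  size = 1 / config$nb_dispersion),
                   nrow = config$n_genes, dimnames = dimnames(log_mu))
  lengths <- stats::setNames(sample(200:10000, config$n_genes,
                                    replace = TRUE), genes)
  tmb <- stats::setNames(exp(stats::rnorm(n, log(5), 0.8)), samples)
  list(counts = expr_matrix(counts, unit = "counts", gene_lengths = lengths),
       truth = list(theta = theta, immune_gene_ids = immune_genes,
                    decoy_gene_ids = decoy_genes, tmb = tmb))
}

#' Simulate TIL-culture reactivity assays
#'
#' Each of `n_cultures_per_sample` cultures is truly reactive with
#' probability `plogis(intercept + slope * theta_j)`. Truly reactive
#' cultures receive 4-1BB and IFN-gamma readouts above the
#' classification gates and at least twice their simulated controls;
#' non-reactive cultures receive values below the absolute gates.
#' Controls carry positive noise.
#'
#' @param theta Named per-sample inflammation levels in [0, 1].
#' @param config A `cohort_config`.
#' @return List with `table` (the per-culture assay data frame) and
#'   `reactive_fraction` (named true per-sample reactive fraction).
#' @export
simulate_reactivity <- function(theta, config) {
  stopifnot(inherits(config, "cohort_config"))
  if (any(theta < 0 | theta > 1)) stop("theta must lie in [0, 1]")
  set.seed(.substream(config$seed, "reactivity"))
  samples <- names(theta)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_along(theta))
  m <- config$n_cultures_per_sample
  p_react <- stats::plogis(config$reactivity_intercept +
                             config$reactivity_slope * theta)
  rows <- lapply(seq_along(theta), function(j) {
    reactive <- stats::runif(m) < p_react[j]
    bb_alone <- stats::runif(m, 0, 0.5)
    bb_apc <- stats::runif(m, 0, 0.5)
    ifng_alone <- stats::runif(m, 0, 40)
    ifng_apc <- stats::runif(m, 0, 40)
    bb_bg <- pmax(bb_alone, bb_apc)
    ifng_bg <- pmax(ifng_alone, ifng_apc)
    p41bb <- ifelse(reactive, 2 * bb_bg + stats::runif(m, 1.2, 20),
                    stats::runif(m, 0, 0.9))
    ifng <- ifelse(reactive, 2 * ifng_bg + stats::runif(m, 110, 1500),
                   stats::runif(m, 0, 90))
    data.frame(sample_id = samples[j],
               culture_id = sprintf("F%02d", seq_len(m)),
               p41bb = pmin(p41bb, 100),
               p41bb_til_alone = bb_alone, p41bb_til_apc = bb_apc,
               ifng = ifng, ifng_til_alone = ifng_alone,
               ifng_til_apc = ifng_apc,
               true_reactive = reactive, stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, rows)
  frac <- tapply(table$true_reactive, table$sample_id, mean)
  frac <- stats::setNames(as.numeric(frac[samples]), samples)
  table$true_reactive <- NULL
  list(table = table, reactive_fraction = frac)
}

.random_cdr3 <- function(n, min_len = 8, max_len = 20) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    lens <- sample(min_len:max_len, need, replace = TRUE)
    new <- vapply(lens, function(l)
      paste(sample(aa, l, replace = TRUE), collapse = ""), character(1))
    out <- unique(c(out, new))
  }
  out[seq_len(n)]
}

#' Simulate one sample's TCR repertoire
#'
#' The number of unique clonotypes grows with the inflammation level
#' within `repertoire_clones_range` (Poisson-jittered); clone counts are
#' geometric with decay `repertoire_decay`; CDR3s are random amino-acid
#' strings of length 8-20. Both TRB and TRA chains are emitted (the TRA
#' repertoire is slightly smaller, as is typical of bulk extraction).
#'
#' @param theta_j Inflammation level of the sample, in [0, 1].
#' @param config A `cohort_config`.
#' @param seed Integer seed for this sample's substream.
#' @param sample_id Sample identifier; default `"S01"`.
#' @return A tabulated clonotype data frame (`sample_id`, `chain`,
#'   `cdr3_aa`, `count`).
#' @export
simulate_repertoire <- function(theta_j, config, seed,
                                sample_id = "S01") {
  stopifnot(inherits(config, "cohort_config"))
  if (theta_j < 0 || theta_j > 1) stop("theta must lie in [0, 1]")
  set.seed(seed)
  lo <- config$repertoire_clones_range[1]
  hi <- config$repertoire_clones_range[2]
  chains <- list(TRB = 1, TRA = 0.8)
  rows <- lapply(names(chains), function(ch) {
    target <- lo + theta_j * (hi - lo) * chains[[ch]]
    s <- min(hi, max(lo, stats::rpois(1, target)))
    data.frame(sample_id = sample_id, chain = ch,
               cdr3_aa = .random_cdr3(s),
               count = 1L + stats::rgeom(s, prob = config$repertoire_decay),
               stringsAsFactors = FALSE)
  })
  tabulate_clonotypes(do.call(rbind, rows))
}

#' Simulate repertoires for a whole cohort
#'
#' @param theta Named per-sample inflammation levels.
#' @param config A `cohort_config`.
#' @return A combined tabulated clonotype table.
#' @export
simulate_repertoires <- function(theta, config) {
  base <- .substream(config$seed, "repertoire")
  samples <- names(theta)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_along(theta))
  do.call(rbind, lapply(seq_along(theta), function(j)
    simulate_repertoire(theta[j], config, seed = base + j,
                        sample_id = samples[j])))
}

#' Simulate marker-structured single cells
#'
#' Cells from a subset of samples (default: the three highest- and three
#' lowest-inflammation samples, mirroring a disparate-score profiling
#' design) are drawn from three true buckets. Immune cells express PTPRC
#' highly; tumor cells express the melanoma marker panel highly; stroma
#' cells have zero counts for all seven markers. The immune fraction
#' grows with the sample's inflammation level. Background expression is
#' per-gene Poisson, dense enough that undetected genes rank beyond the
#' default rank cap of the per-cell score (as they do in a full
#' transcriptome).
#'
#' @param config A `cohort_config`.
#' @param truth Truth list from [simulate_bulk_counts()] (`theta` is
#'   used).
#' @param samples Optional character vector of sample ids to profile.
#' @return List with `counts` (sparse gene-by-cell `dgCMatrix`),
#'   `sample_ids` (per cell) and `true_bucket` (per cell).
#' @export
simulate_cells <- function(config, truth, samples = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  theta <- truth$theta
  if (is.null(samples)) {
    ord <- order(theta)
    take <- min(3, floor(length(theta) / 2))
    samples <- names(theta)[c(utils::head(ord, take),
                              utils::tail(ord, take))]
  }
  if (!all(samples %in% names(theta))) stop("unknown sample ids")
  set.seed(.substream(config$seed, "cells"))
  genes <- .syn_gene_ids(config$n_genes)
  marker_sets <- default_marker_sets()
  markers <- unlist(marker_sets, use.names = FALSE)
  if (!all(markers %in% genes))
    stop("marker genes missing from the gene universe")
  lambda <- stats::runif(config$n_genes, 0.5, 3)
  names(lambda) <- genes
  lambda[markers] <- 0  # marker expression is bucket-determined

  n_cells <- config$n_cells_per_sample
  blocks <- lapply(samples, function(s) {
    p_imm <- 0.05 + 0.55 * theta[s]
    p_str <- 0.15
    bucket <- sample(c("immune", "tumor", "stroma"), n_cells,
                     replace = TRUE,
                     prob = c(p_imm, 1 - p_imm - p_str, p_str))
    m <- matrix(stats::rpois(config$n_genes * n_cells, lambda),
                nrow = config$n_genes,
                dimnames = list(genes, sprintf("%s_C%04d", s,
                                               seq_len(n_cells))))
    imm <- bucket == "immune"
    tum <- bucket == "tumor"
    m[marker_sets$immune, imm] <- 25 + stats::rpois(sum(imm), 10)
    m[marker_sets$tumor, tum] <-
      8 + stats::rpois(length(marker_sets$tumor) * sum(tum), 5)
    list(m = m, bucket = bucket, sample = rep(s, n_cells))
  })
  counts <- do.call(cbind, lapply(blocks, `[[`, "m"))
  list(counts = Matrix::Matrix(counts, sparse = TRUE),
       sample_ids = unlist(lapply(blocks, `[[`, "sample")),
       true_bucket = unlist(lapply(blocks, `[[`, "bucket")))
}

#' Probe gene sets for a synthetic cohort
#'
#' Builds a hallmark-like collection: three immune/inflammatory probe
#' sets drawn from the planted immune program, one decoy-flavored set
#' per decoy program, and unrelated random sets. The immune probe names
#' are the default `immune_set_names` for [identify_immune_axis()].
#'
#' @param truth Truth list from [simulate_bulk_counts()].
#' @param config A `cohort_config`.
#' @param set_size Genes per probe set; default 30.
#' @param n_random Number of unrelated random sets; default 4.
#' @return List with `sets` (a `geneset_collection`) and
#'   `immune_set_names`.
#' @export
cohort_genesets <- function(truth, config, set_size = 30, n_random = 4) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(.substream(config$seed, "genesets"))
  genes <- .syn_gene_ids(config$n_genes)
  immune_names <- c("IFN_GAMMA_RESPONSE_LIKE", "IFN_ALPHA_RESPONSE_LIKE",
                    "ALLOGRAFT_REJECTION_LIKE")
  take <- function(pool) sample(pool, min(set_size, length(pool)))
  sets <- stats::setNames(
    lapply(immune_names, function(nm) take(truth$immune_gene_ids)),
    immune_names)
  decoy_flavors <- c("OXIDATIVE_PHOSPHORYLATION_LIKE", "BILE_ACID_LIKE",
                     "COAGULATION_LIKE", "MYC_TARGETS_LIKE")
  for (p in seq_along(truth$decoy_gene_ids)) {
    nm <- decoy_flavors[(p - 1) %% length(decoy_flavors) + 1]
    sets[[paste0(nm, "_", p)]] <- take(truth$decoy_gene_ids[[p]])
  }
  background <- setdiff(genes, c(truth$immune_gene_ids,
                                 unlist(truth$decoy_gene_ids)))
  for (r in seq_len(n_random))
    sets[[paste0("RANDOM_SET_", r)]] <- take(background)
  list(sets = geneset_collection(sets), immune_set_names = immune_names)
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper running all generator stages from one config:
#' bulk counts, probe gene sets, reactivity assays, TCR repertoires and
#' single cells, with ground truth collected for parameter-recovery
#' testing.
#'
#' @param config A `cohort_config`.
#' @param with_cells Set `FALSE` to skip the single-cell compartment.
#' @return List with `counts`, `genesets`, `immune_set_names`,
#'   `reactivity`, `clonotypes`, `cells` and `truth` (`theta`,
#'   `immune_gene_ids`, `decoy_gene_ids`, `tmb`,
#'   `true_reactive_fraction`, `cell_true_bucket`).
#' @export
simulate_cohort <- function(config = cohort_config(), with_cells = TRUE) {
  bulk <- simulate_bulk_counts(config)
  gs <- cohort_genesets(bulk$truth, config)
  reactivity <- simulate_reactivity(bulk$truth$theta, config)
  clonotypes <- simulate_repertoires(bulk$truth$theta, config)
  cells <- if (with_cells) simulate_cells(config, bulk$truth) else NULL
  truth <- c(bulk$truth,
             list(true_reactive_fraction = reactivity$reactive_fraction,
                  cell_true_bucket = if (with_cells) cells$true_bucket))
  list(counts = bulk$counts, genesets = gs$sets,
       immune_set_names = gs$immune_set_names,
       reactivity = reactivity$table, clonotypes = clonotypes,
       cells = cells, truth = truth, config = config)
}

#' Write a simulated cohort to disk
#'
#' Emits the plain-text exchange formats of every compartment: counts
#' and gene-lengths TSV, probe sets GMT, reactivity TSV, clonotype TSV,
#' MatrixMarket triplet with barcode/feature lists for the cells, and a
#' truth JSON.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             lengths = file.path(dir, "gene_lengths.tsv"),
             gmt = file.path(dir, "genesets.gmt"),
             reactivity = file.path(dir, "reactivity.tsv"),
             clonotypes = file.path(dir, "clonotypes.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression_tsv(cohort$counts, paths[["counts"]])
  write_gene_lengths_tsv(cohort$counts$gene_lengths, paths[["lengths"]])
  write_gmt(cohort$genesets, paths[["gmt"]])
  utils::write.table(cohort$reactivity, paths[["reactivity"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_clonotype_tsv(cohort$clonotypes, paths[["clonotypes"]])
  if (!is.null(cohort$cells)) {
    paths <- c(paths, mtx = file.path(dir, "cells.mtx"),
               barcodes = file.path(dir, "barcodes.tsv"),
               features = file.path(dir, "features.tsv"))
    Matrix::writeMM(cohort$cells$counts, paths[["mtx"]])
    writeLines(colnames(cohort$cells$counts), paths[["barcodes"]])
    writeLines(rownames(cohort$cells$counts), paths[["features"]])
    utils::write.table(
      data.frame(cell_id = colnames(cohort$cells$counts),
                 sample_id = cohort$cells$sample_ids),
      file.path(dir, "cell_samples.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- cohort$truth
  truth$decoy_gene_ids <- lapply(truth$decoy_gene_ids, identity)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = FALSE,
                       digits = NA)
  invisible(paths)
}
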