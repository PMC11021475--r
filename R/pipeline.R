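#' Default pipeline options
#'
#' All analysis thresholds surfaced as named options with their standard
#' values: top-variance fraction 0.10, three candidate PCs, four
#' gene-set clusters, reactivity gates (1% 4-1BB, 100 pg/ml IFN-gamma,
#' twice background), 33% percent-reactive classification threshold,
#' rank cap 1500, DE filters |log2fc| >= 0.5 and FDR < 0.05.
#'
#' @return Named list of option defaults.
#' @export
pipeline_defaults <- function() {
  list(fraction = 0.10, n_components = 3, k = 4,
       reactive_threshold = 33, background_rule = "max",
       r_max = 1500, lfc_min = 0.5, fdr_max = 0.05, centered = FALSE,
       with_cells = TRUE)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates the stages end to end: simulate (or re-simulate) the
#' cohort, normalize and discover the immune signature, score every
#' sample, classify reactivity and benchmark predictors, compute
#' repertoire metrics, catalog cells and test composition, then write
#' all outputs plus a reproducibility manifest with content digests.
#' Rerunning with the same config and seed reproduces the digests.
#'
#' @param config Either a path to a YAML file whose keys mirror
#'   [cohort_config()] plus the option names of [pipeline_defaults()],
#'   or a list with elements `cohort` (a `cohort_config`) and `options`.
#' @param out_dir Output directory.
#' @param seed Optional integer overriding the config seed.
#' @return The run manifest (also written as `manifest.json`), a list
#'   with the config snapshot, seed, stage summaries and per-file
#'   digests.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = NULL) {
  cfg <- .load_pipeline_config(config)
  if (!is.null(seed)) cfg$cohort$seed <- as.integer(seed)
  opts <- cfg$options
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- stage("simulate",
                  simulate_cohort(cfg$cohort, with_cells = opts$with_cells))
  paths <- stage("simulate", write_cohort(cohort, file.path(out_dir, "cohort")))

  disc <- stage("discover",
                discover_signature(cohort$counts, cohort$genesets,
                                   cohort$immune_set_names,
                                   fraction = opts$fraction,
                                   n_components = opts$n_components,
                                   k = opts$k))
  sig_path <- file.path(out_dir, "signature.gmt")
  write_gmt(geneset_collection(list(IMMUNE_AXIS_SIGNATURE =
                                      disc$signature$gene_ids)), sig_path)

  scores <- stage("score",
                  umis_score(disc$tpm, disc$signature,
                             centered = opts$centered))
  scores$group <- dichotomize_by_median(scores$score)
  scores_path <- file.path(out_dir, "scores.tsv")
  utils::write.table(scores, scores_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  react <- stage("reactivity", {
    tab <- classify_reactivity_table(cohort$reactivity,
                                     background_rule = opts$background_rule)
    pct <- percent_reactive(tab)[scores$sample_id]
    bench <- benchmark_predictors(
      list(immune_score = scores$score, tmb = cohort$truth$tmb),
      pct, reactive_threshold = opts$reactive_threshold)
    utils::write.table(bench, file.path(out_dir, "benchmark.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(percent_reactive = pct, benchmark = bench)
  })

  tcr <- stage("tcr", {
    metrics <- repertoire_metrics(cohort$clonotypes)
    utils::write.table(metrics, file.path(out_dir, "repertoire_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    metrics
  })

  catalog <- NULL
  if (opts$with_cells) {
    catalog <- stage("sc_catalog", {
      ann <- catalog_cells(cohort$cells$counts, cohort$cells$sample_ids,
                           r_max = opts$r_max)
      utils::write.table(ann, file.path(out_dir, "cell_annotations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ann
    })
  }

  out_files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  out_files <- out_files[basename(out_files) != "manifest.json"]
  manifest <- list(
    config = list(cohort = unclass(cfg$cohort), options = opts),
    seed = cfg$cohort$seed,
    stages = list(
      discover = list(pc_index = disc$axis$pc_index,
                      direction = disc$axis$direction,
                      n_signature_genes = length(disc$signature$gene_ids)),
      score = list(median = stats::median(scores$score),
                   range = range(scores$score)),
      reactivity = list(
        auc = react$benchmark$auc[react$benchmark$predictor ==
                                    "immune_score"]),
      tcr = list(n_excluded = sum(tcr$excluded))),
    outputs = stats::setNames(
      as.list(unname(tools::md5sum(out_files))),
      sub(paste0("^", out_dir, "/?"), "", out_files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

.load_pipeline_config <- function(config) {
  defaults <- pipeline_defaults()
  if (is.null(config))
    return(list(cohort = cohort_config(), options = defaults))
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    cohort_args <- raw[intersect(names(raw), names(formals(cohort_config)))]
    opts <- utils::modifyList(defaults,
                              raw[intersect(names(raw), names(defaults))])
    return(list(cohort = do.call(cohort_config, cohort_args),
                options = opts))
  }
  if (is.list(config)) {
    cohort <- if (inherits(config$cohort, "cohort_config")) config$cohort
              else do.call(cohort_config, config$cohort %||% list())
    opts <- utils::modifyList(defaults, config$options %||% list())
    return(list(cohort = cohort, options = opts))
  }
  stop("config must be NULL, a YAML path, or a list")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
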