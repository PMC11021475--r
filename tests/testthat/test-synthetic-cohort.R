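small_config <- function(seed = 9, ...) {
  cohort_config(n_samples = 20, n_genes = 400, n_immune_genes = 40,
                n_decoy_programs = 1, decoy_program_size = 30,
                n_cells_per_sample = 50, seed = seed, ...)
}

test_that("config validation rejects impossible program sizes and ranges", {
  expect_error(cohort_config(n_genes = 100, n_immune_genes = 90,
                             n_decoy_programs = 1, decoy_program_size = 20),
               "exceed")
  expect_error(cohort_config(baseline_log_mean_range = c(5, 2)), "ordered")
  expect_error(cohort_config(repertoire_clones_range = c(10, 2)), "ordered")
  expect_s3_class(cohort_config(), "cohort_config")
})

test_that("identical config and seed give bit-identical cohorts", {
  cfg <- small_config()
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$counts$values, b$counts$values)
  expect_identical(a$reactivity, b$reactivity)
  expect_identical(a$clonotypes, b$clonotypes)
  expect_identical(as.matrix(a$cells$counts), as.matrix(b$cells$counts))
  expect_identical(a$truth$theta, b$truth$theta)
  # a different seed changes the data
  c2 <- simulate_cohort(small_config(seed = 10))
  expect_false(identical(a$counts$values, c2$counts$values))
})

test_that("bulk counts link immune genes to theta only when the effect is on", {
  cfg <- cohort_config()
  bulk <- simulate_bulk_counts(cfg)
  expect_length(bulk$truth$theta, cfg$n_samples)
  expect_true(all(bulk$truth$theta >= 0 & bulk$truth$theta <= 1))
  # immune and decoy programs disjoint
  expect_length(intersect(bulk$truth$immune_gene_ids,
                          unlist(bulk$truth$decoy_gene_ids)), 0)
  tpm <- compute_tpm(bulk$counts)
  rho <- cor(bulk$truth$theta,
             colMeans(tpm$values[bulk$truth$immune_gene_ids, ]),
             method = "spearman")
  expect_gte(rho, 0.8)

  # null effect: no association
  null_bulk <- simulate_bulk_counts(cohort_config(immune_effect = 0))
  null_tpm <- compute_tpm(null_bulk$counts)
  null_rho <- cor(null_bulk$truth$theta,
                  colMeans(null_tpm$values[null_bulk$truth$immune_gene_ids, ]),
                  method = "spearman")
  expect_lt(abs(null_rho), 0.3)
})

test_that("planted immune genes dominate variance without decoy competition", {
  # strong, unambiguous planting: the program's variance must clear the
  # count-noise floor for every program gene
  cfg <- cohort_config(n_decoy_programs = 0, immune_effect = 3,
                       nb_dispersion = 0.05,
                       baseline_log_mean_range = c(5, 8))
  bulk <- simulate_bulk_counts(cfg)
  logm <- log_stabilize(normalize_counts(bulk$counts))
  top <- select_top_variance_genes(logm, fraction = 0.10)
  expect_true(all(bulk$truth$immune_gene_ids %in% top))
})

test_that("simulated reactivity respects the logistic link and the classifier", {
  cfg <- cohort_config()
  theta <- setNames(seq(0, 1, length.out = 20), sprintf("S%02d", 1:20))

  # degenerate links saturate the classifier
  all_off <- simulate_reactivity(theta, cohort_config(
    reactivity_slope = 0, reactivity_intercept = -10))
  expect_equal(sum(classify_reactivity_table(all_off$table)$reactive), 0)
  all_on <- simulate_reactivity(theta, cohort_config(
    reactivity_slope = 0, reactivity_intercept = 10))
  tab_on <- classify_reactivity_table(all_on$table)
  expect_true(all(tab_on$reactive))

  # culture conservation
  expect_equal(nrow(all_on$table), 20 * cfg$n_cultures_per_sample)

  # default link: classified percent-reactive tracks theta
  bulk <- simulate_bulk_counts(cfg)
  react <- simulate_reactivity(bulk$truth$theta, cfg)
  pct <- percent_reactive(classify_reactivity_table(react$table))
  pct <- pct[names(bulk$truth$theta)]
  expect_gte(cor(bulk$truth$theta, pct, method = "spearman"), 0.7)
  # classifier recovers the generator's own truth
  expect_equal(unname(pct) / 100, unname(react$reactive_fraction),
               tolerance = 1e-12)
})

test_that("repertoires grow with inflammation and are deterministic", {
  cfg <- cohort_config(repertoire_clones_range = c(1, 50))
  rep_low <- simulate_repertoire(0, cfg, seed = 5)
  trb_low <- rep_low[rep_low$chain == "TRB", ]
  expect_lte(nrow(trb_low), 5)  # lower end of the range
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", rep_low$cdr3_aa)))
  expect_true(all(nchar(rep_low$cdr3_aa) >= 8 & nchar(rep_low$cdr3_aa) <= 20))
  expect_identical(simulate_repertoire(0.4, cfg, seed = 5),
                   simulate_repertoire(0.4, cfg, seed = 5))

  cfg_full <- cohort_config()
  bulk <- simulate_bulk_counts(cfg_full)
  tabs <- simulate_repertoires(bulk$truth$theta, cfg_full)
  met <- repertoire_metrics(tabs)
  trb <- met[met$chain == "TRB", ]
  expect_gte(cor(bulk$truth$theta[trb$sample_id], trb$shannon,
                 method = "spearman"), 0.6)
})

test_that("simulated cells carry the marker structure of their bucket", {
  cfg <- small_config()
  bulk <- simulate_bulk_counts(cfg)
  cells <- simulate_cells(cfg, bulk$truth)
  markers <- default_marker_sets()
  expect_equal(length(cells$true_bucket), ncol(cells$counts))
  # every cell has exactly one bucket
  expect_true(all(cells$true_bucket %in% c("immune", "tumor", "stroma")))
  imm <- cells$true_bucket == "immune"
  tum <- cells$true_bucket == "tumor"
  str <- cells$true_bucket == "stroma"
  expect_true(all(cells$counts["PTPRC", imm] > 0))
  expect_equal(sum(cells$counts["PTPRC", !imm]), 0)
  expect_true(all(cells$counts[markers$tumor, tum] > 0))
  expect_equal(sum(cells$counts[unlist(markers), str]), 0)
})

test_that("a cohort writes complete plain-text outputs", {
  cfg <- small_config()
  coh <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  expect_true(all(file.exists(paths)))
  back <- read_expression_tsv(paths[["counts"]], unit = "counts")
  expect_equal(back$values, coh$counts$values)
  gmt <- read_gmt(paths[["gmt"]])
  expect_setequal(names(gmt), names(coh$genesets))
  m <- Matrix::readMM(paths[["mtx"]])
  expect_equal(dim(m), dim(coh$cells$counts))
})
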