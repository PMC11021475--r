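# A small dense universe where detected genes sit inside the rank cap
# and undetected genes fall beyond it.
make_cell <- function(ptprc = 0, tumor = 0, n_genes = 400, seed = 1) {
  set.seed(seed)
  genes <- c(unlist(default_marker_sets(), use.names = FALSE),
             sprintf("BG%03d", seq_len(n_genes - 7)))
  v <- setNames(c(rep(0, 7), rpois(n_genes - 7, 2)), genes)
  v["PTPRC"] <- ptprc
  if (tumor > 0) v[default_marker_sets()$tumor] <- tumor
  v
}

test_that("bucket assignment follows the stated precedence", {
  r_max <- 300
  # PTPRC high and tumor markers present -> immune wins by precedence
  both <- make_cell(ptprc = 50, tumor = 20)
  expect_equal(assign_bucket(both, r_max = r_max), "immune")
  # no PTPRC, tumor markers within the cap -> tumor
  expect_equal(assign_bucket(make_cell(tumor = 15), r_max = r_max), "tumor")
  # none of the seven markers detected -> stroma
  expect_equal(assign_bucket(make_cell(), r_max = r_max), "stroma")
  # missing marker genes in the universe -> error
  v <- setNames(rpois(50, 2), sprintf("X%02d", 1:50))
  expect_error(assign_bucket(v), "absent")
})

test_that("cataloging recovers the generated buckets", {
  coh <- default_cohort()
  ann <- catalog_cells(coh$cells$counts, coh$cells$sample_ids)
  expect_equal(nrow(ann), ncol(coh$cells$counts))
  accuracy <- mean(ann$bucket == coh$truth$cell_true_bucket)
  expect_gte(accuracy, 0.99)
  # stroma cells carry zero counts for all seven markers, by construction
  markers <- unlist(default_marker_sets(), use.names = FALSE)
  stroma_cols <- which(coh$truth$cell_true_bucket == "stroma")
  expect_equal(sum(coh$cells$counts[markers, stroma_cols]), 0)
})

test_that("per-sample proportions count cells and sum to one", {
  ann <- data.frame(
    sample_id = rep("S1", 10),
    bucket = rep(c("tumor", "immune", "stroma"), c(6, 3, 1)))
  prop <- proportions_per_sample(ann)
  expect_equal(unname(prop["S1", c("tumor", "immune", "stroma")]),
               c(0.6, 0.3, 0.1))
  # single-bucket sample
  solo <- data.frame(sample_id = "S2", bucket = rep("tumor", 5))
  expect_equal(unname(proportions_per_sample(solo)[1, "tumor"]), 1)
  # invariant to cell order
  shuffled <- ann[sample(nrow(ann)), ]
  expect_equal(proportions_per_sample(shuffled), prop)
  # rows always sum to 1
  coh <- default_cohort()
  ann2 <- data.frame(sample_id = coh$cells$sample_ids,
                     bucket = coh$truth$cell_true_bucket)
  expect_equal(unname(rowSums(proportions_per_sample(ann2))),
               rep(1, length(unique(coh$cells$sample_ids))),
               tolerance = 1e-12)
})

test_that("composition test uses arcsin-sqrt values and mean-proportion ratios", {
  prop <- rbind(c(0.2, 0.8), c(0.3, 0.7), c(0.4, 0.6),
                c(0.1, 0.9), c(0.1, 0.9), c(0.1, 0.9))
  dimnames(prop) <- list(paste0("S", 1:6), c("immune", "tumor"))
  groups <- rep(c("high", "low"), each = 3)
  res <- proportion_test(prop, groups)
  expect_equal(res$fold_enrichment[res$cell_type == "immune"], 3)
  # cross-check p-value against a direct t-test on transformed values
  direct <- t.test(asin(sqrt(prop[1:3, 1])), asin(sqrt(prop[4:6, 1])))
  expect_equal(res$p_value[res$cell_type == "immune"], direct$p.value)

  # swapping groups inverts the fold enrichment
  res_swap <- proportion_test(prop, rev(groups))
  expect_equal(res_swap$fold_enrichment[1], 1 / res$fold_enrichment[1],
               tolerance = 1e-12)

  # identical proportions in both groups -> fold 1, p near 1
  flat <- matrix(c(0.5, 0.5, 0.52, 0.48, 0.5, 0.5, 0.52, 0.48),
                 nrow = 4, byrow = TRUE,
                 dimnames = list(paste0("S", 1:4), c("a", "b")))
  res_flat <- proportion_test(flat, c("high", "high", "low", "low"))
  expect_equal(res_flat$fold_enrichment, c(1, 1))
  expect_true(all(res_flat$p_value > 0.9))

  # all-constant column -> p = 1 (no signal, no degeneracy warning)
  zero <- cbind(a = rep(0, 4), b = rep(1, 4))
  rownames(zero) <- paste0("S", 1:4)
  res_zero <- proportion_test(zero, c("high", "high", "low", "low"))
  expect_equal(res_zero$p_value, c(1, 1))

  expect_error(proportion_test(prop, c("high", rep("low", 5))),
               "two samples")
})

test_that("rank-sum DE filters by fold change and FDR with the high-vs-low sign", {
  set.seed(41)
  n_cells <- 40
  groups <- rep(c("high", "low"), each = n_cells / 2)
  expr <- rbind(
    marker = c(rpois(n_cells / 2, 50), rpois(n_cells / 2, 1)),
    null_gene = rpois(n_cells, 10),
    down = c(rpois(n_cells / 2, 1), rpois(n_cells / 2, 40)))
  colnames(expr) <- paste0("C", seq_len(n_cells))
  all_tab <- wilcoxon_de(expr, groups, return_all = TRUE)

  marker_row <- all_tab[all_tab$gene_id == "marker", ]
  expect_gt(marker_row$log2fc, 0.5)
  expect_true(marker_row$retained)
  # cross-check against a direct rank-sum p-value
  direct <- suppressWarnings(
    wilcox.test(expr["marker", groups == "high"],
                expr["marker", groups == "low"])$p.value)
  expect_equal(marker_row$p_value, direct)
  # identical gene excluded
  expect_false(all_tab$retained[all_tab$gene_id == "null_gene"])
  # sign convention: higher in low group is negative
  expect_lt(all_tab$log2fc[all_tab$gene_id == "down"], -0.5)

  # label swap negates every log2fc
  swapped <- wilcoxon_de(expr, ifelse(groups == "high", "low", "high"),
                         return_all = TRUE)
  swapped <- swapped[match(all_tab$gene_id, swapped$gene_id), ]
  expect_equal(swapped$log2fc, -all_tab$log2fc)

  # filtered output is the retained subset, monotone in both thresholds
  filt <- wilcoxon_de(expr, groups)
  expect_setequal(filt$gene_id, all_tab$gene_id[all_tab$retained])
  stricter <- wilcoxon_de(expr, groups, lfc_min = 2, fdr_max = 0.01)
  expect_true(all(stricter$gene_id %in% filt$gene_id))
})
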