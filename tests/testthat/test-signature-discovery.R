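make_planted_log_matrix <- function(n_samples = 30, n_genes = 50,
                                    seed = 5) {
  set.seed(seed)
  axis <- seq(-1, 1, length.out = n_samples)
  m <- matrix(rnorm(n_genes * n_samples, sd = 0.05), nrow = n_genes,
              dimnames = list(paste0("G", 1:n_genes),
                              paste0("S", 1:n_samples)))
  m[1:10, ] <- m[1:10, ] + rep(2 * axis, each = 10)  # dominant planted axis
  expr_matrix(m + 5, unit = "log")
}

test_that("PCA recovers a planted dominant axis and reconstructs the data", {
  em <- make_planted_log_matrix()
  pca <- run_pca(em, n_components = 5)
  expect_gt(pca$explained_variance_fraction[1],
            max(pca$explained_variance_fraction[-1]))
  # loadings orthonormal
  gram <- crossprod(pca$loadings)
  expect_equal(gram, diag(5), tolerance = 1e-8, ignore_attr = TRUE)
  # explained variance non-increasing, sums <= 1
  expect_true(all(diff(pca$explained_variance_fraction) <= 1e-12))
  expect_lte(sum(pca$explained_variance_fraction), 1 + 1e-12)
  # full-rank reconstruction reproduces the centered data
  full <- run_pca(em, n_components = ncol(em$values) - 1)
  centered <- t(scale(t(em$values), center = TRUE, scale = FALSE))
  recon <- full$loadings %*% t(full$scores)
  expect_equal(recon, centered, tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(run_pca(em, n_components = 40), "n_components")
})

test_that("PC sign convention makes the dominant loading positive", {
  em <- make_planted_log_matrix()
  pca <- run_pca(em, n_components = 3)
  for (j in 1:3) {
    l <- pca$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
})

test_that("Spearman PC-gene-set correlation follows hand-computed values", {
  scores <- matrix(c(1, 2, 3, 4), ncol = 1,
                   dimnames = list(paste0("S", 1:4), "PC1"))
  pca <- structure(list(scores = scores), class = "pca_result")
  set_scores <- cbind(mono = c(5, 6, 7, 8),
                      anti = c(8, 7, 6, 5),
                      handv = c(10, 30, 20, 40),
                      flat = c(1, 1, 1, 1))
  rownames(set_scores) <- rownames(scores)
  corr <- correlate_pcs_with_genesets(pca, set_scores, pcs = 1)
  expect_equal(corr$rho["mono", "PC1"], 1)
  expect_equal(corr$rho["anti", "PC1"], -1)
  expect_equal(corr$rho["handv", "PC1"], 0.8)
  expect_true(is.na(corr$rho["flat", "PC1"]))
})

test_that("gene-set clustering recovers separated correlation blocks", {
  rho <- rbind(matrix(rep(c(0.8, -0.1, 0.0), each = 4), nrow = 4),
               matrix(rep(c(-0.7, 0.6, 0.1), each = 4), nrow = 4))
  rho <- rho + seq(-0.02, 0.02, length.out = 24)
  dimnames(rho) <- list(paste0("SET", 1:8), paste0("PC", 1:3))
  corr <- structure(list(rho = rho, pcs = 1:3, cluster_labels = NULL),
                    class = "pc_geneset_correlation")
  cl <- cluster_genesets(corr, k = 2)$cluster_labels
  expect_length(unique(cl[1:4]), 1)
  expect_length(unique(cl[5:8]), 1)
  expect_true(cl[1] != cl[5])
  # k = number of sets -> singletons
  expect_equal(sort(unname(cluster_genesets(corr, k = 8)$cluster_labels)),
               1:8)
  expect_error(cluster_genesets(corr, k = 9), "exceeds")
})

test_that("immune-axis identification follows the mean-rho rule", {
  # pattern echoing an immune cluster correlated only with negative PC2
  rho <- rbind(IFN_G = c(0.02, -0.30, 0.05),
               IFN_A = c(-0.03, -0.35, 0.01),
               ALLO = c(0.01, -0.31, -0.02),
               METAB = c(0.76, 0.05, 0.10))
  colnames(rho) <- paste0("PC", 1:3)
  corr <- structure(list(rho = rho, pcs = 1:3, cluster_labels = NULL),
                    class = "pc_geneset_correlation")
  axis <- identify_immune_axis(corr, c("IFN_G", "IFN_A", "ALLO"))
  expect_equal(axis$pc_index, 2)
  expect_equal(axis$direction, "negative")
  expect_equal(unname(axis$mean_rho["PC2"]), -0.32)

  # single dominant positive axis
  rho1 <- rbind(IMM = c(0.9, 0.0, 0.0))
  colnames(rho1) <- paste0("PC", 1:3)
  corr1 <- structure(list(rho = rho1, pcs = 1:3, cluster_labels = NULL),
                     class = "pc_geneset_correlation")
  expect_equal(identify_immune_axis(corr1, "IMM")[c("pc_index", "direction")],
               list(pc_index = 1, direction = "positive"))

  # exact tie -> lowest PC index
  rho2 <- rbind(IMM = c(0.5, -0.5, 0.1))
  colnames(rho2) <- paste0("PC", 1:3)
  corr2 <- structure(list(rho = rho2, pcs = 1:3, cluster_labels = NULL),
                     class = "pc_geneset_correlation")
  expect_equal(identify_immune_axis(corr2, "IMM")$pc_index, 1)
})

test_that("signature selection filters strictly by loading sign", {
  loadings <- cbind(PC1 = c(0.9, 0.1, 0.3, 0.2),
                    PC2 = c(-0.5, 0.1, -0.2, 0.3))
  rownames(loadings) <- paste0("G", 1:4)
  pca <- structure(list(loadings = loadings), class = "pca_result")
  neg <- select_signature(pca, 2, "negative")
  expect_equal(neg$gene_ids, c("G1", "G3"))
  pos <- select_signature(pca, 2, "positive")
  expect_equal(pos$gene_ids, c("G2", "G4"))
  # positive + negative + zero-loading genes partition the PCA gene set
  expect_setequal(c(neg$gene_ids, pos$gene_ids), rownames(loadings))
  expect_error(select_signature(pca, 1, "negative"), "no genes")
})

test_that("axis identification is invariant to PC sign flips", {
  disc <- default_discovery()
  pca <- disc$pca
  flipped <- pca
  j <- disc$axis$pc_index
  flipped$loadings[, j] <- -flipped$loadings[, j]
  flipped$scores[, j] <- -flipped$scores[, j]
  corr_f <- correlate_pcs_with_genesets(flipped, disc$set_scores, pcs = 1:3)
  coh <- default_cohort()
  axis_f <- identify_immune_axis(corr_f, coh$immune_set_names)
  expect_equal(axis_f$pc_index, disc$axis$pc_index)
  expect_true(axis_f$direction != disc$axis$direction)
  sig_f <- select_signature(flipped, axis_f$pc_index, axis_f$direction)
  expect_setequal(sig_f$gene_ids, disc$signature$gene_ids)
})

test_that("discovery recovers the planted immune program on the default cohort", {
  coh <- default_cohort()
  disc <- default_discovery()
  truth <- coh$truth
  # a top-3 PC tracks the latent inflammation level
  pc_rho <- apply(disc$pca$scores, 2,
                  function(s) cor(s, truth$theta, method = "spearman"))
  expect_gte(max(abs(pc_rho)), 0.8)
  # planted immune set scores track theta
  imm_scores <- rowMeans(disc$set_scores[, coh$immune_set_names])
  expect_gte(cor(imm_scores, truth$theta, method = "spearman"), 0.8)
  # signature overlaps the planted program within the PCA gene set
  planted <- intersect(truth$immune_gene_ids, disc$pca_genes)
  jac <- length(intersect(disc$signature$gene_ids, planted)) /
    length(union(disc$signature$gene_ids, planted))
  expect_gte(jac, 0.7)
  # end-to-end: signature score recovers theta
  sc <- umis_score(disc$tpm, disc$signature)
  expect_gte(cor(sc$score, truth$theta, method = "spearman"), 0.9)
})
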