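# Brute-force oracles, written independently of the package internals:
# explicit loops over genes, no calls to rank() or to the package's
# normalization helpers.

# Average-tie rank of each element by pair counting.
oracle_ranks <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    smaller <- sum(x < x[i])
    ties <- sum(x == x[i])
    smaller + (ties + 1) / 2
  }, numeric(1))
}

# Unidirectional rank score: mean percentile rank of the set genes,
# normalized between the best and worst achievable mean rank for a set
# of that size (enumerated as the bottom-n and top-n rank blocks).
oracle_singscore <- function(values, set_idx) {
  r <- oracle_ranks(values)
  n <- length(set_idx)
  N <- length(values)
  worst <- mean(seq(1, n))
  best <- mean(seq(N - n + 1, N))
  (mean(r[set_idx]) - worst) / (best - worst)
}

# Capped-rank U-statistic score, descending ranks by pair counting.
oracle_ucell <- function(values, set_idx, r_max) {
  n_all <- length(values)
  desc <- vapply(seq_len(n_all), function(i) {
    larger <- sum(values > values[i])
    ties <- sum(values == values[i])
    larger + (ties + 1) / 2
  }, numeric(1))
  set_r <- desc[set_idx]
  if (all(set_r > r_max)) return(0)
  set_r[set_r > r_max] <- r_max + 1
  n <- length(set_idx)
  u <- sum(set_r) - n * (n + 1) / 2
  1 - u / (n * r_max)
}

# AUC as the fraction of concordant positive/negative score pairs, ties
# counted one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Small deterministic count fixture: 6 genes x 4 samples.
tiny_counts <- function() {
  m <- matrix(c(10, 20, 5, 80, 1, 40,
                12, 18, 7, 90, 0, 41,
                30, 60, 15, 240, 3, 120,
                9, 22, 4, 70, 2, 39),
              nrow = 6,
              dimnames = list(paste0("G", 1:6), paste0("S", 1:4)))
  expr_matrix(m, unit = "counts",
              gene_lengths = c(G1 = 1000, G2 = 2000, G3 = 500,
                               G4 = 1500, G5 = 800, G6 = 1200))
}
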