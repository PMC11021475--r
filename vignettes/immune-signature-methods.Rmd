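---
title: "Methods: immune-axis discovery, rank scoring, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune-axis discovery, rank scoring, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umiscore)
```

# The problem

Bulk transcriptomes of tumor metastases vary along several strong axes at
once: cellular metabolism, tissue-of-origin physiology (liver-dominant
programs in hepatic metastases), proliferation, and immune infiltration.
The analysis implemented here isolates the immune axis without
supervision, converts it into a gene signature, and scores that signature
in single samples so that a new biopsy can be evaluated prospectively,
without reference to the discovery cohort. The downstream claims — that
the score predicts ex vivo TIL reactivity, correlates with repertoire
diversity, and separates cell-type composition — are each implemented as
their own module.

# Discovery model and assumptions

Raw counts are normalized with **median-of-ratios size factors**: the
reference is the per-gene geometric mean over samples (restricted to
genes positive in every sample) and each sample's factor is the median
count-to-reference ratio. This assumes most genes are not differentially
expressed between samples — the standard bulk RNA-seq assumption.

Normalized counts are transformed with **log2(x + 1)**. A
dispersion-model-based variance-stabilizing transform would differ in
detail, but every downstream consumer of this matrix is either PCA (which
needs only approximate variance stabilization) or rank-based scoring and
Spearman correlation, which are invariant to any monotone within-sample
transform; the simpler transform is therefore adequate and exactly
reproducible.

**PCA** is computed by singular value decomposition of the gene-centered
matrix over the top-variance genes, with no scaling to unit variance:
scaling would equalize the contribution of noise-floor genes with the
planted biology, and the discovery logic relies on variance ordering. The
arbitrary sign of each component is fixed deterministically (the
largest-magnitude loading is made positive); the axis-identification step
is invariant to this convention, since flipping a PC flips the reported
direction and selects the same genes.

**Axis identification** correlates per-sample gene-set enrichment scores
(unidirectional rank scores on TPM) with PC coordinates using Spearman's
rho with average-rank ties, then picks the PC with the largest absolute
mean rho across the named immune/inflammatory probe sets; the sign of
that mean is the axis direction. Exact ties go to the lowest PC index. An
exclusivity ratio (winner over runner-up) is reported as a diagnostic: a
ratio near 1 means the immune program is not cleanly separated from the
other covariance axes. Candidate PCs default to the first three,
reflecting the common situation where the leading few components carry
the bulk of variance and later ones are individually small; the set is
configurable through `n_components`.

**Signature selection** keeps every PCA-input gene whose loading on the
immune PC strictly matches the axis direction; zero loadings are
excluded, and no supervised filtering is applied. The counts of positive,
negative and zero loadings are recorded in the signature's provenance.
The positive-direction and negative-direction selections, together with
zero-loading genes, partition the PCA gene set.

Gene-set clustering (for the heatmap-style grouping of probe sets) uses
complete-linkage hierarchical clustering on Euclidean distances between
PC-correlation profiles, cut at `k = 4` by default; complete linkage is
the default of the common heatmap tools and is deterministic.

# Rank scoring

The **unidirectional score** of a set of $n_s$ genes in a sample of $N$
genes ranks all genes ascending (average ranks on ties) and rescales the
set's mean rank between its achievable extremes,
$(n_s + 1)/2$ and $(2N - n_s + 1)/2$, giving a score in $[0, 1]$ with 0.5
as the random-set expectation. The **bidirectional score** adds an
equivalent component computed on reversed ranks for the
expected-downregulated genes; a signature with an empty down component is
rejected rather than silently reduced, to keep the mode an explicit
choice. Signature genes absent from a sample's universe are dropped per
sample and the used set size is recorded — single-sample robustness to
panel differences matters more than strict universe agreement.

Scores are reported uncentered in $[0, 1]$ by default; `centered = TRUE`
subtracts 0.5 per component. Which convention a published score used is
generally not recoverable from its printed range alone, so both are
exposed and neither is privileged beyond the default.

The **per-cell capped-rank score** ranks genes descending, replaces ranks
beyond `r_max` (default 1500) with `r_max + 1`, and maps the resulting
Mann-Whitney U statistic to $[0, 1]$. Two numerical choices matter:

* A set whose genes all fall beyond the cap is clamped to exactly 0. The
  raw formula would return $(n-1)/(2\,r_{max})$ — a small positive
  artifact — and the cataloging rule "score > 0" must mean "at least one
  marker inside the rank cap" to be well defined.
* `r_max` must be at least the set size; below that the normalization is
  undefined and the call errors.

The descending convention here versus ascending in the bulk score matches
each method's definition; both are documented at the operation level to
prevent convention drift.

# Reactivity classification and benchmarking

A TIL culture is tumor reactive when 4-1BB expression exceeds 1% of CD3+
cells and is at least twice the effective background, or IFN-γ release
exceeds 100 pg/ml and is at least twice background. The absolute gates
are strict inequalities and the background comparisons are inclusive,
following the rule's phrasing exactly; with zero background only the
absolute gate binds. Two control conditions exist (TIL alone, TIL +
autologous APCs) but the combination rule is not standardized; the
default takes their **maximum** — the conservative choice — with `sum`
and `apc_only` selectable. Percent-reactive is 100 times the reactive
fraction of a sample's cultures.

ROC curves are computed directly on the predictor by sweeping all
distinct thresholds with tied scores grouped; this is monotone-equivalent
to the ROC of a univariate logistic model, so the logistic fit is
omitted. AUC is the trapezoid area, which equals the concordant-pair
fraction with ties counted one half (verified against a brute-force pair
count in the tests). Benchmarking reports Spearman rho against continuous
percent-reactive plus AUC at the ≥33% threshold, with FDR adjustment
across predictors.

# Repertoire metrics

Shannon diversity uses natural logarithms; clonality is $1 - H/\ln S$,
which is base-independent. Clonotype identity is (chain, amino-acid
CDR3); V/J segments are ignored. Samples with fewer than two unique
clonotypes for a chain have undefined clonality and are excluded from
that chain's analysis only — an explicit, logged exclusion rather than an
NA propagating silently. Public clonotypes are those observed in at least
two samples.

# Single-cell cataloging

Cells are assigned to broad buckets in fixed precedence: immune if the
PTPRC score is positive, else tumor if the melanoma marker panel (SOX10,
S100A1, MITF, MLANA, PMEL, TYR) scores positive, else stroma. Granular
immune phenotyping via reference-atlas mapping is out of scope — the
atlas is an external artifact — so the catalog stops at the bucket level
the rules define.

Composition testing transforms per-sample proportions with arcsin square
root and applies an ordinary two-sample t-test per cell type, with FDR
across cell types; fold enrichment is the ratio of mean untransformed
proportions (high over low). A moderated-variance test would differ at
very small group sizes; results are not claimed identical to one.
Degenerate inputs are handled explicitly: identical transformed values in
both groups give p = 1, and zero variance with differing means is
reported as missing with a warning rather than a fabricated p-value.

Differential expression between score groups uses a two-sided Wilcoxon
rank-sum test per gene with `log2fc = log2((mean_high + 1) / (mean_low +
1))` (pseudocount 1 on normalized expression), FDR adjustment, and the
filter |log2fc| ≥ 0.5 and FDR < 0.05. The sign convention is
high-versus-low, so genes elevated in low-score samples carry negative
fold changes.

# The synthetic cohort generator

The study conditions the package is tested under are produced by
`cohort_config()` / `simulate_cohort()`. A latent inflammation level
$\theta_j \sim U(0,1)$ per sample drives every compartment:

* **Bulk counts**: negative binomial, per-gene baseline log2 means
  uniform in `baseline_log_mean_range = c(3, 8)`, immune program genes
  shifted by `immune_effect * theta` (default 2 log2 units at full
  inflammation), each decoy program shifted by `decoy_effect` (default 1)
  times its own independent uniform latent factor, dispersion
  `nb_dispersion = 0.1`. Defaults: 60 samples, 2000 genes, a 150-gene
  immune program and two 100-gene decoys. The decoys are deliberately
  weaker than the immune program: they must create competing covariance
  axes without drowning the planted signal, since the purpose of the
  generator is a cohort on which discovery *should* succeed — effect
  sizes are artifact choices, not estimates of the real cohort.
* **Reactivity**: each of 24 cultures per sample is truly reactive with
  probability `plogis(-3 + 6 * theta)`; reactive cultures draw readouts
  guaranteed above both gates and twice their simulated controls,
  non-reactive cultures below the absolute gates. The logistic-link
  defaults are calibrated to the artifact (the real dose-response of
  inflammation on reactivity probability is unknown).
* **Repertoires**: unique clonotype numbers grow with theta inside
  `repertoire_clones_range = c(2, 150)` (Poisson-jittered), clone counts
  are geometric with decay 0.15, CDR3s are random strings over the 20
  standard amino acids, length 8–20, for both TRB and TRA.
* **Cells**: six samples are profiled by default — the three highest and
  three lowest theta, mirroring a disparate-score single-cell design —
  at 300 cells each. Immune cells express PTPRC highly, tumor cells the
  marker panel, stroma cells none of the seven markers. Background
  expression is per-gene Poisson with rates in (0.5, 3), which leaves
  roughly a fifth of the 2000-gene universe undetected per cell; with
  average-tie ranking the undetected block then sits beyond the default
  rank cap of 1500, as it does in a full transcriptome, keeping
  "score > 0" meaningful at desk scale.

One global seed drives per-component substreams (bulk, reactivity,
repertoire, cells, gene sets), so each compartment can be regenerated
independently and identical configs give bit-identical output.

**What the generator does not emulate**: raw reads and UMIs, library-size
confounding, batch effects, doublets and ambient RNA, somatic variation
(TMB appears only as an inflammation-independent lognormal covariate for
benchmarking), biologically structured CDR3 sequences, and correlated
gene-gene noise beyond the planted programs. Passing the
parameter-recovery tests therefore shows the pipeline is correct and
well-calibrated under its own assumptions — not that it would achieve the
same recovery on real tumor data, where the immune axis is weaker and
confounded.

# Problem sizes and determinism

The test suite and acceptance script use the default cohort (60 samples x
2000 genes, 1800 cells), sizes chosen so the full discovery chain runs in
seconds while keeping the planted-program recovery statistically stable.
All randomness flows from explicit integer seeds; reruns are
bit-identical, and the pipeline manifest records md5 digests of every
output to make that checkable.

# Known limitations

* The log2(x+1) stand-in for a model-based variance stabilization changes
  PCA loadings slightly relative to a dispersion-aware transform; the
  rank-based downstream is unaffected, but loading-sign membership for
  genes very close to zero loading can differ.
* The signature selection takes the loading-sign rule literally; any
  additional filtering a published gene list may have undergone is not
  modeled, and provenance records the sign counts so users can audit the
  split.
* Percent-reactive treats cultures as exchangeable; fragment-level
  heterogeneity within a metastasis is not modeled.
* The composition test is unmoderated and will be anticonservative for
  group sizes of 2–3 relative to moderated alternatives.
* `dichotomize_by_median` sends median ties to the low group; with many
  tied scores the groups can be unbalanced.
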