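# The default synthetic cohort and its discovery run are shared across
# test files; generated once per session, lazily.
.cohort_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.cohort_cache$cohort))
    .cohort_cache$cohort <- simulate_cohort(cohort_config())
  .cohort_cache$cohort
}

default_discovery <- function() {
  if (is.null(.cohort_cache$discovery)) {
    coh <- default_cohort()
    .cohort_cache$discovery <-
      discover_signature(coh$counts, coh$genesets, coh$immune_set_names)
  }
  .cohort_cache$discovery
}
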