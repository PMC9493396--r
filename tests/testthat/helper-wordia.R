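# Shared helpers: independent oracles and a small cached synthetic dataset.

# Brute-force pairwise-comparison oracle for the ROC area: one comparison
# per baseline image against the within-image fraction. Independent of the
# cumulative-curve/trapezoid implementation.
auc_pairwise_oracle <- function(within, baseline) {
  score <- ifelse(baseline < within, 1, ifelse(baseline == within, 0.5, 0))
  mean(score)
}

# random report fractions on a discrete grid (denominator as in a cohort)
rand_fracs <- function(n, denom = 9L) {
  sample(0:denom, n, replace = TRUE) / denom
}

# a small full-design dataset: 2 blocks x 6 images x 12 participants
# (4 per cell), cleaned and assembled, cached across tests in one file
small_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_reports(
        sim_config(n_blocks = 2L, images_per_block = 6L,
                   participants_per_block = 12L,
                   n_similar_natural = 2L, n_similar_artificial = 1L),
        seed = 101)
      cl <- clean_table(sim$records)
      cache <<- list(sim = sim, records = cl$records,
                     report = cl$report,
                     x = ia_data(cl$records,
                                 similar_pairs = sim$similar_pairs))
    }
    cache
  }
})
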