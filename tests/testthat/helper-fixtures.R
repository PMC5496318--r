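# Small dataset builders used across test files.

# Two well-separated 1-D classes (classification is trivial).
separated_dataset <- function(n_per_class = 10L, gap = 100, seed = 1L) {
  set.seed(seed)
  vals <- c(rnorm(n_per_class, 0, 0.1), rnorm(n_per_class, gap, 0.1))
  matrix(vals, nrow = 1L,
         dimnames = list("g1", sprintf("s%02d", seq_len(2L * n_per_class))))
}

# Minimal "gaknn"-classed stub exposing only the fields the ensemble
# aggregation operations consume, for direct arithmetic checks.
fake_fit <- function(predictions, test_labels, classes,
                     test_ids = paste0("s", seq_along(test_labels)),
                     gene_ids = NULL, runs = NULL, chromosome_length = 2L) {
  structure(
    list(predictions = predictions, test_labels = test_labels,
         classes = classes, test_ids = test_ids, gene_ids = gene_ids,
         runs = runs, n_runs = nrow(predictions),
         config = list(chromosome_length = chromosome_length)),
    class = "gaknn"
  )
}

# The scaled-down planted-signal study: 5 classes x 30 samples, 1000 genes,
# 5 informative genes per class at effect 2 (sd 1); ensemble of 50 GA runs
# with 10-gene chromosomes, population 50, at most 50 generations. Computed
# once per session and reused by the acceptance checks.
scaled_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_expression(synthetic_spec(seed = 1L))
      ds <- log2_transform(sim$dataset)
      fit <- gaknn(ds, n_runs = 50L,
                   config = ga_config(chromosome_length = 10L,
                                      population_size = 50L,
                                      max_generations = 50L),
                   seed = 1L)
      cache <<- list(sim = sim, dataset = ds, fit = fit)
    }
    cache
  }
})
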