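# Lazily computed, cached quarter-scale experiment summaries shared by the
# acceptance-level tests. Only the summary statistics and information curves
# are retained; each (preset, seed) combination is simulated once per test
# session.
.experiment_cache <- new.env(parent = emptyenv())

experiment_summary <- function(name, seed, scale = 0.25, epochs = 5,
                               n_iterations = 20) {
  key <- paste(name, seed, scale, epochs, sep = "#")
  if (is.null(.experiment_cache[[key]])) {
    ex <- run_experiment(name, seed = seed, scale = scale, epochs = epochs,
                         n_iterations = n_iterations)
    .experiment_cache[[key]] <- list(
      summary = ex$summary,
      bits = ex$info$bits,
      single_bits = ex$info$single_cell$max_bits
    )
  }
  .experiment_cache[[key]]
}

median_metric <- function(name, metric, seeds = 1:3, ...) {
  stats::median(vapply(seeds, function(sd) {
    s <- experiment_summary(name, sd, ...)
    if (metric == "multi_max") max(s$bits) else s$summary[[metric]]
  }, numeric(1)))
}
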