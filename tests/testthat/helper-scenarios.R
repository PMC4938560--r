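# scenario runs shared between acceptance tests (trained once per session)

.scenario_cache <- new.env(parent = emptyenv())

scenario_summaries <- function(scenario, seeds = 1:5) {
  key <- paste0(scenario, "-", paste(seeds, collapse = "_"))
  if (is.null(.scenario_cache[[key]])) {
    .scenario_cache[[key]] <- lapply(seeds, function(s) {
      out <- run_experiment(experiment_config(scenario, seed = s,
                                              out_dir = tempfile()))
      attr(out, "summary")
    })
  }
  .scenario_cache[[key]]
}

n_of <- function(summaries, field, pred) {
  sum(vapply(summaries, function(s) isTRUE(pred(s[[field]])), logical(1)))
}
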