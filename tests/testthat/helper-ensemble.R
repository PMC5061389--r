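# Shared full-scale probabilistic ensemble for the headline-reproduction
# tests: built once per test session and reused (it is by far the most
# expensive fixture). 560 replications at 100,000 persons give a filtered
# current-scenario subgroup of roughly 200 runs.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_ensemble <- function() {
  if (is.null(.acceptance_cache$ensemble)) {
    cfg <- crcdemand::load_config()
    .acceptance_cache$config <- cfg
    .acceptance_cache$ensemble <- crcdemand::run_ensemble(cfg, n_runs = 560,
                                                          seed = 20150101)
    .acceptance_cache$filtered <-
      crcdemand::filter_scenario(.acceptance_cache$ensemble, cfg$run$filter)
  }
  .acceptance_cache
}
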