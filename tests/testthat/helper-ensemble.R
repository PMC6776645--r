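# The 200-event ensemble study is shared between two acceptance checks;
# compute it once per test run.
ensemble_cache <- new.env(parent = emptyenv())

cached_ensemble_study <- function() {
  if (is.null(ensemble_cache$study))
    ensemble_cache$study <- fusion_ensemble_study(n_events = 200,
                                                  seed = 1)
  ensemble_cache$study
}
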