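# The full default-scale altitude experiment is expensive (~1-2 min), so it
# runs once per test session and is shared by the acceptance checks.

.exp_cache <- new.env(parent = emptyenv())

default_experiment <- function() {
  if (is.null(.exp_cache$res)) {
    cfg <- experiment_config(out_dir = file.path(tempdir(), "seedstand_acc"),
                             seed = 1L, make_plots = FALSE)
    .exp_cache$res <- suppressMessages(run_experiment(cfg))
  }
  .exp_cache$res
}
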