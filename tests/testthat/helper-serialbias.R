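# Small shared simulation used across unit tests (trial-level only).
small_experiment <- function(seed = 101, ...) {
  args <- utils::modifyList(
    list(n_participants = 6, n_blocks = 2, n_trials_per_block = 60,
         seed = seed),
    list(...))
  simulate_experiment(do.call(sim_config, args))
}

# A tiny hand-built trial table with a known serial structure.
toy_trials <- function() {
  data.frame(
    participant = "s01", condition = "A", block = c(1, 1, 1, 2, 2),
    trial_index = c(1, 2, 3, 1, 2),
    target = c(10, 40, 350, 100, 100),
    report = c(12, 38, 352, 99, 103),
    report_rt = 1,
    stringsAsFactors = FALSE
  )
}
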