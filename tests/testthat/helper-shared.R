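# One full default-scale synthetic study, generated once per test run and
# shared by the end-to-end checks.

.shared <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.shared$sim)) {
    dir <- file.path(tempdir(), "evnet-shared-sim")
    .shared$sim <- simulate_all(sim_config(seed = 1234), dir)
  }
  .shared$sim
}
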