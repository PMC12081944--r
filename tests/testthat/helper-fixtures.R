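# Shared fixtures: all synthetic, built in code at test time.

# Ground truth with switchable variability/noise, for deterministic checks.
quiet_truth <- function(noise_sd = 0, offsets = c(real = 0, virtual = 0),
                        jitter = FALSE) {
  tr <- ground_truth_default(noise_sd = noise_sd, onset_offset = offsets)
  if (!jitter) {
    tr$components$subject_sd <- 0
    tr$components$cell_sd <- 0
    tr$components$latency_sd <- 0
  }
  tr
}

# Small feasible sequence spec for fast sessions.
small_seq <- function(n_total = 60, n_per_target = 4) {
  sequence_spec(n_total = n_total, n_per_target = n_per_target)
}

# One fully processed small session via the literal module chain.
literal_session <- function(truth, age = "younger", environment = "real",
                            seed = 11, seq_spec = small_seq(),
                            margin = 32) {
  ev <- generate_sequence(seq_spec, seed = seed)
  ev <- simulate_behavior(ev, truth, environment, seed = seed + 1)
  syn <- synthesize_participant(ev, truth, age, environment, seed = seed + 2)
  ep <- preprocess_session(syn$recording, ev, margin = margin)
  list(events = ev, recording = syn$recording, epochs = ep)
}

# Single-channel waveform from a vector (times in ms).
wf1 <- function(x, times = seq_along(x) - 1) erp_waveform(x, times)

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / max(abs(y), .Machine$double.eps), tol)
}
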