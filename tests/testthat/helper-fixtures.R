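# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A magnitude-sensitive main-task session with attached values.
main_behavior <- function() {
  fixture("main_behavior", function() {
    attach_values(simulate_agent(generate_schedule("main", 160, seed = 11),
                                 rl_params("reversal", 0.35, 4, w_mag = 2),
                                 seed = 12))
  })
}

# Strongly tuned parametric recording (types at clear gains).
parametric_recording <- function() {
  fixture("parametric_recording", function() {
    beh <- main_behavior()
    pop <- generate_population(80, seed = 13, gain_mean = 12, gain_sd = 2)
    generate_spike_counts(pop, beh, seed = 14)
  })
}

# Circuit-constrained recording used by the encoding/decoding/RSA tests:
# view-dominated population over a 160-trial session.
circuit_corpus <- function() {
  fixture("circuit_corpus", function() {
    beh <- main_behavior()
    cs <- simulate_circuit_session(circuit_params(), beh, seed = 15)
    beh <- align_behavior_to_circuit(beh, cs)
    props <- c(object_value_A = 0.08, object_value_B = 0.08,
               view_value_pos = 0.17, view_value_neg = 0.17,
               view_choice_current = 0.15, view_choice_last = 0.15,
               object_choice = 0.06, object_sequence = 0.05,
               combination = 0.07, untuned = 0.02)
    pop <- generate_population(60, props, seed = 16,
                               gain_mean = 15, gain_sd = 2)
    rec <- generate_spike_counts(pop, beh, rate_source = "circuit",
                                 circuit = cs, seed = 17)
    list(behavior = beh, circuit = cs, population = pop, recording = rec)
  })
}
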