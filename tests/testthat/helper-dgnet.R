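# Small configurations and protocols used across the suite.

tiny_config <- function(...) {
  network_config(n_gc = 6, n_mc = 2, n_in_a = 1, n_in_b = 1, ...)
}

# short schedule for engine-level tests (fractions of a day)
tiny_protocol <- function(...) {
  experiment_protocol(stim_start = 0.05, stim_duration_min = 30,
                      t_i = 0.1, gabaa_duration_days = 0.2,
                      inverted_fraction = 0.25, total_days = 0.3, ...)
}

# step-resolution activity trace builder for the event detector
make_trace <- function(s, step_days = 0.36 * 150 / 1440) {
  tibble::tibble(time_days = seq_along(s) * step_days, s_gc = s)
}
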