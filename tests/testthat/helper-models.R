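# Shared fixtures, built in code and memoised for the session.

fixtures <- new.env(parent = emptyenv())

# small interface + activation table used by excitation/fitting tests
toy_model <- function(n_fibers = 101, mean_deg = 5, seed = 2) {
  key <- paste0("toy", n_fibers, "_", mean_deg, "_", seed)
  if (is.null(fixtures[[key]])) {
    g <- build_geometry(geometry_config(n_fibers = n_fibers))
    g <- apply_degeneration(g, mean_deg, 3, seed = seed)
    fixtures[[key]] <- list(interface = g, act = unit_activation(g))
  }
  fixtures[[key]]
}

# desk-sized interface for filter-bank bound checks
desk_model <- function(mean_deg = 5, seed = 2) {
  toy_model(n_fibers = 301, mean_deg = mean_deg, seed = seed)
}

# a single-slot induced-current object for direct neuron-model tests:
# `amps_a` is the per-fiber anodic-phase current (A) applied to every pulse
# of a train with the given period
pulse_train_ic <- function(amps_a, n_pulses = 50, period_us = 540,
                           phase_us = 18, margin_us = 10000) {
  onsets <- margin_us + (seq_len(n_pulses) - 1) * period_us
  structure(list(
    I = matrix(rep(amps_a, n_pulses), nrow = length(amps_a)),
    onset_us = onsets, phase_us = phase_us,
    duration_us = margin_us * 2 + n_pulses * period_us,
    M_C = 89.525e6), class = "induced_current")
}

# deterministic neuron parameters (no noise, no adaptation)
det_params <- function(...) {
  neuron_params(sigma_noise = 0, a_supra = 0, q_sub = 0, ...)
}
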