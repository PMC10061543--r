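## Dual adaptive integrate-and-fire auditory nerve fiber population.
##
## Each fiber is modeled as two independent leaky integrate-and-fire
## circuits - one cathodic-excitatory (the peripheral axon) and one
## anodic-excitatory (the central axon) - coupled by a logical OR: a
## threshold crossing in either circuit produces a spike, after which both
## circuits reset and the fiber is silenced for the absolute refractory
## period. The circuits share the induced current I(t) but receive
## phase-split drives with an inhibitory compression of the non-preferred
## phase.

#' Neuron model parameters
#'
#' Capacitances, the inhibitory compression and the refractory period are
#' fixed model constants; the passive filter, the sub- and suprathreshold
#' adaptation processes and the membrane noise are first-order processes
#' whose internals are exposed here. The threshold and noise amplitude are
#' the two calibration knobs of the peripheral model (see the methods
#' vignette); together with the activation-to-current factor `M_C` they
#' were fixed once so that most-comfortable levels stay below 250 CU in
#' every neural health condition.
#'
#' @param beta inhibitory compression applied to the non-preferred phase.
#' @param C_cathodic_f,C_anodic_f membrane capacitances (F).
#' @param tau_m_us passive membrane time constant (us); the passive filter
#'   is `h(V) = -(C/tau_m) V`.
#' @param v_thr threshold voltage (V).
#' @param v_reset reset voltage (V).
#' @param arp_us absolute refractory period (us).
#' @param tau_sub_us,q_sub subthreshold adaptation: a first-order tracker
#'   of the membrane voltage with gain `q_sub` (A/V).
#' @param tau_supra_us,a_supra suprathreshold adaptation: decaying current
#'   incremented by `a_supra` (A) at each spike.
#' @param tau_noise_us,sigma_noise membrane noise: an Ornstein-Uhlenbeck
#'   current with correlation time `tau_noise_us` and stationary standard
#'   deviation `sigma_noise` (A); 0 disables noise (deterministic output).
#' @return list of parameters.
#' @export
neuron_params <- function(beta = 0.75,
                          C_cathodic_f = 856.96e-9,
                          C_anodic_f = 1772.4e-9,
                          tau_m_us = 300,
                          v_thr = 2.5e-3,
                          v_reset = 0,
                          arp_us = 500,
                          tau_sub_us = 50e3, q_sub = 5e-4,
                          tau_supra_us = 10e3, a_supra = 5e-7,
                          tau_noise_us = 100, sigma_noise = 1.75e-6) {
  as.list(environment())
}

#' Split an induced current into circuit-specific drives
#'
#' With `I+` and `I-` the positive and negative parts of the induced
#' current, the cathodic-excitatory circuit receives `-(I- + beta I+)` and
#' the anodic-excitatory circuit `I+ + beta I-`: each circuit is excited by
#' its preferred phase and inhibited by a compressed copy of the other.
#'
#' @param I induced current (A), any shape.
#' @param beta inhibitory compression.
#' @return list with elements `cathodic` and `anodic`.
#' @export
split_phases <- function(I, beta = 0.75) {
  ip <- pmax(I, 0); im <- pmin(I, 0)
  list(cathodic = -(im + beta * ip), anodic = ip + beta * im)
}

#' Simulate spike trains for a fiber population
#'
#' Integrates both circuits of every fiber with an exponential-Euler scheme
#' on an event-aligned grid: the step is at most `dt_pulse_us` inside pulse
#' phases and `dt_gap_us` in stimulation gaps (the drive is piecewise
#' constant, so the membrane update is exact between grid points). Each
#' fiber draws its noise from an independent stream derived from `seed`, so
#' a fiber's spike train does not depend on which other fibers are
#' simulated.
#'
#' @param ic an [induced_current()], or a matrix `[n_fibers, n_slots]` of
#'   anodic-phase currents (A) together with `onset_us`/`phase_us`/
#'   `duration_us` attributes as produced internally.
#' @param params see [neuron_params()].
#' @param seed integer seed for the population noise.
#' @param dt_pulse_us integration step inside pulse phases (us).
#' @param dt_gap_us integration step in gaps (us).
#' @param fibers optional subset of fiber indices to simulate.
#' @return object of class `spike_activity`: list with `times` (list of
#'   sorted spike-time vectors, seconds), `fibers` (indices simulated),
#'   `duration_s` and `seed`.
#' @export
simulate_spikes <- function(ic, params = neuron_params(), seed = 1,
                            dt_pulse_us = 2, dt_gap_us = 20,
                            fibers = NULL) {
  stopifnot(inherits(ic, "induced_current"))
  I <- ic$I
  if (!is.null(fibers)) I <- I[fibers, , drop = FALSE] else
    fibers <- seq_len(nrow(I))
  pv <- with(params, c(beta, C_cathodic_f, C_anodic_f, tau_m_us, v_thr,
                       v_reset, arp_us, tau_sub_us, q_sub, tau_supra_us,
                       a_supra, tau_noise_us, sigma_noise))
  ## per-fiber seeds tied to the global fiber index (seed isolation)
  seeds <- vapply(fibers, function(f)
    as.double(derive_seed(seed, paste0("fiber", f))), numeric(1))
  if (!all(is.finite(I))) stop("non-finite induced current")
  st <- cpp_lif_population(I, ic$onset_us, ic$phase_us, ic$duration_us,
                           pv, dt_pulse_us, dt_gap_us, seeds)
  structure(list(times = st, fibers = fibers,
                 duration_s = ic$duration_us * 1e-6, seed = seed),
            class = "spike_activity")
}

#' @export
print.spike_activity <- function(x, ...) {
  n <- sum(lengths(x$times))
  cat(sprintf("spike activity: %d fibers, %d spikes over %.3f s\n",
              length(x$times), n, x$duration_s))
  invisible(x)
}

#' Total spike count of a spike activity
#' @param spikes a `spike_activity`.
#' @return integer count.
#' @export
spike_count <- function(spikes) sum(lengths(spikes$times))
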