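## Voltage spread, activation function and induced current.
##
## The extracellular medium is homogeneous: a point-source electrode
## carrying current I produces U = rho_ext * I / (4 pi d) at distance d.
## The activation function is the discrete second difference of the
## external potential along a fiber's nodes divided by the axon internal
## resistance; it carries units of amperes here because the membrane
## capacitance is applied later, inside the neuron model. The induced
## current fed to a fiber's neuron model is M_C times the combined
## (summed-over-electrodes) activation at the node where its absolute
## value is largest.

#' Physical constants of the excitation model
#'
#' @param rho_ext_ohm_m extracellular resistivity (Ohm m).
#' @param axon_diameter_m axon diameter D (m).
#' @param axial_resistivity_ohm_m axial resistivity r (Ohm m).
#' @param internode_m internodal length L_i (m).
#' @return list with the constants and the derived axon internal
#'   resistance `R_i = 4 L_i r / (pi D^2)` (Ohm).
#' @export
excitation_constants <- function(rho_ext_ohm_m = 3.0,
                                 axon_diameter_m = 2.0e-6,
                                 axial_resistivity_ohm_m = 1.0,
                                 internode_m = 200e-6) {
  R_i <- 4 * internode_m * axial_resistivity_ohm_m /
    (pi * axon_diameter_m^2)
  list(rho_ext_ohm_m = rho_ext_ohm_m, axon_diameter_m = axon_diameter_m,
       axial_resistivity_ohm_m = axial_resistivity_ohm_m,
       internode_m = internode_m, R_i = R_i)
}

#' Point-source extracellular potential
#'
#' `U = rho_ext * I / (4 pi d)`.
#'
#' @param current_a electrode current (A).
#' @param distance_m electrode-node distance (m), strictly positive.
#' @param rho_ext extracellular resistivity (Ohm m).
#' @return potential (V).
#' @export
point_source_voltage <- function(current_a, distance_m, rho_ext = 3.0) {
  if (any(distance_m <= 0)) stop("zero or negative electrode-node distance")
  rho_ext * current_a / (4 * pi * distance_m)
}

#' Potentials at every node of every fiber
#'
#' Evaluates the point-source potential of each electrode at each node;
#' superposition across electrodes is left to the caller (the activation
#' function and induced current are linear in the potentials).
#'
#' @param interface an `eni`.
#' @param electrode_currents_ua length-16 vector of electrode currents (uA).
#' @param rho_ext extracellular resistivity (Ohm m).
#' @return array `[n_nodes, n_fibers, n_electrodes]` of potentials (V).
#' @export
voltage_at_nodes <- function(interface, electrode_currents_ua,
                             rho_ext = 3.0) {
  stopifnot(inherits(interface, "eni"))
  n_el <- nrow(interface$electrodes)
  stopifnot(length(electrode_currents_ua) == n_el)
  dims <- dim(interface$nodes)
  out <- array(0, dim = c(dims[1], dims[3], n_el))
  for (e in seq_len(n_el)) {
    d_mm <- node_electrode_distance(interface, e)
    out[, , e] <- point_source_voltage(electrode_currents_ua[e] * 1e-6,
                                       d_mm * 1e-3, rho_ext)
  }
  out
}

## distance (mm) from electrode e to every node: matrix n_nodes x n_fibers
node_electrode_distance <- function(interface, e) {
  p <- interface$electrodes[e, ]
  sqrt((interface$nodes[, 1, ] - p[1])^2 +
       (interface$nodes[, 2, ] - p[2])^2 +
       (interface$nodes[, 3, ] - p[3])^2)
}

#' Activation function along one fiber
#'
#' Interior nodes get
#' `A_a = (U_{a-1} - U_a)/R_i + (U_{a+1} - U_a)/R_i`. End nodes - the
#' fiber's central tip and, after degeneration, the new most-peripheral
#' node - lack a neighbour and are excluded from the activation function
#' (their entry is zero and they never become the maximising node). A
#' one-sided end-node rule is deliberately not used: because it reduces to
#' a first difference it can raise the peak activation as degeneration
#' progresses, which is inconsistent with a worsening neural state.
#'
#' @param U potentials at the fiber's effective nodes (V), length >= 3.
#' @param R_i axon internal resistance (Ohm).
#' @return activation per node (A), same length as `U`; the two end
#'   entries are 0 (excluded).
#' @export
activation_function <- function(U, R_i = excitation_constants()$R_i) {
  n <- length(U)
  if (n < 3) stop("degenerate fiber: fewer than 3 effective nodes")
  d1 <- diff(U)                    # U_{a+1} - U_a
  A <- numeric(n)
  A[2:(n - 1)] <- (d1[2:(n - 1)] - d1[1:(n - 2)]) / R_i
  A
}

#' Unit-current activation table
#'
#' Activation at every effective node of every fiber for 1 A on each
#' electrode. Degenerated nodes hold zeros. This is the cache that the
#' induced-current computation, virtual fitting and fiber grouping all
#' share.
#'
#' @param interface an `eni`.
#' @param constants see [excitation_constants()].
#' @return object of class `activation_table`: list with `A` (array
#'   `[n_nodes, n_fibers, 16]`, A per A), `peak` (matrix
#'   `[n_fibers, 16]` of max absolute activation per fiber and electrode)
#'   and `constants`.
#' @export
unit_activation <- function(interface, constants = excitation_constants()) {
  stopifnot(inherits(interface, "eni"))
  dims <- dim(interface$nodes)
  n_nodes <- dims[1]; n_fib <- dims[3]
  n_el <- nrow(interface$electrodes)
  R_i <- constants$R_i
  A <- array(0, dim = c(n_nodes, n_fib, n_el))
  alpha <- interface$alpha
  groups <- split(seq_len(n_fib), alpha)
  for (e in seq_len(n_el)) {
    d_mm <- node_electrode_distance(interface, e)
    U <- constants$rho_ext_ohm_m * 1.0 / (4 * pi * (d_mm * 1e-3))
    D1 <- U[-1, , drop = FALSE] - U[-n_nodes, , drop = FALSE]
    Ae <- matrix(0, n_nodes, n_fib)
    Ae[2:(n_nodes - 1), ] <- (D1[2:(n_nodes - 1), , drop = FALSE] -
                              D1[1:(n_nodes - 2), , drop = FALSE]) / R_i
    for (g in names(groups)) {
      a <- as.integer(g); fs <- groups[[g]]
      if (a > 0) Ae[1:(a + 1L), fs] <- 0   # removed nodes + new end node
    }
    A[, , e] <- Ae
  }
  peak <- apply(abs(A), c(2, 3), max)
  structure(list(A = A, peak = peak, constants = constants),
            class = "activation_table")
}

## node activations for a steering configuration: current split (1-c) on
## the apical electrode of the channel and c on the basal one
steering_config_activation <- function(act, channel, steering) {
  (1 - steering) * act$A[, , channel] + steering * act$A[, , channel + 1L]
}

#' Induced current per fiber from an electrodogram
#'
#' For every stimulation slot (a set of simultaneously active virtual
#' channels), the combined activation per node is formed by superposition
#' of the active electrode currents; the node `a_max` with the maximum
#' absolute combined activation is selected per fiber and instant, and the
#' induced current is `M_C` times the signed combined activation there.
#' The value is computed for the anodic phase; the cathodic phase is its
#' negation (the waveform is piecewise constant).
#'
#' Fibers whose peak unit activation for every active channel falls below
#' `support_rel` times the population maximum for that channel receive
#' exactly zero (they are unstimulated for that slot).
#'
#' @param elg an `electrodogram`.
#' @param interface an `eni`.
#' @param M_C calibration factor coupling activation to the neuron model's
#'   stimulation current (default 89.525e6).
#' @param act optional precomputed [unit_activation()] table.
#' @param support_rel relative support cutoff.
#' @return object of class `induced_current`: list with `I` (matrix
#'   `[n_fibers, n_slots]`, A, anodic-phase value), `onset_us`, `phase_us`,
#'   `duration_us`, `M_C`.
#' @export
induced_current <- function(elg, interface, M_C = 89.525e6, act = NULL,
                            support_rel = 1e-3) {
  stopifnot(inherits(elg, "electrodogram"), inherits(interface, "eni"))
  if (is.null(act)) act <- unit_activation(interface)
  n_fib <- dim(act$A)[2]
  if (nrow(elg) == 0) {
    return(structure(list(I = matrix(0, n_fib, 0), onset_us = numeric(0),
                          phase_us = 18, duration_us = 0, M_C = M_C),
                     class = "induced_current"))
  }
  phase_us <- elg$phase_us[1]

  ## configurations in use: (channel, steering) pairs
  cfg_key <- paste(elg$channel, elg$steering)
  cfg_tab <- unique(data.frame(channel = elg$channel,
                               steering = elg$steering,
                               key = cfg_key, stringsAsFactors = FALSE))
  cfg_idx <- match(cfg_key, cfg_tab$key)
  n_nodes <- dim(act$A)[1]
  n_cfg <- nrow(cfg_tab)
  cfgA <- array(0, dim = c(n_nodes, n_fib, n_cfg))
  support <- matrix(FALSE, n_fib, n_cfg)
  for (j in seq_len(n_cfg)) {
    cf <- steering_config_activation(act, cfg_tab$channel[j],
                                     cfg_tab$steering[j])
    cfgA[, , j] <- cf
    pk <- apply(abs(cf), 2, max)
    support[, j] <- pk >= support_rel * max(pk)
  }

  ## slots: events grouped by onset
  ord <- order(elg$onset_us, elg$channel)
  onset <- elg$onset_us[ord]
  amp_a <- cu_to_microamps(elg$amplitude_cu[ord], elg$phase_us[ord]) * 1e-6
  cfg_o <- cfg_idx[ord]
  slot_id <- cumsum(c(1L, diff(onset) > 1e-9))
  slot_onset <- onset[!duplicated(slot_id)]
  slot_ptr <- c(0L, cumsum(tabulate(slot_id)))

  I <- cpp_slot_currents(cfgA, c(n_nodes, n_fib, n_cfg), support,
                         as.integer(slot_ptr), as.integer(cfg_o - 1L),
                         amp_a, M_C)
  structure(list(I = I, onset_us = slot_onset, phase_us = phase_us,
                 duration_us = attr(elg, "duration_us"), M_C = M_C),
            class = "induced_current")
}

#' @export
print.induced_current <- function(x, ...) {
  cat(sprintf("induced current: %d fibers x %d slots, peak |I| = %.3g mA\n",
              nrow(x$I), ncol(x$I),
              if (length(x$I)) max(abs(x$I)) * 1e3 else 0))
  invisible(x)
}
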