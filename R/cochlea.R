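## Parametric 3D electrode-nerve interface.
##
## The cochlea is a logarithmic spiral in right-handed mm coordinates with
## the modiolar axis as z. Auditory nerve fibers (ANFs) start at their
## peripheral terminal on the basilar-membrane (BM) spiral, run radially
## toward the modiolar axis, then centrally along it, as a chain of nodes
## separated by a constant 200 um internodal length. The electrode array is
## a 22-contact template placed on an offset spiral inside the scala
## tympani, from which 6 contacts are removed to obtain the 16-electrode
## configuration. Degeneration removes segments strictly from the
## peripheral end of each fiber.

#' Geometry configuration
#'
#' All spiral and array parameters of the parametric interface. The default
#' population is 9001 fibers at 0.1 degree spacing over 900 degrees of
#' insertion angle (two and a half turns); smaller `n_fibers` decimate the
#' population uniformly over the same span.
#'
#' @param n_fibers number of ANFs.
#' @param span_deg angular span of the BM spiral (degrees).
#' @param bm_length_mm BM length (mm).
#' @param radius_ratio basal-to-apical BM radius ratio of the log spiral.
#' @param height_mm total z rise of the spiral from base to apex (mm).
#' @param n_segments segments per fiber (nodes = segments + 1).
#' @param internode_mm internodal length (mm).
#' @param axial_drop_mm fibers run along the straight line from their BM
#'   terminal toward the point on the modiolar axis this far below the
#'   terminal, emulating the oblique course toward the spiral ganglion and
#'   the nerve trunk (mm).
#' @param elec_offset_radial_mm radial offset of the scala-tympani path
#'   relative to the BM spiral (mm); positive values move the contacts
#'   toward the modiolus, negative values toward the lateral wall.
#' @param elec_offset_z_mm z offset of the electrode path (mm); the scala
#'   tympani lies below the basilar membrane.
#' @param insertion_depth_mm arc-length insertion depth of the deepest
#'   (most apical) template contact (mm).
#' @param elec_pitch_mm template contact pitch along the array (mm).
#' @return list of geometry parameters.
#' @export
geometry_config <- function(n_fibers = 9001, span_deg = 900,
                            bm_length_mm = 42, radius_ratio = 2.8,
                            height_mm = 2.0, n_segments = 30,
                            internode_mm = 0.2, axial_drop_mm = 5.0,
                            elec_offset_radial_mm = -0.8,
                            elec_offset_z_mm = -2.4,
                            insertion_depth_mm = 20,
                            elec_pitch_mm = 0.75) {
  as.list(environment())
}

#' Build the parametric electrode-nerve interface
#'
#' @param config geometry parameters, see [geometry_config()].
#' @return object of class `eni` with elements:
#'   `nodes` (array n_nodes x 3 x n_fibers, mm; node 1 is the peripheral
#'   terminal), `alpha` (per-fiber degeneration index, initially 0),
#'   `insertion_angle_deg`, `bm_arc_mm` (arc position of each terminal),
#'   `electrodes` (16 x 3 matrix, row 1 most apical), `config`.
#' @export
build_geometry <- function(config = geometry_config()) {
  cfg <- config
  if (cfg$bm_length_mm <= 0 || cfg$span_deg <= 0 || cfg$n_fibers < 2)
    stop("inconsistent geometry configuration")
  theta_max <- cfg$span_deg * pi / 180
  b <- log(cfg$radius_ratio) / theta_max
  ## planar arc length of r = r0 exp(-b theta): s = sqrt(1+b^2)/b (r0 - r)
  dr <- cfg$bm_length_mm * b / sqrt(1 + b^2)
  r0 <- dr * cfg$radius_ratio / (cfg$radius_ratio - 1)

  ang_deg <- seq(0, cfg$span_deg, length.out = cfg$n_fibers)
  theta <- ang_deg * pi / 180
  r_bm <- r0 * exp(-b * theta)
  x_bm <- r_bm * cos(theta)
  y_bm <- r_bm * sin(theta)
  z_bm <- cfg$height_mm * theta / theta_max

  n_nodes <- cfg$n_segments + 1L
  nodes <- array(NA_real_, dim = c(n_nodes, 3, cfg$n_fibers))
  arc <- seq(0, by = cfg$internode_mm, length.out = n_nodes)
  for (f in seq_len(cfg$n_fibers)) {
    p0 <- c(x_bm[f], y_bm[f], z_bm[f])
    target <- c(0, 0, z_bm[f] - cfg$axial_drop_mm)
    u <- (target - p0) / sqrt(sum((target - p0)^2))
    nodes[, , f] <- cbind(p0[1] + arc * u[1], p0[2] + arc * u[2],
                          p0[3] + arc * u[3])
  }

  ## BM arc position of each terminal (cumulative chord length, rescaled)
  seglen <- sqrt(diff(x_bm)^2 + diff(y_bm)^2 + diff(z_bm)^2)
  s_raw <- c(0, cumsum(seglen))
  bm_arc <- s_raw / s_raw[cfg$n_fibers] * cfg$bm_length_mm

  electrodes <- electrode_positions(cfg, r0, b)

  structure(list(
    nodes = nodes,
    alpha = integer(cfg$n_fibers),
    insertion_angle_deg = ang_deg,
    bm_arc_mm = bm_arc,
    electrodes = electrodes,
    config = cfg
  ), class = "eni")
}

## 22-contact template on the scala-tympani path; contacts 21, 19, 17, 15,
## 13 and 11 (1 = most apical) are removed to obtain 16 electrodes
electrode_positions <- function(cfg, r0, b) {
  depth <- cfg$insertion_depth_mm - (0:21) * cfg$elec_pitch_mm
  if (any(depth <= 0)) stop("electrode template extends outside the cochlea")
  r_at <- r0 - depth * b / sqrt(1 + b^2)
  theta <- log(r0 / r_at) / b
  theta_max <- cfg$span_deg * pi / 180
  r_st <- r0 * exp(-b * theta) - cfg$elec_offset_radial_mm
  z_st <- cfg$height_mm * theta / theta_max + cfg$elec_offset_z_mm
  keep <- setdiff(1:22, c(21, 19, 17, 15, 13, 11))
  pos <- cbind(r_st * cos(theta), r_st * sin(theta), z_st)[keep, ]
  rownames(pos) <- paste0("e", seq_len(nrow(pos)))
  colnames(pos) <- c("x", "y", "z")
  pos
}

#' @export
print.eni <- function(x, ...) {
  cat(sprintf(
    "electrode-nerve interface: %d fibers over %g deg, %d electrodes\n",
    length(x$alpha), x$config$span_deg, nrow(x$electrodes)))
  cat(sprintf("  nodes/fiber: %d (internode %g mm); degeneration: mean %.2f [%d..%d]\n",
              dim(x$nodes)[1], x$config$internode_mm, mean(x$alpha),
              min(x$alpha), max(x$alpha)))
  invisible(x)
}

#' Health presets: mean number of degenerated peripheral segments
#'
#' "healthy" = 5, "moderate" = 10, "severe" = 15 mean degenerated nodes;
#' "ideal" (0) and "total" (20) are the two reference extremes.
#' @return named numeric vector.
#' @export
health_presets <- function() {
  c(ideal = 0, healthy = 5, moderate = 10, severe = 15, total = 20)
}

#' Apply neural degeneration to an interface
#'
#' Draws a per-fiber degeneration index `alpha_f = round(N(mean, sd))`
#' clipped to `[0, 20]`; `alpha_f` peripheral segments are removed from the
#' fiber (strictly peripheral-first) in all downstream computations.
#'
#' @param interface an `eni`.
#' @param mean_nodes mean number of degenerated segments, in `[0, 20]`.
#' @param sd_nodes standard deviation (nodes).
#' @param seed RNG seed.
#' @return the interface with its `alpha` vector replaced.
#' @export
apply_degeneration <- function(interface, mean_nodes, sd_nodes = 3, seed = 1) {
  stopifnot(inherits(interface, "eni"))
  if (mean_nodes < 0 || mean_nodes > 20)
    stop("mean degeneration must be within [0, 20]")
  n <- length(interface$alpha)
  a <- if (sd_nodes == 0) rep(round(mean_nodes), n)
       else with_seed(seed, round(rnorm(n, mean_nodes, sd_nodes)))
  interface$alpha <- as.integer(pmin(20, pmax(0, a)))
  interface
}

#' Effective (non-degenerated) node indices of a fiber
#'
#' @param interface an `eni`.
#' @param fiber fiber index.
#' @return integer vector of surviving node indices (at least 3 by
#'   construction: 31 nodes minus at most 20).
#' @export
effective_nodes <- function(interface, fiber) {
  n_nodes <- dim(interface$nodes)[1]
  (interface$alpha[fiber] + 1L):n_nodes
}
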