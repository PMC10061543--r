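## Sound coding: HiRes Fidelity 120 style current-steering coder with
## sequential (S), paired (P) and triplet (T) channel scheduling.
##
## A virtual channel k (k = 1..15) steers current between the adjacent
## electrode pair (k, k+1); electrodes are numbered 1 (most apical) to 16
## (most basal). Every pulse is a cathodic-leading biphasic pulse of 18 us
## phase duration and every channel is stimulated once per 540 us cycle
## (about 1852 pulses per second), for all three variants.

#' Convert clinical units to output current
#'
#' The device maps an integer clinical-unit (CU) amplitude to electrode
#' current as `cu / 6000 * I_max * T_max / phase_us`, with a maximum output
#' current of 2040 uA and a maximum phase duration of 229 us. The current is
#' inversely proportional to the phase duration so that charge per phase is
#' linear in CU.
#'
#' @param cu clinical units, non-negative (device range 1..471).
#' @param phase_us pulse phase duration in microseconds, positive.
#' @return current in microamperes.
#' @export
cu_to_microamps <- function(cu, phase_us) {
  if (any(phase_us <= 0)) stop("phase duration must be positive")
  if (any(cu < 0)) stop("clinical units must be non-negative")
  cu / 6000 * 2040 * 229 / phase_us
}

#' Build the pulse table for an F120 variant
#'
#' A pulse table describes one stimulation cycle: the ordered groups of
#' virtual channels that are stimulated simultaneously, and the zero-phase
#' gaps that keep the per-channel pulse rate constant at one pulse per
#' 540 us cycle for all variants.
#'
#' * `"S"`: 15 singleton groups in channel order, back to back.
#' * `"P"`: paired groups `{i, i+8}` (i = 1..7) plus the leftover `{8}`,
#'   each followed by one zero-phase gap slot.
#' * `"T"`: triplet groups `{i, i+5, i+10}` (i = 1..5), each followed by two
#'   zero-phase gap slots.
#'
#' Group onsets are spaced uniformly at `540 / n_groups` us so that the
#' 540 us per-channel period is exact; for the paired variant the implied
#' gap (31.5 us) is therefore slightly shorter than one biphasic pulse.
#'
#' @param variant one of `"S"`, `"P"`, `"T"`.
#' @param phase_us pulse phase duration (us).
#' @param channel_period_us per-channel pulse period (us).
#' @return an object of class `pulse_table`.
#' @export
build_pulse_table <- function(variant = c("S", "P", "T"), phase_us = 18,
                              channel_period_us = 540) {
  variant <- match.arg(variant)
  n_ch <- 15L
  groups <- switch(variant,
    S = lapply(seq_len(n_ch), identity),
    P = c(lapply(1:7, function(i) c(i, i + 8L)), list(8L)),
    T = lapply(1:5, function(i) c(i, i + 5L, i + 10L)))
  gap_slots <- switch(variant, S = 0L, P = 1L, T = 2L)
  onsets <- (seq_along(groups) - 1) * channel_period_us / length(groups)
  structure(list(
    variant = variant,
    slots = groups,
    gap_slots = gap_slots,
    phase_us = phase_us,
    channel_period_us = channel_period_us,
    group_onsets_us = onsets,
    n_channels = n_ch
  ), class = "pulse_table")
}

#' @export
print.pulse_table <- function(x, ...) {
  cat(sprintf("F120-%s pulse table: %d groups per %g us cycle (%.0f pps/channel)\n",
              x$variant, length(x$slots), x$channel_period_us,
              1e6 / x$channel_period_us))
  for (i in seq_along(x$slots))
    cat(sprintf("  t=%6.1f us  channels {%s}\n", x$group_onsets_us[i],
                paste(x$slots[[i]], collapse = ",")))
  invisible(x)
}

#' Construct a fitting map (T and MCL levels per virtual channel)
#'
#' @param mcl_cu integer vector of 15 most-comfortable levels in CU.
#' @param t_cu threshold levels; defaults to `round(0.1 * mcl_cu)`, the
#'   device's 10 percent rule (a 20 dB electrical dynamic range).
#' @return object of class `fitting_map`.
#' @export
fitting_map <- function(mcl_cu, t_cu = round(0.1 * mcl_cu)) {
  stopifnot(length(mcl_cu) == 15, length(t_cu) == 15)
  if (any(mcl_cu < 1 | mcl_cu > 471)) stop("MCL out of the 1..471 CU range")
  structure(list(t_cu = as.numeric(t_cu), mcl_cu = as.numeric(mcl_cu)),
            class = "fitting_map")
}

#' @export
print.fitting_map <- function(x, ...) {
  cat("fitting map (CU):\n")
  print(data.frame(channel = 1:15, T = x$t_cu, MCL = x$mcl_cu), row.names = FALSE)
  invisible(x)
}

#' Default coder configuration
#'
#' The published description of the strategy does not specify the filterbank,
#' envelope detector, steering-position selection or compression knee; these
#' are exposed here.
#'
#' @param fs_proc internal processing rate (Hz).
#' @param band_lo,band_hi analysis band edges (Hz) of the 15-band filterbank,
#'   log-spaced.
#' @param sat_dbfs envelope level mapped to MCL (dBFS); the default sits at
#'   the calibrated presentation level (65 dB SPL corresponds to -49 dBFS,
#'   the knee point of the processor's gain control), so conversational
#'   input drives the upper part of the electrical dynamic range.
#' @param idr_db input dynamic range: envelope levels in
#'   `[sat_dbfs - idr_db, sat_dbfs]` map onto `[T, MCL]`.
#' @param steer_win,steer_hop spectral-centroid steering analysis window and
#'   hop (samples at `fs_proc`).
#' @return list of coder parameters.
#' @export
coder_config <- function(fs_proc = 17400, band_lo = 350, band_hi = 5600,
                         sat_dbfs = -49, idr_db = 30,
                         steer_win = 256, steer_hop = 174) {
  list(fs_proc = fs_proc, band_lo = band_lo, band_hi = band_hi,
       sat_dbfs = sat_dbfs, idr_db = idr_db,
       steer_win = steer_win, steer_hop = steer_hop)
}

## analytic-signal envelope via FFT
hilbert_env <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

## band edges of the 15 analysis bands, log-spaced
coder_band_edges <- function(cfg) {
  exp(seq(log(cfg$band_lo), log(cfg$band_hi), length.out = 16))
}

#' Encode audio into an electrodogram
#'
#' Runs the current-steering coder: a 15-band log-spaced filterbank with
#' Hilbert envelopes, a within-band spectral-centroid locator that picks one
#' of 8 steering positions between the band's electrode pair, logarithmic
#' mapping of the envelope from T to MCL over the input dynamic range, and
#' pulse scheduling according to the variant's pulse table.
#'
#' The sparse pulse-event table is the canonical electrodogram form; use
#' [render_electrodogram()] for the dense 1 MHz current matrix.
#'
#' @param audio numeric waveform, calibrated so that 65 dB SPL corresponds
#'   to -49 dBFS (`dbfs(audio)`).
#' @param sample_rate sampling rate of `audio` (Hz).
#' @param map a [fitting_map()].
#' @param variant `"S"`, `"P"` or `"T"`.
#' @param config coder parameters, see [coder_config()].
#' @return object of class `electrodogram`: a data frame with columns
#'   `onset_us`, `channel`, `electrode_apical`, `electrode_basal`,
#'   `steering` (in \{0/8, ..., 7/8\}), `amplitude_cu`, `phase_us`, plus
#'   attributes `duration_us`, `variant`, `pulse_table`.
#' @export
encode <- function(audio, sample_rate, map, variant = c("S", "P", "T"),
                   config = coder_config()) {
  variant <- match.arg(variant)
  if (!inherits(map, "fitting_map")) stop("map must be a fitting_map")
  pt <- build_pulse_table(variant)
  if (length(audio) == 0) {
    return(empty_electrodogram(pt))
  }
  cfg <- config
  if (sample_rate != cfg$fs_proc) {
    audio <- signal::resample(audio, cfg$fs_proc, sample_rate)
  }
  fs <- cfg$fs_proc
  n <- length(audio)
  dur_us <- n / fs * 1e6
  edges <- coder_band_edges(cfg)

  ## per-band envelopes (2nd-order butterworth bandpass + analytic envelope)
  env <- matrix(0, nrow = n, ncol = 15)
  for (b in 1:15) {
    w <- c(edges[b], edges[b + 1]) / (fs / 2)
    bf <- signal::butter(2, w, type = "pass")
    xb <- signal::filtfilt(bf, audio)
    env[, b] <- hilbert_env(xb)
  }

  ## steering positions from the within-band log-frequency spectral centroid
  steer <- steering_tracks(audio, fs, edges, cfg)

  ## schedule pulses (vectorized over cycles within each table group)
  n_cycles <- floor(dur_us / pt$channel_period_us)
  if (n_cycles < 1) return(empty_electrodogram(pt))
  t_cu <- map$t_cu; mcl_cu <- map$mcl_cu
  floor_db <- cfg$sat_dbfs - cfg$idr_db
  cyc_on <- (seq_len(n_cycles) - 1) * pt$channel_period_us
  parts <- list()
  for (g in seq_along(pt$slots)) {
    onset <- cyc_on + pt$group_onsets_us[g]
    idx <- pmin(n, pmax(1L, 1L + floor(onset * 1e-6 * fs)))
    sidx <- pmin(nrow(steer), 1L + floor(onset * 1e-6 * fs / cfg$steer_hop))
    for (ch in pt$slots[[g]]) {
      e <- env[idx, ch]
      e_db <- ifelse(e > 0, 20 * log10(e), -Inf)
      frac <- pmin(1, pmax(0, (e_db - floor_db) / cfg$idr_db))
      parts[[length(parts) + 1]] <- data.frame(
        onset_us = onset, channel = ch,
        electrode_apical = ch, electrode_basal = ch + 1L,
        steering = steer[sidx, ch],
        amplitude_cu = t_cu[ch] + (mcl_cu[ch] - t_cu[ch]) * frac,
        phase_us = pt$phase_us)
    }
  }
  ev <- do.call(rbind, parts)
  ev <- ev[order(ev$onset_us, ev$channel), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, duration_us = n_cycles * pt$channel_period_us,
            variant = variant, pulse_table = pt,
            class = c("electrodogram", "data.frame"))
}

empty_electrodogram <- function(pt) {
  ev <- data.frame(onset_us = numeric(0), channel = integer(0),
                   electrode_apical = integer(0), electrode_basal = integer(0),
                   steering = numeric(0), amplitude_cu = numeric(0),
                   phase_us = numeric(0))
  structure(ev, duration_us = 0, variant = pt$variant, pulse_table = pt,
            class = c("electrodogram", "data.frame"))
}

## short-time log-frequency centroid per band, quantized to the 8 steering
## positions {0/8 .. 7/8}; rows are analysis hops, columns channels
steering_tracks <- function(audio, fs, edges, cfg) {
  win <- cfg$steer_win; hop <- cfg$steer_hop
  n <- length(audio)
  n_hops <- max(1L, ceiling(n / hop))
  st <- matrix(0.5, nrow = n_hops, ncol = 15)
  hw <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / (win + 1))
  freqs <- (0:(win / 2)) * fs / win
  for (hix in seq_len(n_hops)) {
    i0 <- (hix - 1) * hop + 1
    seg <- audio[i0:min(n, i0 + win - 1)]
    if (length(seg) < win) seg <- c(seg, numeric(win - length(seg)))
    P <- Mod(fft(seg * hw)[1:(win / 2 + 1)])^2
    for (b in 1:15) {
      sel <- which(freqs >= edges[b] & freqs < edges[b + 1])
      if (length(sel) == 0 || sum(P[sel]) <= 0) { st[hix, b] <- 0.5; next }
      cen <- sum(log2(freqs[sel]) * P[sel]) / sum(P[sel])
      frac <- (cen - log2(edges[b])) / (log2(edges[b + 1]) - log2(edges[b]))
      st[hix, b] <- floor(pmin(0.999, pmax(0, frac)) * 8) / 8
    }
  }
  st
}

#' Render an electrodogram as a dense per-electrode current matrix
#'
#' Expands the sparse pulse events into signed per-electrode current
#' waveforms (cathodic phase negative, then anodic positive, equal duration
#' and magnitude). Steering splits the channel current across its electrode
#' pair: the apical electrode carries `(1 - c)` and the basal electrode `c`
#' of the amplitude.
#'
#' @param elg an `electrodogram`.
#' @param fs render sampling rate (Hz); 1 MHz gives integer samples per
#'   18 us phase.
#' @return matrix 16 x n_samples of currents in uA.
#' @export
render_electrodogram <- function(elg, fs = 1e6) {
  dur_us <- attr(elg, "duration_us")
  n <- ceiling(dur_us * 1e-6 * fs)
  out <- matrix(0, nrow = 16, ncol = max(n, 0))
  if (nrow(elg) == 0 || n == 0) return(out)
  for (i in seq_len(nrow(elg))) {
    amp_ua <- cu_to_microamps(elg$amplitude_cu[i], elg$phase_us[i])
    c_st <- elg$steering[i]
    i_ap <- (1 - c_st) * amp_ua
    i_ba <- c_st * amp_ua
    s0 <- round(elg$onset_us[i] * 1e-6 * fs) + 1
    ph <- round(elg$phase_us[i] * 1e-6 * fs)
    cath <- s0:(s0 + ph - 1)
    anod <- (s0 + ph):(s0 + 2 * ph - 1)
    cath <- cath[cath <= n]; anod <- anod[anod <= n]
    ea <- elg$electrode_apical[i]; eb <- elg$electrode_basal[i]
    out[ea, cath] <- out[ea, cath] - i_ap
    out[eb, cath] <- out[eb, cath] - i_ba
    out[ea, anod] <- out[ea, anod] + i_ap
    out[eb, anod] <- out[eb, anod] + i_ba
  }
  out
}
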