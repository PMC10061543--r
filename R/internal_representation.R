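## Internal representation: spatial and temporal integration of the
## population spike activity into the low-rate feature matrix seen by the
## recognizer. Fibers are grouped into auditory filters by their most
## likely stimulating electrode, group spike counts are binned at 10 kHz,
## low-pass filtered with a Gaussian kernel, passed through a forward
## masking stage and downsampled to 100 Hz.

#' Group fibers into auditory filters
#'
#' Each fiber is labeled by the electrode with the highest absolute unit
#' activation; labels are majority-smoothed over a 5-fiber window, and
#' contiguous runs of one label become candidate filters. Filters whose
#' basilar-membrane extent is below `min_mm` are merged with the adjacent
#' filter toward the apex; filters above `max_mm` are split basal-first
#' into a maximal filter plus a remainder. The number of filters that can
#' result is bounded between the electrode count and 39 for the default
#' cochlea (42 mm BM with extents in [1.1, 2.6] mm).
#'
#' @param interface an `eni`.
#' @param act a [unit_activation()] table.
#' @param min_mm,max_mm extent bounds (mm).
#' @return object of class `auditory_filter_bank`: list with `groups`
#'   (list of fiber index vectors, base to apex), `extent_mm`, and
#'   `electrode` (modal electrode label per group).
#' @export
group_fibers <- function(interface, act, min_mm = 1.1, max_mm = 2.6) {
  stopifnot(inherits(interface, "eni"))
  n_fib <- length(interface$alpha)
  lab <- apply(act$peak, 1, which.max)
  ## 5-fiber majority smoothing to suppress isolated non-contiguous labels
  sm <- lab
  if (n_fib >= 5) {
    for (f in 3:(n_fib - 2)) {
      w <- lab[(f - 2):(f + 2)]
      tb <- tabulate(w, nbins = ncol(act$peak))
      sm[f] <- which.max(tb)
    }
  }
  r <- rle(sm)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1
  groups <- mapply(function(a, b) a:b, idx_start, idx_end, SIMPLIFY = FALSE)
  labels <- r$values
  arc <- interface$bm_arc_mm
  extent <- function(g) arc[max(g)] - arc[min(g)]

  merge_pass <- function(groups, labels) {
    i <- 1
    while (i <= length(groups)) {
      if (extent(groups[[i]]) < min_mm && length(groups) > 1) {
        if (i < length(groups)) {
          ## merge into the adjacent filter toward the apex
          groups[[i + 1]] <- c(groups[[i]], groups[[i + 1]])
          labels <- labels[-i]; groups[i] <- NULL
        } else {
          ## apical-most filter has no apex-side neighbour: merge backward
          groups[[i - 1]] <- c(groups[[i - 1]], groups[[i]])
          labels <- labels[-i]; groups[i] <- NULL
          i <- i - 1
        }
      } else i <- i + 1
    }
    list(groups = groups, labels = labels)
  }
  split_pass <- function(groups, labels) {
    out <- list(); out_lab <- integer(0)
    for (j in seq_along(groups)) {
      g <- sort(groups[[j]])
      while (extent(g) > max_mm) {
        ## most basal fibers form a new filter of maximal size
        cut <- which(arc[g] - arc[g[1]] <= max_mm)
        out <- c(out, list(g[cut])); out_lab <- c(out_lab, labels[j])
        g <- g[-cut]
      }
      out <- c(out, list(g)); out_lab <- c(out_lab, labels[j])
    }
    list(groups = out, labels = out_lab)
  }
  ## alternate the two passes so that split remainders below the minimum
  ## are themselves merged apically; the apical-most remainder may stay
  ## below the minimum when merging it would overrun the maximum
  for (pass in 1:3) {
    m <- merge_pass(groups, labels)
    s <- split_pass(m$groups, m$labels)
    stable <- identical(lapply(s$groups, sort), lapply(groups, sort))
    groups <- s$groups; labels <- s$labels
    if (stable) break
  }
  structure(list(groups = groups,
                 extent_mm = vapply(groups, extent, numeric(1)),
                 electrode = labels),
            class = "auditory_filter_bank")
}

#' @export
print.auditory_filter_bank <- function(x, ...) {
  cat(sprintf("auditory filter bank: %d filters, extents %.2f-%.2f mm\n",
              length(x$groups), min(x$extent_mm), max(x$extent_mm)))
  invisible(x)
}

#' Spike group activity at 10 kHz
#'
#' Bins every fiber's spike train at 100 us and sums the counts of each
#' auditory filter's member fibers. The total count is conserved.
#'
#' @param spikes a `spike_activity` covering all fibers of the bank.
#' @param bank an [group_fibers()] bank.
#' @param fs bin rate (Hz).
#' @param duration_s stimulus duration; defaults to the activity duration.
#' @return matrix `[n_groups, n_bins]` of spike counts.
#' @export
spike_group_activity <- function(spikes, bank, fs = 10000,
                                 duration_s = spikes$duration_s) {
  n_bins <- ceiling(duration_s * fs)
  n_g <- length(bank$groups)
  S <- matrix(0, n_g, n_bins)
  fiber_of <- integer(max(unlist(bank$groups)))
  for (g in seq_len(n_g)) fiber_of[bank$groups[[g]]] <- g
  pos <- match(seq_along(fiber_of), spikes$fibers)
  for (g in seq_len(n_g)) {
    tt <- unlist(spikes$times[pos[bank$groups[[g]]]], use.names = FALSE)
    if (!length(tt)) next
    b <- pmin(n_bins, pmax(1L, floor(tt * fs) + 1L))
    S[g, ] <- tabulate(b, nbins = n_bins)
  }
  S
}

## discrete Gaussian kernel in normalized time k / (fs * tau), truncated at
## four standard deviations and area-normalized
gaussian_kernel <- function(fs, tau_lp, width = 1) {
  sigma <- width * fs * tau_lp / sqrt(2)
  K <- ceiling(4 * sigma)
  k <- -K:K
  w <- exp(-(k / (width * fs * tau_lp))^2)
  w / sum(w)
}

#' Temporal low-pass filtering of the spike group activity
#'
#' Convolution with a Gaussian-shaped kernel whose width is set by the
#' product of the sample rate and the 1 ms time constant; the kernel is
#' truncated at four standard deviations and normalized to unit area, so a
#' constant input is preserved.
#'
#' @param S matrix `[n_groups, n_bins]` (see [spike_group_activity()]).
#' @param fs sample rate (Hz).
#' @param tau_lp filter time constant (s).
#' @param width kernel width factor.
#' @return filtered matrix, same shape.
#' @export
temporal_filter <- function(S, fs = 10000, tau_lp = 1e-3, width = 1) {
  kern <- gaussian_kernel(fs, tau_lp, width)
  K <- (length(kern) - 1) / 2
  n <- ncol(S)
  out <- S
  for (g in seq_len(nrow(S))) {
    x <- c(numeric(K), S[g, ], numeric(K))
    y <- stats::filter(x, kern, method = "convolution", sides = 2)
    out[g, ] <- y[(K + 1):(K + n)]
  }
  out
}

#' Forward masking
#'
#' A masker signal tracks the filtered spike group activity: it rises
#' exponentially toward the signal on onsets (attack time constant) and
#' decays exponentially on offsets (release time constant). The output is
#' the elementwise maximum of masker and signal, so activity following a
#' burst is partially masked by the decaying masker tail.
#'
#' @param F_g filtered spike group activity `[n_groups, n_bins]`.
#' @param fs sample rate (Hz).
#' @param tau_attack_s,tau_release_s masker time constants (s).
#' @return masked activity, same shape, pointwise `>= F_g`.
#' @export
forward_masking <- function(F_g, fs = 10000, tau_attack_s = 5e-3,
                            tau_release_s = 50e-3) {
  a_att <- exp(-1 / (fs * tau_attack_s))
  a_rel <- exp(-1 / (fs * tau_release_s))
  n <- ncol(F_g)
  Z <- F_g
  z <- F_g[, 1] * 0
  for (k in seq_len(n)) {
    fk <- F_g[, k]
    up <- fk >= z
    z[up] <- fk[up] + (z[up] - fk[up]) * a_att
    z[!up] <- z[!up] * a_rel
    Z[, k] <- z
  }
  pmax(Z, F_g)
}

#' Downsample the internal representation to 100 Hz
#'
#' Moving-average anti-alias filter over non-overlapping windows of
#' `factor` samples followed by decimation: each output frame is the mean
#' of its 10 ms block, so a constant input is preserved and a single-sample
#' impulse of height h becomes one frame of height h/factor.
#'
#' @param IR matrix `[n_groups, n_bins]` at the high rate.
#' @param factor decimation factor (100: 10 kHz to 100 Hz).
#' @return matrix `[n_groups, ceil(n_bins/factor)]`.
#' @export
downsample_ir <- function(IR, factor = 100) {
  n <- ncol(IR)
  n_out <- ceiling(n / factor)
  pad <- n_out * factor - n
  if (pad > 0) IR <- cbind(IR, matrix(0, nrow(IR), pad))
  out <- matrix(0, nrow(IR), n_out)
  for (j in seq_len(n_out)) {
    out[, j] <- rowMeans(IR[, ((j - 1) * factor + 1):(j * factor), drop = FALSE])
  }
  out
}

#' Full internal-representation chain
#'
#' Spike binning, Gaussian low-pass, forward masking and 100 Hz
#' downsampling in one call.
#'
#' @param spikes a `spike_activity`.
#' @param bank an auditory filter bank.
#' @param fs intermediate rate (Hz).
#' @param tau_lp low-pass time constant (s).
#' @param tau_attack_s,tau_release_s masker constants (s).
#' @param out_rate output frame rate (Hz).
#' @param duration_s stimulus duration (s).
#' @return matrix `[n_groups, n_frames]` at `out_rate`; attribute
#'   `frame_rate`.
#' @export
internal_representation <- function(spikes, bank, fs = 10000,
                                    tau_lp = 1e-3, tau_attack_s = 5e-3,
                                    tau_release_s = 50e-3, out_rate = 100,
                                    duration_s = spikes$duration_s) {
  S <- spike_group_activity(spikes, bank, fs = fs, duration_s = duration_s)
  F_g <- temporal_filter(S, fs = fs, tau_lp = tau_lp)
  M <- forward_masking(F_g, fs = fs, tau_attack_s = tau_attack_s,
                       tau_release_s = tau_release_s)
  out <- downsample_ir(M, factor = round(fs / out_rate))
  attr(out, "frame_rate") <- out_rate
  out
}
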