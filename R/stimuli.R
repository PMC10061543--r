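## Experimental stimuli: spectral ripple noise, a synthetic matrix-sentence
## corpus with matched speech-shaped noise, SNR mixing and loudness roving.
## All audio is generated at 17.4 kHz; levels follow the convention
## dBFS = 20*log10(RMS).

#' Spectral ripple noise
#'
#' Random-phase noise whose log-magnitude spectrum is sinusoidal in
#' log2-frequency: at frequency bin f in (350, 5600) Hz the magnitude is
#' `10^(C_t/2 * sin(2 pi log2(f/350) f_RPO + theta_0) / 20)` and zero
#' outside the band (hard band limits). The in-band peak-to-valley
#' contrast is therefore `C_t` dB; `C_t = 0` gives flat (reference) noise.
#'
#' @param contrast_db spectral contrast C_t (dB), >= 0.
#' @param seed RNG seed (component phases and, if `theta_0` is `NULL`, the
#'   ripple phase).
#' @param f_rpo ripples per octave.
#' @param theta_0 ripple phase (rad); `NULL` draws uniformly on [0, 2 pi).
#' @param fs sampling rate (Hz).
#' @param duration_s duration (s).
#' @param band lower and upper hard band edges (Hz).
#' @param level_dbfs output RMS level, dBFS (`NULL` = leave unscaled).
#' @return numeric waveform; attribute `theta_0`.
#' @export
ripple_noise <- function(contrast_db, seed = 1, f_rpo = 0.5, theta_0 = NULL,
                         fs = 17400, duration_s = 0.4, band = c(350, 5600),
                         level_dbfs = -49) {
  if (contrast_db < 0) stop("contrast must be non-negative")
  n <- round(fs * duration_s)
  nyq <- floor(n / 2)
  freq <- (1:nyq) * fs / n
  with_seed(seed, {
    if (is.null(theta_0)) theta_0 <- runif(1, 0, 2 * pi)
    mag <- numeric(nyq)
    inb <- freq > band[1] & freq < band[2]
    mag[inb] <- 10^(contrast_db / 2 *
                    sin(2 * pi * log2(freq[inb] / band[1]) * f_rpo + theta_0) / 20)
    ph <- runif(nyq, 0, 2 * pi)
    X <- complex(modulus = c(0, mag, numeric(n - nyq - 1)),
                 argument = c(0, ph, numeric(n - nyq - 1)))
    ## hermitian completion for a real signal
    X[(n:2)[1:(n - nyq - 1)]] <- Conj(X[2:(n - nyq)])
    x <- Re(fft(X, inverse = TRUE)) / n
  })
  if (!is.null(level_dbfs)) x <- set_level(x, level_dbfs)
  attr(x, "theta_0") <- theta_0
  x
}

#' Loudness roving
#'
#' Draws a per-stimulus presentation level uniformly from the grid
#' `mean_dbfs + seq(-peak_db, peak_db, by = resolution_db)` and rescales
#' the stimulus to that RMS level, removing absolute loudness as a cue.
#'
#' @param audio waveform.
#' @param mean_dbfs mean level (dBFS).
#' @param peak_db roving peak (dB).
#' @param resolution_db grid resolution (dB).
#' @param seed RNG seed.
#' @return rescaled waveform; attribute `level_dbfs`.
#' @export
loudness_roving <- function(audio, mean_dbfs = -49, peak_db = 5,
                            resolution_db = 0.5, seed = 1) {
  if (peak_db > 0 && abs((2 * peak_db / resolution_db) %% 1) > 1e-9)
    stop("resolution must divide the roving range")
  grid <- if (peak_db == 0) mean_dbfs
          else mean_dbfs + seq(-peak_db, peak_db, by = resolution_db)
  lev <- with_seed(seed, grid[sample.int(length(grid), 1)])
  out <- set_level(audio, lev)
  attr(out, "level_dbfs") <- lev
  out
}

#' Word inventory of the synthetic matrix test
#'
#' Five categories (name, verb, number, adjective, noun) of ten words
#' each. Every word has a deterministic synthesis recipe: fundamental
#' frequency, two formant tracks (start and end frequencies) and duration,
#' spread systematically so that all fifty tokens are spectro-temporally
#' distinct.
#'
#' @return data.frame with one row per word: `word`, `category`,
#'   `index`, `f0`, `f1_start`, `f1_end`, `f2_start`, `f2_end`,
#'   `duration_s`.
#' @export
word_inventory <- function() {
  cats <- c("name", "verb", "number", "adjective", "noun")
  rows <- list()
  for (ci in seq_along(cats)) {
    for (wi in 1:10) {
      rows[[length(rows) + 1]] <- data.frame(
        word = sprintf("%s%02d", cats[ci], wi),
        category = cats[ci], index = wi,
        f0 = 95 + 9 * ((wi * 3 + ci) %% 11),
        f0_glide = c(-0.2, 0, 0.25)[1 + (wi + ci) %% 3],
        f1_start = 280 + 55 * ((wi + 2 * ci) %% 9),
        f1_end   = 280 + 55 * ((wi * 5 + ci) %% 9),
        f2_start = 850 + 170 * ((wi * 7 + 3 * ci) %% 11),
        f2_end   = 850 + 170 * ((wi * 2 + ci) %% 11),
        tilt = c(0.55, 0.75, 0.9, 0.97)[1 + (wi * 3 + 2 * ci) %% 4],
        syllables = 1 + (wi + 2 * ci) %% 2,
        duration_s = 0.25 + 0.02 * ((wi * 5 + 2 * ci) %% 8))
    }
  }
  do.call(rbind, rows)
}

#' Balanced matrix-sentence corpus
#'
#' Builds sentences of one word per category (name, verb, number,
#' adjective, noun, in that order) by stacking independent random
#' permutations of each category's ten words: in a corpus of `10 k`
#' sentences every one of the 50 words appears exactly `k` times.
#'
#' @param n_sentences corpus size, a multiple of 10.
#' @param seed RNG seed.
#' @return data.frame `[n_sentences, 5]` of word ids, columns named by
#'   category.
#' @export
matrix_corpus <- function(n_sentences = 100, seed = 1) {
  if (n_sentences %% 10 != 0) stop("corpus size must be a multiple of 10")
  inv <- word_inventory()
  cats <- unique(inv$category)
  k <- n_sentences / 10
  with_seed(seed, {
    cols <- lapply(cats, function(cat) {
      words <- inv$word[inv$category == cat]
      unlist(lapply(seq_len(k), function(i) sample(words)))
    })
  })
  out <- as.data.frame(cols, col.names = cats, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## one synthetic word token: glottal pulse train through two time-varying
## formant resonators, with a seeded micro-variation of the pulse timing
synth_word <- function(word, seed, fs = 17400) {
  inv <- word_inventory()
  w <- inv[inv$word == word, ]
  if (nrow(w) != 1) stop("unknown word id: ", word)
  n <- round(w$duration_s * fs)
  jit <- with_seed(derive_seed(seed, word), rnorm(400, 0, 2e-4))
  ## glottal source: impulse train with a word-specific f0 glide and
  ## micro-jittered periods (the seeded micro-variation)
  times <- numeric(0); t <- 0; i <- 1
  while (t < w$duration_s) {
    f0_t <- w$f0 * (1 + w$f0_glide * t / w$duration_s)
    t <- t + 1 / f0_t + jit[i]; i <- i + 1
    if (t < w$duration_s) times <- c(times, t)
  }
  src <- numeric(n)
  src[pmax(1, round(times * fs))] <- 1
  src <- src + with_seed(derive_seed(seed, paste0(word, "asp")),
                         rnorm(n, 0, 0.01))
  ## spectral tilt: one-pole lowpass whose pole sets the roll-off
  src <- as.numeric(signal::filter(signal::Arma(b = 1 - w$tilt,
                                                a = c(1, -w$tilt)), src))
  ## two formant resonators with linear glides (start/end formant sets
  ## filtered separately and cross-faded)
  reso <- function(x, f, bw) {
    r <- exp(-pi * bw / fs)
    th <- 2 * pi * f / fs
    a <- c(1, -2 * r * cos(th), r^2)
    as.numeric(signal::filter(signal::Arma(b = (1 - r), a = a), x))
  }
  half <- function(f1, f2) reso(reso(src, f1, 70), f2, 110)
  y1 <- half(w$f1_start, w$f2_start)
  y2 <- half(w$f1_end, w$f2_end)
  fade <- seq(0, 1, length.out = n)
  y <- (1 - fade) * y1 + fade * y2
  ## syllable envelope: one or two raised-cosine energy bumps
  k <- w$syllables
  env <- 0.15 + 0.85 * abs(sin(pi * k * seq(0, 1, length.out = n)))^0.7
  ramp <- pmin(1, seq_len(n) / (0.01 * fs), rev(seq_len(n)) / (0.01 * fs))
  y <- y * env * ramp
  y / sqrt(mean(y^2))
}

#' Synthesize a matrix sentence
#'
#' Renders each word as a distinct formant token and concatenates the five
#' words with 50 ms silent gaps. The same sentence and seed give
#' bit-identical audio; the seed only drives sub-millisecond micro-jitter
#' of the glottal source.
#'
#' @param sentence character vector of 5 word ids (category order).
#' @param seed RNG seed.
#' @param fs sampling rate (Hz).
#' @param gap_s inter-word gap (s).
#' @return waveform with attribute `boundaries_s`, a `[5, 2]` matrix of
#'   word start/end times (end includes the trailing gap, which belongs to
#'   the word for segmentation purposes).
#' @export
synth_speech <- function(sentence, seed = 1, fs = 17400, gap_s = 0.05) {
  stopifnot(length(sentence) == 5)
  toks <- lapply(sentence, synth_word, seed = seed, fs = fs)
  gap <- numeric(round(gap_s * fs))
  pieces <- list(); bounds <- matrix(0, 5, 2)
  t0 <- 0
  for (i in 1:5) {
    x <- toks[[i]]
    piece <- if (i < 5) c(x, gap) else x
    pieces[[i]] <- piece
    bounds[i, ] <- c(t0, t0 + length(piece) / fs)
    t0 <- t0 + length(piece) / fs
  }
  out <- unlist(pieces)
  attr(out, "boundaries_s") <- bounds
  out
}

#' Speech-shaped masking noise
#'
#' Gaussian noise spectrally shaped to the long-term average spectrum of
#' the 50-word synthetic inventory (the matrix test's noise is designed to
#' match its speech material). The shaping filter is a 512-tap
#' frequency-sampling FIR built from the Welch spectrum of all tokens.
#'
#' @param duration_s duration (s).
#' @param seed RNG seed.
#' @param fs sampling rate (Hz).
#' @return waveform (unit RMS).
#' @export
speech_shaped_noise <- function(duration_s, seed = 1, fs = 17400) {
  ir <- ltas_filter_ir(fs)
  n <- round(duration_s * fs)
  x <- with_seed(seed, rnorm(n + length(ir)))
  y <- stats::filter(x, ir, method = "convolution", sides = 1)
  y <- y[!is.na(y)][seq_len(n)]
  y / sqrt(mean(y^2))
}

## long-term-average-spectrum FIR (cached per session)
ltas_cache <- new.env(parent = emptyenv())
ltas_filter_ir <- function(fs, ntap = 1024) {
  key <- paste0("fs", fs)
  if (!is.null(ltas_cache[[key]])) return(ltas_cache[[key]])
  inv <- word_inventory()
  all <- unlist(lapply(inv$word, synth_word, seed = 1, fs = fs))
  ps <- welch_psd(all, fs, nfft = 1024)
  f_grid <- (0:(ntap / 2)) * fs / ntap
  mag <- sqrt(approx(ps$freq, ps$psd, xout = f_grid, rule = 2)$y)
  mag <- mag / max(mag)
  H <- c(mag, rev(mag[2:(ntap / 2)]))
  ir <- Re(fft(H, inverse = TRUE)) / ntap
  ir <- c(ir[(ntap / 2 + 1):ntap], ir[1:(ntap / 2)])
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(ntap) / (ntap + 1))
  ir <- ir * w
  ltas_cache[[key]] <- ir
  ir
}

## Welch power spectral density (Hann window, 50% overlap)
welch_psd <- function(x, fs, nfft = 1024) {
  hop <- nfft / 2
  n_seg <- max(1, floor((length(x) - nfft) / hop) + 1)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / (nfft + 1))
  acc <- numeric(nfft / 2 + 1)
  for (s in seq_len(n_seg)) {
    seg <- x[((s - 1) * hop + 1):((s - 1) * hop + nfft)]
    X <- fft(seg * w)
    acc <- acc + Mod(X[1:(nfft / 2 + 1)])^2
  }
  list(freq = (0:(nfft / 2)) * fs / nfft,
       psd = acc / (n_seg * sum(w^2) * fs))
}

#' Mix speech and noise at a target SNR
#'
#' The speech is fixed at `speech_dbfs`; a random excerpt of the noise is
#' scaled so that `20*log10(RMS_speech / RMS_noise)` equals `snr_db`, and
#' the two are summed. `snr_db = Inf` returns the level-set clean speech
#' (the no-noise training condition).
#'
#' @param speech speech waveform.
#' @param noise noise waveform, at least as long as the speech.
#' @param snr_db signal-to-noise ratio (dB), may be `Inf`.
#' @param speech_dbfs presentation level of the speech (dBFS).
#' @param seed RNG seed for the excerpt position.
#' @return mixed waveform, same length as `speech`.
#' @export
mix_at_snr <- function(speech, noise, snr_db, speech_dbfs = -49, seed = 1) {
  sp <- set_level(as.numeric(speech), speech_dbfs)
  if (is.infinite(snr_db) && snr_db > 0) return(sp)
  if (length(noise) < length(speech)) stop("noise shorter than speech")
  start <- with_seed(seed,
    sample.int(length(noise) - length(speech) + 1, 1))
  ex <- noise[start:(start + length(speech) - 1)]
  ex <- set_level(ex, speech_dbfs - snr_db)
  sp + ex
}
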