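test_that("ripple noise realizes the designed sinusoidal log-frequency spectrum", {
  fs <- 17400
  x <- ripple_noise(0, seed = 1, level_dbfs = NULL)
  n <- length(x)
  expect_equal(n, round(fs * 0.4))
  X <- Mod(fft(x))[1:(n %/% 2)]
  freq <- (0:(n %/% 2 - 1)) * fs / n
  inb <- freq > 350 & freq < 5600
  # flat reference: all in-band magnitudes equal, zero outside
  expect_lt(diff(range(X[inb][-1])), 1e-6 * max(X))
  expect_lt(max(X[freq > 5700]), 1e-8 * max(X))
  expect_lt(max(X[freq < 340 & freq > 0]), 1e-8 * max(X))

  x10 <- ripple_noise(10, seed = 2, theta_0 = 0, level_dbfs = NULL)
  X10 <- Mod(fft(x10))[1:(n %/% 2)]
  p2v <- 20 * log10(max(X10[inb]) / min(X10[inb & freq > 360 & freq < 5500]))
  expect_equal(p2v, 10, tolerance = 0.1)
  # realized magnitudes follow the sinusoid in log2 frequency bin by bin
  sel <- inb & freq > 360 & freq < 5500
  expected_db <- 10 / 2 * sin(2 * pi * log2(freq[sel] / 350) * 0.5)
  got_db <- 20 * log10(X10[sel] / X10[sel][1]) + expected_db[1]
  expect_equal(got_db, expected_db, tolerance = 1e-6)
  # 0.5 ripples/octave over the 4-octave band: two full periods of phase
  expect_equal(log2(5600 / 350) * 0.5, 2)
})

test_that("welch-estimated in-band contrast of rendered ripple noise is close to C_t", {
  x <- ripple_noise(10, seed = 5, theta_0 = 0, level_dbfs = -49)
  ps <- cisim:::welch_psd(as.numeric(x), 17400, nfft = 2048)
  inb <- ps$freq > 500 & ps$freq < 4000
  env_db <- 10 * log10(ps$psd[inb])
  expect_equal(max(env_db) - min(env_db), 10, tolerance = 1.5)
})

test_that("loudness roving draws from the stated grid and hits its level", {
  x <- ripple_noise(0, seed = 1, level_dbfs = -49)
  r0 <- loudness_roving(x, peak_db = 0, seed = 1)
  expect_equal(dbfs(r0), -49, tolerance = 1e-9)
  levs <- sapply(1:100, function(s) {
    y <- loudness_roving(x, seed = s)
    lev <- attr(y, "level_dbfs")
    expect_lt(abs(dbfs(y) - lev), 0.01)
    lev
  })
  grid <- seq(-54, -44, by = 0.5)
  expect_true(all(levs %in% grid))
  expect_length(grid, 21)
  expect_lt(abs(mean(levs) + 49), 0.6)
  expect_error(loudness_roving(x, peak_db = 5, resolution_db = 0.7), "divide")
})

test_that("matrix corpus is balanced: every word appears n/10 times", {
  co <- matrix_corpus(100, seed = 3)
  expect_equal(dim(co), c(100, 5))
  counts <- table(unlist(co))
  expect_length(counts, 50)
  expect_true(all(counts == 10))
  expect_equal(sum(counts), 500)
  co10 <- matrix_corpus(10, seed = 4)
  expect_true(all(table(unlist(co10)) == 1))
  expect_error(matrix_corpus(55), "multiple")
})

test_that("speech synthesis is deterministic and words are mutually distinct", {
  co <- matrix_corpus(10, seed = 1)
  s <- unlist(co[1, ])
  a <- synth_speech(s, seed = 7)
  b <- synth_speech(s, seed = 7)
  expect_identical(as.numeric(a), as.numeric(b))
  c2 <- synth_speech(s, seed = 8)
  expect_false(identical(as.numeric(a), as.numeric(c2)))

  inv <- word_inventory()
  durs <- inv$duration_s[match(s, inv$word)]
  expect_equal(length(a) / 17400, sum(durs) + 4 * 0.05, tolerance = 1e-3)
  expect_error(cisim:::synth_word("nosuchword", 1), "unknown")

  # linear-magnitude spectrograms of distinct words decorrelate
  spg <- function(w) {
    x <- cisim:::synth_word(w, seed = 1)
    win <- 256; hop <- 128
    hw <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / (win + 1))
    nf <- floor((length(x) - win) / hop)
    sapply(seq_len(nf), function(i)
      Mod(fft(x[((i - 1) * hop + 1):((i - 1) * hop + win)] * hw))[1:128])
  }
  # within-category pairs are what the recognizer must tell apart
  words <- inv$word[inv$category %in% c("name", "noun")]
  pairs <- with_seed(5, cbind(sample(words, 20, TRUE), sample(words, 20, TRUE)))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  for (i in seq_len(nrow(pairs))) {
    a <- spg(pairs[i, 1]); b <- spg(pairs[i, 2])
    k <- min(ncol(a), ncol(b))
    expect_lt(cor(as.vector(a[, 1:k]), as.vector(b[, 1:k])), 0.9)
  }
})

test_that("SNR mixing fixes the speech level and realizes the requested ratio", {
  sp <- ripple_noise(0, seed = 1, level_dbfs = NULL)  # any signal stands in
  noi <- speech_shaped_noise(2, seed = 2)
  mx0 <- mix_at_snr(sp, noi, 0, seed = 3)
  # reconstruct components to measure the realized SNR
  spl <- set_level(as.numeric(sp), -49)
  ex <- mx0 - spl
  expect_equal(dbfs(spl) - dbfs(ex), 0, tolerance = 0.01)
  mx6 <- mix_at_snr(sp, noi, 6, seed = 3)
  ex6 <- mx6 - spl
  expect_equal(dbfs(spl) - dbfs(ex6), 6, tolerance = 0.01)
  # no-noise condition returns clean speech at level
  clean <- mix_at_snr(sp, noi, Inf)
  expect_equal(as.numeric(clean), spl, tolerance = 1e-12)
  expect_equal(dbfs(clean), -49, tolerance = 1e-6)
  expect_error(mix_at_snr(sp, noi[1:100], 0), "shorter")
})

test_that("generated stimuli never clip at the roved presentation levels", {
  worst <- -49 + 5
  for (s in 1:5) {
    x <- set_level(ripple_noise(20, seed = s, level_dbfs = NULL), worst)
    expect_lt(max(abs(x)), 1)
  }
  co <- matrix_corpus(10, seed = 2)
  au <- set_level(synth_speech(unlist(co[2, ]), seed = 3), worst)
  expect_lt(max(abs(au)), 1)
})

test_that("masking noise matches the corpus long-term spectrum per third-octave band", {
  fs <- 17400
  noi <- speech_shaped_noise(8, seed = 6, fs = fs)
  inv <- word_inventory()
  sp <- unlist(lapply(inv$word, cisim:::synth_word, seed = 1, fs = fs))
  pn <- cisim:::welch_psd(noi, fs, nfft = 2048)
  ps <- cisim:::welch_psd(sp, fs, nfft = 2048)
  edges <- 350 * 2^(seq(0, 4, by = 1 / 3))
  del <- sapply(seq_len(length(edges) - 1), function(i) {
    sel <- pn$freq >= edges[i] & pn$freq < edges[i + 1]
    10 * log10(sum(pn$psd[sel]) / sum(ps$psd[sel]))
  })
  del <- del - mean(del)   # overall gain is arbitrary
  expect_true(all(abs(del) <= 3))
})
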