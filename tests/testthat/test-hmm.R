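rnd_feat <- function(n, frames = 30, dims = 4, mean = 0, seed = 1) {
  with_seed(seed, lapply(seq_len(n), function(i)
    matrix(rnorm(frames * dims, mean), frames, dims)))
}

test_that("training log-likelihood is non-decreasing across iterations", {
  feats <- rnd_feat(6, mean = 1, seed = 2)
  m <- hmm_train(feats, n_states = 4)
  tr <- m$loglik_trace
  expect_gte(length(tr), 1)
  if (length(tr) > 1) {
    expect_true(all(diff(tr) >= -1e-6 * abs(tr[-length(tr)])))
  }
})

test_that("separable classes are learned to perfect training accuracy", {
  a <- rnd_feat(5, mean = 0, seed = 3)
  b <- rnd_feat(5, mean = 5, seed = 4)
  models <- train_models(c(a, b), rep(c("ref", "tgt"), each = 5),
                         n_states = 3)
  for (f in a) expect_equal(recognize_binary(f, models)$label, "ref")
  for (f in b) expect_equal(recognize_binary(f, models)$label, "tgt")
})

test_that("a single-state model recovers the sample moments", {
  feats <- rnd_feat(3, frames = 200, dims = 2, mean = 1.5, seed = 5)
  m <- hmm_train(feats, n_states = 1, var_floor_frac = 1e-12)
  pooled <- do.call(rbind, feats)
  expect_equal(m$means[1, ], colMeans(pooled), tolerance = 1e-9)
  mle_var <- apply(pooled, 2, function(z) mean((z - mean(z))^2))
  expect_equal(m$vars[1, ], mle_var, tolerance = 1e-9)
})

test_that("training requires at least two examples per label", {
  f <- rnd_feat(3, seed = 6)
  expect_error(train_models(f, c("a", "a", "b")), "fewer than 2")
  expect_error(hmm_train(f[1]), "at least 2")
})

test_that("viterbi equals exhaustive path enumeration on a 3-frame toy", {
  with_seed(8, {
    S <- 3
    logB <- matrix(rnorm(3 * S), 3, S)
    A <- matrix(runif(S * S), S, S); A <- A / rowSums(A)
    logA <- log(A)
    logpi <- log(rep(1 / S, S))
  })
  v <- hmm_viterbi(logpi, logA, logB)
  paths <- as.matrix(expand.grid(1:S, 1:S, 1:S))
  brute <- apply(paths, 1, function(p)
    logpi[p[1]] + logB[1, p[1]] + logA[p[1], p[2]] + logB[2, p[2]] +
      logA[p[2], p[3]] + logB[3, p[3]])
  expect_equal(v$loglik, max(brute), tolerance = 1e-12)
  expect_equal(v$path, unname(paths[which.max(brute), ]))
})

test_that("feature dimension mismatches are rejected", {
  m <- hmm_train(rnd_feat(2, dims = 4, seed = 9), n_states = 2)
  expect_error(hmm_loglik(m, matrix(0, 10, 3)), "dimension")
})

test_that("sentence decoding emits exactly one word per slot", {
  inv <- word_inventory()
  slots <- split(inv$word, inv$category)[unique(inv$category)]
  frames_per_word <- 12
  mk_word_feats <- function(w, n) {
    wi <- match(w, inv$word)
    with_seed(1000 + wi, lapply(seq_len(n), function(i)
      matrix(rnorm(frames_per_word * 3, mean = (wi %% 7)), frames_per_word, 3)))
  }
  feats <- list(); labs <- character(0)
  for (w in inv$word) {
    fw <- mk_word_feats(w, 2)
    feats <- c(feats, fw); labs <- c(labs, rep(w, 2))
  }
  models <- train_models(feats, labs, n_states = 2)
  sent <- vapply(slots, `[`, "", 3)
  feat <- do.call(rbind, lapply(sent, function(w) mk_word_feats(w, 1)[[1]]))
  dec <- recognize_sentence(feat, models, slots)
  expect_length(dec$words, 5)
  for (i in 1:5) expect_true(dec$words[i] %in% slots[[i]])
})

test_that("shuffled labels drive accuracy to the chance floors", {
  # binary task: 50% chance
  with_seed(11, {
    feats <- rnd_feat(40, frames = 20, dims = 3, seed = 12)
    labs <- sample(rep(c("ref", "tgt"), 20))
  })
  models <- train_models(feats[1:30], labs[1:30], n_states = 2)
  test_feats <- rnd_feat(60, frames = 20, dims = 3, seed = 13)
  truth <- with_seed(14, sample(c("ref", "tgt"), 60, replace = TRUE))
  acc <- mean(vapply(seq_along(test_feats), function(i)
    recognize_binary(test_feats[[i]], models)$label == truth[i], logical(1)))
  ci <- qbinom(c(0.005, 0.995), 60, 0.5) / 60
  expect_gte(acc, ci[1]); expect_lte(acc, ci[2])

  # ten-alternative word task: 10% chance
  inv <- word_inventory()
  slots <- split(inv$word, inv$category)[unique(inv$category)]
  feats <- list(); labs <- character(0)
  for (w in inv$word) {
    feats <- c(feats, rnd_feat(2, frames = 10, dims = 3,
                               seed = match(w, inv$word)))
    labs <- c(labs, rep(w, 2))
  }
  models <- train_models(feats, labs, n_states = 2)
  n_sent <- 30
  correct <- 0
  for (k in seq_len(n_sent)) {
    truth_w <- vapply(slots, function(s) with_seed(500 + k, sample(s, 1)), "")
    feat <- do.call(rbind, rnd_feat(5, frames = 10, dims = 3, seed = 900 + k))
    dec <- recognize_sentence(feat, models, slots)
    correct <- correct + sum(dec$words == truth_w)
  }
  acc <- correct / (5 * n_sent)
  ci <- qbinom(c(0.005, 0.995), 5 * n_sent, 0.1) / (5 * n_sent)
  expect_gte(acc, ci[1]); expect_lte(acc, ci[2])
})
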