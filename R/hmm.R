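## Whole-stimulus hidden Markov models with single-Gaussian emissions:
## 8 emitting states, strict left-to-right topology with self-loops,
## diagonal covariances with a global variance floor. Training is
## segmental k-means (uniform segmentation init, Viterbi re-alignment,
## maximum-likelihood re-estimation) whose joint path likelihood is
## non-decreasing across iterations. Decoding is Viterbi, either over a
## binary whole-stimulus choice or over a 5-slot x 10-word sentence chain.

#' Train one whole-stimulus HMM
#'
#' @param features list of feature matrices (`frames x dims`), at least 2.
#' @param n_states number of emitting states.
#' @param max_iter maximum segmental k-means iterations.
#' @param tol relative log-likelihood improvement at which to stop.
#' @param var_floor_frac variance floor as a fraction of the pooled
#'   per-dimension variance.
#' @param label optional label stored in the model.
#' @return object of class `stimulus_hmm`: `means`, `vars`
#'   (`n_states x dims`), `log_trans`, `label`, `loglik_trace`.
#' @export
hmm_train <- function(features, n_states = 8, max_iter = 25, tol = 1e-5,
                      var_floor_frac = 1e-4, label = NULL) {
  if (!is.list(features) || length(features) < 2)
    stop("training error: need at least 2 examples per label")
  features <- lapply(features, as.matrix)
  dims <- ncol(features[[1]])
  if (any(vapply(features, ncol, 1L) != dims))
    stop("inconsistent feature dimensions")
  if (any(vapply(features, nrow, 1L) < n_states))
    stop("an example is shorter than the number of states")
  pooled <- do.call(rbind, features)
  floorv <- pmax(apply(pooled, 2, stats::var) * var_floor_frac, 1e-12)

  ## initial uniform segmentation
  aligns <- lapply(features, function(f) {
    n <- nrow(f)
    sort(rep(seq_len(n_states), length.out = n,
             each = ceiling(n / n_states))[seq_len(n)])
  })
  model <- NULL
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    model <- hmm_estimate(features, aligns, n_states, floorv)
    ll <- 0
    new_aligns <- vector("list", length(features))
    for (i in seq_along(features)) {
      v <- hmm_viterbi_model(model, features[[i]])
      ll <- ll + v$loglik
      new_aligns[[i]] <- v$path
    }
    trace <- c(trace, ll)
    if (it > 1 && ll - trace[it - 1] <= tol * abs(trace[it - 1])) {
      aligns <- new_aligns
      break
    }
    aligns <- new_aligns
  }
  model$label <- label
  model$loglik_trace <- trace
  model
}

## maximum-likelihood re-estimation given state alignments
hmm_estimate <- function(features, aligns, n_states, floorv) {
  dims <- ncol(features[[1]])
  means <- matrix(0, n_states, dims)
  vars <- matrix(0, n_states, dims)
  n_self <- numeric(n_states); n_adv <- numeric(n_states)
  for (s in seq_len(n_states)) {
    rows <- do.call(rbind, mapply(function(f, a) f[a == s, , drop = FALSE],
                                  features, aligns, SIMPLIFY = FALSE))
    if (nrow(rows) == 0) rows <- matrix(0, 1, dims)
    means[s, ] <- colMeans(rows)
    vars[s, ] <- pmax(apply(rows, 2, function(z)
      mean((z - mean(z))^2)), floorv)
  }
  for (a in aligns) {
    tr <- table(factor(a[-length(a)], levels = seq_len(n_states)),
                factor(a[-1], levels = seq_len(n_states)))
    n_self <- n_self + diag(tr)
    if (n_states > 1)
      n_adv <- n_adv + c(tr[cbind(seq_len(n_states - 1), 2:n_states)], 0)
  }
  a_self <- (n_self + 1) / (n_self + n_adv + 2)
  log_trans <- matrix(-Inf, n_states, n_states)
  for (s in seq_len(n_states - 1)) {
    log_trans[s, s] <- log(a_self[s])
    log_trans[s, s + 1] <- log(1 - a_self[s])
  }
  log_trans[n_states, n_states] <- log(a_self[n_states])
  structure(list(means = means, vars = vars, log_trans = log_trans,
                 n_states = n_states,
                 exit_logp = log(1 - a_self[n_states])),
            class = "stimulus_hmm")
}

#' @export
print.stimulus_hmm <- function(x, ...) {
  cat(sprintf("whole-stimulus HMM '%s': %d states, %d feature dims\n",
              if (is.null(x$label)) "?" else x$label,
              x$n_states, ncol(x$means)))
  invisible(x)
}

## log emission densities: frames x states
hmm_logb <- function(model, feat) {
  n <- nrow(feat); S <- model$n_states
  out <- matrix(0, n, S)
  for (s in seq_len(S)) {
    mu <- model$means[s, ]; v <- model$vars[s, ]
    out[, s] <- -0.5 * colSums((t(feat) - mu)^2 / v) -
      0.5 * sum(log(2 * pi * v))
  }
  out
}

#' Viterbi decoding against a generic model
#'
#' Maximum-probability state path given log initial probabilities, log
#' transition matrix and per-frame log emission densities. Ties are broken
#' toward the lowest state index.
#'
#' @param log_pi length-S log initial distribution.
#' @param log_trans S x S log transition matrix (rows: from).
#' @param log_b frames x S log emission matrix.
#' @param final_states states in which the path may end (default all).
#' @return list with `loglik` and `path` (integer states).
#' @export
hmm_viterbi <- function(log_pi, log_trans, log_b,
                        final_states = seq_len(ncol(log_b))) {
  n <- nrow(log_b); S <- ncol(log_b)
  delta <- log_pi + log_b[1, ]
  psi <- matrix(0L, n, S)
  if (n > 1) for (k in 2:n) {
    cand <- delta + log_trans          # S x S: from (row) to (col)
    best_from <- max.col(t(cand), ties.method = "first")
    delta <- cand[cbind(best_from, seq_len(S))] + log_b[k, ]
    psi[k, ] <- best_from
  }
  fin <- rep(-Inf, S); fin[final_states] <- 0
  end <- which.max(delta + fin)
  path <- integer(n); path[n] <- end
  for (k in n:2) path[k - 1] <- psi[k, path[k]]
  list(loglik = (delta + fin)[end], path = path)
}

## Viterbi against one left-to-right model (start in state 1, end in the
## last state, as fits a whole-stimulus model)
hmm_viterbi_model <- function(model, feat) {
  S <- model$n_states
  log_pi <- c(0, rep(-Inf, S - 1))
  hmm_viterbi(log_pi, model$log_trans, hmm_logb(model, as.matrix(feat)),
              final_states = S)
}

#' Log-likelihood of a feature matrix under a whole-stimulus model
#'
#' @param model a `stimulus_hmm`.
#' @param feat feature matrix (`frames x dims`).
#' @return Viterbi path log-likelihood.
#' @export
hmm_loglik <- function(model, feat) {
  if (ncol(as.matrix(feat)) != ncol(model$means))
    stop("feature dimension mismatch")
  hmm_viterbi_model(model, feat)$loglik
}

#' Train one model per label
#'
#' @param features list of feature matrices.
#' @param labels character vector of labels, one per feature matrix.
#' @param ... passed to [hmm_train()].
#' @return named list of `stimulus_hmm` models.
#' @export
train_models <- function(features, labels, ...) {
  stopifnot(length(features) == length(labels))
  out <- list()
  for (lb in unique(labels)) {
    sel <- which(labels == lb)
    if (length(sel) < 2)
      stop("training error: label '", lb, "' has fewer than 2 examples")
    out[[lb]] <- hmm_train(features[sel], label = lb, ...)
  }
  out
}

#' Binary whole-stimulus classification
#'
#' @param feat feature matrix.
#' @param models named list of (two) `stimulus_hmm` models.
#' @return list with `label` (name of the best model) and `loglik`
#'   (named vector).
#' @export
recognize_binary <- function(feat, models) {
  ll <- vapply(models, hmm_loglik, numeric(1), feat = feat)
  list(label = names(models)[which.max(ll)], loglik = ll)
}

#' Sentence recognition over the matrix-test grammar
#'
#' Viterbi decoding over the composite chain: 5 slots in category order,
#' 10 candidate word models per slot (uniform 1/10 within a slot), entered
#' through each word's first state and left through its last. Exactly one
#' word per slot is emitted.
#'
#' @param feat feature matrix of the whole sentence.
#' @param models named list of `stimulus_hmm` word models.
#' @param slots list of 5 character vectors: candidate word ids per slot.
#' @return list with `words` (length 5) and `loglik`.
#' @export
recognize_sentence <- function(feat, models, slots) {
  feat <- as.matrix(feat)
  stopifnot(length(slots) == 5)
  words <- unlist(lapply(seq_along(slots), function(i) slots[[i]]))
  slot_of <- rep(seq_along(slots), vapply(slots, length, 1L))
  S_each <- vapply(words, function(w) as.integer(models[[w]]$n_states),
                   integer(1))
  offs <- cumsum(c(0, S_each[-length(S_each)]))
  S_tot <- sum(S_each)
  n <- nrow(feat)
  logB <- matrix(-Inf, n, S_tot)
  for (j in seq_along(words)) {
    logB[, (offs[j] + 1):(offs[j] + S_each[j])] <-
      hmm_logb(models[[words[j]]], feat)
  }
  logA <- matrix(-Inf, S_tot, S_tot)
  for (j in seq_along(words)) {
    m <- models[[words[j]]]
    rng <- (offs[j] + 1):(offs[j] + S_each[j])
    logA[rng, rng] <- m$log_trans
    if (slot_of[j] < length(slots)) {
      nxt <- which(slot_of == slot_of[j] + 1)
      for (j2 in nxt) {
        logA[rng[length(rng)], offs[j2] + 1] <-
          m$exit_logp - log(length(nxt))
      }
    }
  }
  log_pi <- rep(-Inf, S_tot)
  first <- which(slot_of == 1)
  for (j in first) log_pi[offs[j] + 1] <- -log(length(first))
  finals <- offs[slot_of == length(slots)] + S_each[slot_of == length(slots)]
  v <- hmm_viterbi(log_pi, logA, logB, final_states = finals)
  ## read the word sequence off the decoded state path
  widx <- findInterval(v$path - 1, offs)
  seq_w <- rle(widx)$values
  decoded <- character(length(slots))
  for (i in seq_along(slots)) {
    in_slot <- seq_w[slot_of[seq_w] == i]
    decoded[i] <- words[in_slot[1]]
  }
  list(words = decoded, loglik = v$loglik)
}
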