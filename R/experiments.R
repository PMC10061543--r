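## End-to-end orchestration of the spectral-modulation-threshold (SMT) and
## speech-reception-threshold (SRT) experiments over the 3 x 3 grid of
## coding variant (S, P, T) and neural health (healthy, moderate, severe).
##
## Two built-in profiles: "paper" reproduces the full-scale study
## conditions (9001 fibers, full corpora - cluster-scale, hours of CPU),
## "desk" decimates the fiber population and corpora so a full experiment
## runs in minutes on one CPU; "micro" is a further-reduced profile used
## for smoke tests. The decimation preserves the structure of the
## experiments (grammar, balance, SNR/contrast grids, criteria) exactly.

#' Simulation profile
#'
#' @param name `"paper"`, `"desk"` or `"micro"`.
#' @return list of scale parameters: fiber count, integration steps,
#'   corpus sizes, condition grids, fitting seeds.
#' @export
sim_profile <- function(name = c("desk", "paper", "micro")) {
  name <- match.arg(name)
  base <- list(
    name = name,
    smt_contrasts = c(2, 3, 4, 5, 7, 9, 11, 14, 17, 20),
    smt_train_contrasts = 2:20,
    srt_train_snrs = c(seq(0, 18, by = 3), Inf),
    srt_test_snrs = seq(-9, 18, by = 3),
    rove_mean_dbfs = -49, rove_peak_db = 5, rove_res_db = 0.5,
    srt_test_sentences = NULL)
  scale <- switch(name,
    paper = list(n_fibers = 9001, dt_pulse_us = 2, dt_gap_us = 20,
                 fit_seeds = 3, smt_train_per_class = 1000,
                 smt_test_per_class = 50, srt_sentences = 100),
    desk  = list(n_fibers = 301, dt_pulse_us = 18, dt_gap_us = 60,
                 fit_seeds = 2, smt_train_per_class = 30,
                 smt_test_per_class = 5, srt_sentences = 10,
                 srt_train_snrs = c(0, 6, 12, 18, Inf)),
    micro = list(n_fibers = 101, dt_pulse_us = 18, dt_gap_us = 90,
                 fit_seeds = 1, smt_train_per_class = 10,
                 smt_test_per_class = 2, srt_sentences = 10,
                 srt_train_snrs = c(0, 9, Inf),
                 srt_test_snrs = c(-9, -3, 3, 9, 15),
                 srt_test_sentences = 5))
  utils::modifyList(base, scale)
}

#' Load a simulation profile from a YAML configuration file
#'
#' The file holds overrides of [sim_profile()] fields, plus an optional
#' `base` field naming the profile to start from (default `"desk"`), e.g.
#'
#' ```yaml
#' base: desk
#' n_fibers: 501
#' srt_sentences: 20
#' ```
#'
#' @param path YAML file path.
#' @return a profile list.
#' @export
load_profile <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read configuration files")
  cfg <- yaml::read_yaml(path)
  base <- sim_profile(if (is.null(cfg$base)) "desk" else cfg$base)
  cfg$base <- NULL
  utils::modifyList(base, cfg)
}

## per-session cache of fitted models (geometry + activation + bank + map)
model_cache <- new.env(parent = emptyenv())

#' Set up the peripheral model for one experiment cell
#'
#' Builds (or retrieves from the session cache) the geometry, applies the
#' health preset, computes the activation table, the auditory filter bank
#' and the fitting map.
#'
#' @param health health preset name (see [health_presets()]) or a numeric
#'   mean degeneration.
#' @param profile a [sim_profile()].
#' @param seed master seed (drives degeneration and fitting noise).
#' @param params neuron parameters.
#' @param use_cache reuse a previously built identical cell.
#' @return list with `interface`, `act`, `bank`, `map`, `params`,
#'   `profile`.
#' @export
setup_model <- function(health, profile = sim_profile("desk"), seed = 1,
                        params = neuron_params(), use_cache = TRUE) {
  mean_deg <- if (is.character(health)) health_presets()[[health]]
              else as.numeric(health)
  key <- paste(profile$name, profile$n_fibers, mean_deg, seed, sep = "|")
  if (use_cache && !is.null(model_cache[[key]])) return(model_cache[[key]])
  g <- build_geometry(geometry_config(n_fibers = profile$n_fibers))
  g <- apply_degeneration(g, mean_deg, 3, seed = derive_seed(seed, "degeneration"))
  act <- unit_activation(g)
  bank <- group_fibers(g, act)
  map <- fit_map(g, act, params = params, n_seeds = profile$fit_seeds,
                 seed = derive_seed(seed, "fitting"),
                 dt_pulse_us = profile$dt_pulse_us,
                 dt_gap_us = profile$dt_gap_us)
  out <- list(interface = g, act = act, bank = bank, map = map,
              params = params, profile = profile, health = mean_deg)
  if (use_cache) model_cache[[key]] <- out
  out
}

#' Run the front end on one stimulus
#'
#' Audio to internal-representation features: sound coding, induced
#' currents, spike simulation, internal representation.
#'
#' @param audio waveform (already at presentation level).
#' @param fs sampling rate of `audio` (Hz).
#' @param model a [setup_model()] result.
#' @param variant coding variant.
#' @param seed stimulus-level noise seed.
#' @return feature matrix `frames x n_filters` (100 Hz).
#' @export
front_end <- function(audio, fs, model, variant, seed = 1) {
  elg <- encode(audio, fs, model$map, variant)
  ic <- induced_current(elg, model$interface, act = model$act)
  sp <- simulate_spikes(ic, model$params, seed = seed,
                        dt_pulse_us = model$profile$dt_pulse_us,
                        dt_gap_us = model$profile$dt_gap_us)
  t(internal_representation(sp, model$bank))
}

#' Run one spectral modulation threshold experiment
#'
#' Training corpus: `smt_train_per_class` ripples at random integer
#' contrasts 2..20 dB plus as many flat references; test corpus:
#' `smt_test_per_class` ripples and references at each contrast of the
#' test grid. All stimuli are 0.4 s at 17.4 kHz with loudness roving
#' (mean -49 dBFS, peak 5 dB, 0.5 dB steps). Scores per contrast are
#' fitted with a psychometric function (chance 50%) and the SMT is read at
#' 79.4% correct.
#'
#' @param variant coding variant (`"S"`, `"P"`, `"T"`).
#' @param health health preset name or mean degeneration.
#' @param profile a [sim_profile()].
#' @param seed master seed.
#' @param model optional pre-built [setup_model()] (overrides
#'   `health`/`profile`).
#' @return list with `fit` (a `psychfit`), `smt_db` (threshold, `NA` if
#'   the criterion exceeds the fitted asymptote), `scores` (contrast,
#'   percent correct), `variant`, `health`.
#' @export
run_smt <- function(variant = "S", health = "healthy",
                    profile = sim_profile("desk"), seed = 1, model = NULL) {
  if (is.null(model)) model <- setup_model(health, profile, seed)
  profile <- model$profile
  fs <- 17400
  make_stim <- function(contrast, sd) {
    x <- ripple_noise(contrast, seed = sd, level_dbfs = NULL)
    loudness_roving(x, profile$rove_mean_dbfs, profile$rove_peak_db,
                    profile$rove_res_db, seed = derive_seed(sd, "rove"))
  }
  n_tr <- profile$smt_train_per_class
  train_feats <- vector("list", 2 * n_tr)
  train_labs <- character(2 * n_tr)
  for (i in seq_len(n_tr)) {
    ct <- with_seed(derive_seed(seed, paste0("trct", i)),
                    sample(profile$smt_train_contrasts, 1))
    sd_t <- derive_seed(seed, paste0("smt-train-t", i))
    train_feats[[i]] <- front_end(make_stim(ct, sd_t), fs, model, variant,
                                  seed = derive_seed(sd_t, "noise"))
    train_labs[i] <- "target"
    sd_r <- derive_seed(seed, paste0("smt-train-r", i))
    train_feats[[n_tr + i]] <- front_end(make_stim(0, sd_r), fs, model,
                                         variant,
                                         seed = derive_seed(sd_r, "noise"))
    train_labs[n_tr + i] <- "reference"
  }
  models <- train_models(train_feats, train_labs)

  n_te <- profile$smt_test_per_class
  scores <- data.frame(contrast_db = profile$smt_contrasts, correct = NA_real_)
  for (ci in seq_along(profile$smt_contrasts)) {
    ct <- profile$smt_contrasts[ci]
    ok <- 0L
    for (i in seq_len(n_te)) {
      for (cls in c("target", "reference")) {
        sd_i <- derive_seed(seed, paste0("smt-test", ct, cls, i))
        x <- make_stim(if (cls == "target") ct else 0, sd_i)
        fe <- front_end(x, fs, model, variant,
                        seed = derive_seed(sd_i, "noise"))
        r <- recognize_binary(fe, models)
        ok <- ok + (r$label == cls)
      }
    }
    scores$correct[ci] <- 100 * ok / (2 * n_te)
  }
  fit <- fit_psychometric(scores$correct, scores$contrast_db, p_chance = 50)
  smt <- tryCatch(threshold(fit, 79.4), error = function(e) {
    message("SMT undefined: ", conditionMessage(e)); NA_real_ })
  list(fit = fit, smt_db = smt, scores = scores, variant = variant,
       health = model$health)
}

#' Run one speech reception threshold experiment
#'
#' A balanced matrix corpus of `srt_sentences` sentences is mixed with
#' speech-shaped noise (speech fixed at -49 dBFS). Training pools all
#' sentences at every training SNR (plus clean); word models are trained
#' on the word-aligned feature segments. Testing decodes every sentence at
#' every test SNR through the 5-slot x 10-word grammar; word scores per
#' SNR are fitted with a psychometric function (chance 10%) and the SRT is
#' read at 50% words correct.
#'
#' @inheritParams run_smt
#' @return list with `fit`, `srt_db`, `scores` (snr, percent words
#'   correct), `variant`, `health`.
#' @export
run_srt <- function(variant = "S", health = "healthy",
                    profile = sim_profile("desk"), seed = 1, model = NULL) {
  if (is.null(model)) model <- setup_model(health, profile, seed)
  profile <- model$profile
  fs <- 17400
  corpus <- matrix_corpus(profile$srt_sentences,
                          seed = derive_seed(seed, "corpus"))
  noise <- speech_shaped_noise(12, seed = derive_seed(seed, "ssn"), fs = fs)
  inv <- word_inventory()
  slots <- split(inv$word, inv$category)[unique(inv$category)]

  sent_features <- function(si, snr, tag) {
    sent <- unlist(corpus[si, ])
    sd_i <- derive_seed(seed, paste(tag, si, snr))
    au <- synth_speech(sent, seed = derive_seed(seed, paste0("tok", si)),
                       fs = fs)
    b <- attr(au, "boundaries_s")
    mix <- mix_at_snr(au, noise, snr, speech_dbfs = profile$rove_mean_dbfs,
                      seed = sd_i)
    fe <- front_end(mix, fs, model, variant,
                    seed = derive_seed(sd_i, "noise"))
    list(feat = fe, bounds = b, words = sent)
  }

  ## training: pooled over SNR conditions, word-aligned segments
  wfeat <- list(); wlab <- character(0)
  for (snr in profile$srt_train_snrs) {
    for (si in seq_len(nrow(corpus))) {
      r <- sent_features(si, snr, "train")
      fr <- nrow(r$feat)
      for (wi in 1:5) {
        i0 <- max(1, floor(r$bounds[wi, 1] * 100) + 1)
        i1 <- min(fr, ceiling(r$bounds[wi, 2] * 100))
        wfeat[[length(wfeat) + 1]] <- r$feat[i0:i1, , drop = FALSE]
        wlab <- c(wlab, r$words[wi])
      }
    }
  }
  models <- train_models(wfeat, wlab)

  ## testing: full-sentence decoding through the closed grammar; a reduced
  ## profile may decode only the first srt_test_sentences of the corpus
  n_test <- if (is.null(profile$srt_test_sentences)) nrow(corpus)
            else min(profile$srt_test_sentences, nrow(corpus))
  scores <- data.frame(snr_db = profile$srt_test_snrs, correct = NA_real_)
  for (ci in seq_along(profile$srt_test_snrs)) {
    snr <- profile$srt_test_snrs[ci]
    ok <- 0L; tot <- 0L
    for (si in seq_len(n_test)) {
      r <- sent_features(si, snr, "test")
      dec <- recognize_sentence(r$feat, models, slots)
      ok <- ok + sum(dec$words == r$words)
      tot <- tot + 5L
    }
    scores$correct[ci] <- 100 * ok / tot
  }
  fit <- fit_psychometric(scores$correct, scores$snr_db, p_chance = 10)
  srt <- tryCatch(threshold(fit, 50), error = function(e) {
    message("SRT undefined: ", conditionMessage(e)); NA_real_ })
  list(fit = fit, srt_db = srt, scores = scores, variant = variant,
       health = model$health)
}

#' Run the variant x health experiment matrix
#'
#' Executes one experiment type over all requested coding variants and
#' neural health conditions with a shared master seed (geometry and
#' fitting are cached per cell within the session). Cells that fail are
#' reported and skipped; the run continues.
#'
#' @param type `"smt"` or `"srt"`.
#' @param variants coding variants to run.
#' @param healths health presets to run.
#' @param profile a [sim_profile()].
#' @param seed master seed.
#' @return data.frame with one row per cell: variant, health,
#'   threshold_db, p_max, r_squared.
#' @export
run_matrix <- function(type = c("smt", "srt"), variants = c("S", "P", "T"),
                       healths = c("healthy", "moderate", "severe"),
                       profile = sim_profile("desk"), seed = 1) {
  type <- match.arg(type)
  rows <- list()
  for (h in healths) for (v in variants) {
    res <- tryCatch({
      if (type == "smt") {
        r <- run_smt(v, h, profile, seed)
        data.frame(variant = v, health = h, threshold_db = r$smt_db,
                   p_max = r$fit$p_max, r_squared = r$fit$r_squared)
      } else {
        r <- run_srt(v, h, profile, seed)
        data.frame(variant = v, health = h, threshold_db = r$srt_db,
                   p_max = r$fit$p_max, r_squared = r$fit$r_squared)
      }
    }, error = function(e) {
      warning(sprintf("cell %s/%s failed: %s", v, h, conditionMessage(e)))
      data.frame(variant = v, health = h, threshold_db = NA_real_,
                 p_max = NA_real_, r_squared = NA_real_)
    })
    rows[[length(rows) + 1]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
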