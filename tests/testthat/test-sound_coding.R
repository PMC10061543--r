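test_that("clinical-unit to current conversion is linear with the device constants", {
  expect_equal(cu_to_microamps(0, 18), 0)
  expect_equal(cu_to_microamps(250, 18), 1081.4, tolerance = 1e-4)
  expect_equal(cu_to_microamps(471, 229), 160.1, tolerance = 1e-3)
  expect_equal(cu_to_microamps(100, 18), 2 * cu_to_microamps(50, 18))
  expect_error(cu_to_microamps(100, 0), "positive")
  expect_error(cu_to_microamps(-1, 18), "non-negative")
})

test_that("pulse tables cover every channel once per cycle at a 540 us period", {
  for (v in c("S", "P", "T")) {
    pt <- build_pulse_table(v)
    expect_equal(sort(unlist(pt$slots)), 1:15)
    expect_equal(pt$channel_period_us, 540)
    expect_equal(pt$phase_us, 18)
  }
  s <- build_pulse_table("S")
  expect_length(s$slots, 15)
  expect_true(all(lengths(s$slots) == 1))
  expect_equal(s$gap_slots, 0L)
  expect_equal(diff(s$group_onsets_us), rep(36, 14))

  p <- build_pulse_table("P")
  expect_equal(p$gap_slots, 1L)
  grp6 <- p$slots[[which(vapply(p$slots, function(g) 6 %in% g, logical(1)))]]
  expect_true(14 %in% grp6)

  t3 <- build_pulse_table("T")
  expect_length(t3$slots, 5)
  expect_equal(t3$slots[[1]], c(1L, 6L, 11L))
  expect_equal(t3$gap_slots, 2L)
  expect_equal(diff(t3$group_onsets_us), rep(108, 4))
  expect_error(build_pulse_table("X"))
})

test_that("per-channel pulse rate is 1852 pps for all variants and any input", {
  map <- fitting_map(rep(120, 15))
  x <- with_seed(4, rnorm(17400))  # 1 s of noise
  for (v in c("S", "P", "T")) {
    elg <- encode(set_level(x, -49), 17400, map, v)
    for (ch in c(1, 8, 15)) {
      on <- sort(elg$onset_us[elg$channel == ch])
      expect_equal(diff(on), rep(540, length(on) - 1))
      expect_equal(length(on) / (attr(elg, "duration_us") * 1e-6),
                   1852, tolerance = 0.01)
    }
  }
})

test_that("digital silence is coded at the threshold floor", {
  map <- fitting_map(rep(120, 15))
  elg <- encode(numeric(8700), 17400, map, "S")
  expect_true(all(elg$amplitude_cu <= map$t_cu[elg$channel] + 1e-9))
})

test_that("empty audio gives an empty electrodogram", {
  map <- fitting_map(rep(120, 15))
  elg <- encode(numeric(0), 17400, map, "S")
  expect_equal(nrow(elg), 0L)
  expect_equal(attr(elg, "duration_us"), 0)
})

test_that("a pure tone at a band center maximises that band's channel", {
  map <- fitting_map(rep(200, 15))
  cfg <- coder_config()
  edges <- exp(seq(log(cfg$band_lo), log(cfg$band_hi), length.out = 16))
  for (b in c(3, 8, 12)) {
    f0 <- sqrt(edges[b] * edges[b + 1])   # log-center of band b
    tt <- seq(0, 0.3, by = 1 / 17400)
    tone <- set_level(sin(2 * pi * f0 * tt), -40)
    elg <- encode(tone, 17400, map, "S")
    mean_amp <- tapply(elg$amplitude_cu, elg$channel, mean)
    expect_equal(as.integer(names(which.max(mean_amp))), b)
  }
})

test_that("rendered pulses are charge balanced on every electrode", {
  map <- fitting_map(rep(150, 15))
  x <- set_level(with_seed(9, rnorm(8700)), -49)
  for (v in c("S", "P", "T")) {
    elg <- encode(x, 17400, map, v)
    dense <- render_electrodogram(elg)
    n_cycle <- 540  # samples per cycle at 1 MHz
    n_full <- floor(ncol(dense) / n_cycle) * n_cycle
    for (e in c(1, 8, 16)) {
      expect_equal(sum(dense[e, 1:n_full]), 0, tolerance = 1e-9)
    }
  }
})

test_that("steering splits the channel current across the pair and conserves it", {
  ev <- data.frame(onset_us = 0, channel = 8L, electrode_apical = 8L,
                   electrode_basal = 9L, steering = 3 / 8,
                   amplitude_cu = 200, phase_us = 18)
  elg <- structure(ev, duration_us = 100, variant = "S",
                   pulse_table = build_pulse_table("S"),
                   class = c("electrodogram", "data.frame"))
  dense <- render_electrodogram(elg)
  amp <- cu_to_microamps(200, 18)
  expect_equal(dense[8, 1], -(1 - 3 / 8) * amp)
  expect_equal(dense[9, 1], -(3 / 8) * amp)
  expect_equal(dense[8, 1] + dense[9, 1], -amp)   # current conservation
  expect_equal(dense[8, 19], (1 - 3 / 8) * amp)   # anodic phase follows
})
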