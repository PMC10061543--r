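test_that("auditory filters partition the population within the extent bounds", {
  for (deg in c(5, 10, 15)) {
    tm <- desk_model(mean_deg = deg)
    bank <- group_fibers(tm$interface, tm$act)
    all_f <- sort(unlist(bank$groups))
    expect_equal(all_f, seq_along(tm$interface$alpha))  # disjoint + exhaustive
    n_g <- length(bank$groups)
    expect_gte(n_g, 16)
    expect_lte(n_g, 39)
    ext <- bank$extent_mm
    expect_true(all(ext <= 2.6 + 1e-9))
    # the minimum-extent rule may be relaxed only for the apical remainder
    expect_true(all(ext[-n_g] >= 1.1 - 1e-9))
  }
})

test_that("hand-applied merge and split rules reproduce the grouping", {
  # synthetic interface: 60 fibers, 0.1 mm apart; labels force one short run
  arc <- seq(0, by = 0.1, length.out = 60)
  iface <- structure(list(alpha = integer(60), bm_arc_mm = arc),
                     class = "eni")
  peak <- matrix(0, 60, 3)
  peak[1:14, 1] <- 1          # 1.3 mm run: kept
  peak[15:19, 2] <- 1         # 0.4 mm run: merged toward the apex
  peak[20:60, 3] <- 1         # 4.0 mm run: split basal-first at 2.6 mm
  act <- list(peak = peak)
  bank <- group_fibers(iface, act)
  expect_equal(bank$groups[[1]], 1:14)
  # the short run was absorbed apically, then the long run split at 2.6 mm
  expect_equal(bank$groups[[2]][1], 15)
  expect_equal(bank$extent_mm[2], 2.6, tolerance = 1e-9)
  expect_equal(sort(unlist(bank$groups)), 1:60)
})

test_that("a run already within bounds is left untouched", {
  arc <- seq(0, by = 0.1, length.out = 40)
  iface <- structure(list(alpha = integer(40), bm_arc_mm = arc),
                     class = "eni")
  peak <- matrix(0, 40, 2)
  peak[1:20, 1] <- 1; peak[21:40, 2] <- 1   # 1.9 mm runs
  bank <- group_fibers(iface, list(peak = peak))
  expect_equal(bank$groups, list(1:20, 21:40))
})

test_that("spike binning conserves counts and stacks coincident spikes", {
  bank <- structure(list(groups = list(1:2, 3L),
                         extent_mm = c(1, 1), electrode = c(1L, 2L)),
                    class = "auditory_filter_bank")
  sp <- structure(list(times = list(c(0.01001, 0.02), 0.01005, 0.5),
                       fibers = 1:3, duration_s = 1, seed = 1),
                  class = "spike_activity")
  S <- spike_group_activity(sp, bank)
  expect_equal(sum(S), 4)
  expect_equal(dim(S), c(2, 10000))
  # fibers 1 and 2 spike in the same 100 us bin
  expect_equal(S[1, floor(0.01001 * 1e4) + 1], 2)
  expect_equal(S[2, floor(0.5 * 1e4) + 1], 1)
  # no spikes: all-zero
  sp0 <- structure(list(times = list(numeric(0), numeric(0), numeric(0)),
                        fibers = 1:3, duration_s = 1, seed = 1),
                   class = "spike_activity")
  expect_true(all(spike_group_activity(sp0, bank) == 0))
})

test_that("temporal filter is a normalized Gaussian convolution", {
  S <- matrix(0, 1, 400); S[1, 200] <- 1
  F1 <- temporal_filter(S)
  # impulse response equals the sampled kernel
  kern <- cisim:::gaussian_kernel(10000, 1e-3)
  K <- (length(kern) - 1) / 2
  expect_equal(F1[1, (200 - K):(200 + K)], kern, tolerance = 1e-12)
  expect_equal(sum(F1), 1, tolerance = 1e-12)
  # DC preserved, zero in -> zero out, linearity
  expect_equal(temporal_filter(matrix(3, 2, 300))[, 150], c(3, 3),
               tolerance = 1e-9)
  expect_true(all(temporal_filter(matrix(0, 2, 100)) == 0))
  expect_equal(temporal_filter(2 * S), 2 * F1, tolerance = 1e-12)
})

test_that("forward masking bounds the signal and decays with the release constant", {
  n <- 3000
  F_g <- matrix(0, 1, n)
  F_g[1, 500:800] <- 1
  IR <- forward_masking(F_g, tau_release_s = 50e-3)
  expect_true(all(IR >= F_g - 1e-12))
  # constant region: masker equals signal in steady state
  expect_equal(IR[1, 800], 1, tolerance = 1e-2)
  # after the offset the tail decays exponentially at the release rate
  tail_ratio <- IR[1, 1001] / IR[1, 1000]
  expect_equal(tail_ratio, exp(-1 / (10000 * 50e-3)), tolerance = 1e-6)
  # constant input: identity in steady state
  Fc <- matrix(2, 1, n)
  expect_equal(forward_masking(Fc)[1, n], 2, tolerance = 1e-6)
})

test_that("downsampling preserves means and the stated frame arithmetic", {
  expect_equal(ncol(downsample_ir(matrix(0, 1, 4000))), 40)  # 0.4 s -> 40
  X <- matrix(5, 2, 1000)
  expect_true(all(downsample_ir(X) == 5))
  imp <- matrix(0, 1, 1000); imp[1, 355] <- 7
  D <- downsample_ir(imp)
  expect_equal(D[1, 4], 7 / 100)
  expect_equal(sum(D != 0), 1)
})

test_that("the full chain stays non-negative and finite on real spike input", {
  tm <- toy_model(101, mean_deg = 5)
  bank <- group_fibers(tm$interface, tm$act)
  elg <- make_fitting_pulse_train(8, 150)
  ic <- induced_current(elg, tm$interface, act = tm$act)
  sp <- simulate_spikes(ic, neuron_params(), seed = 3,
                        dt_pulse_us = 18, dt_gap_us = 90)
  ir <- internal_representation(sp, bank)
  expect_true(all(is.finite(ir)))
  expect_true(all(ir >= 0))
  expect_equal(ncol(ir), ceiling(0.22 * 100))
})
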