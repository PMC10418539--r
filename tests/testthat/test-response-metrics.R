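test_that("PSTH arithmetic, conservation and input checks", {
  p <- compute_psth(list(0.5, 0.5), bin_ms = 1, window = c(0, 2))
  expect_equal(p$rates, c(1000, 0))
  expect_equal(compute_psth(list(numeric(0), numeric(0)), 1, c(0, 5))$rates,
               rep(0, 5))
  # conservation: sum(rates) * bin * n_trials recovers the spike count
  set.seed(1)
  trials <- replicate(7, sort(runif(20, 0, 400)), simplify = FALSE)
  p <- compute_psth(trials, 10, c(0, 400))
  expect_equal(sum(p$rates) * 10 / 1000 * 7, 140)
  expect_error(compute_psth(list(), 1, c(0, 10)), "empty")
  expect_error(compute_psth(list(1), 3, c(0, 10)), "divide")
})

test_that("spontaneous rate pools baseline counts", {
  trials <- c(replicate(10, c(-50, -20, 5), simplify = FALSE),
              replicate(10, c(-80, -10), simplify = FALSE))
  expect_equal(spontaneous_rate(trials), 40 / (20 * 0.1))  # 20 Hz
  expect_equal(spontaneous_rate(list(numeric(0), numeric(0))), 0)
  expect_error(spontaneous_rate(trials, baseline = c(0, 0)), "positive")
})

test_that("driven spikes are baseline-corrected per presentation", {
  trials <- replicate(5, seq(10, 390, length.out = 12), simplify = FALSE)
  expect_equal(driven_spikes(trials, c(0, 400), 0), 12)
  expect_equal(driven_spikes(trials, c(0, 400), 10), 12 - 4)  # 10 Hz x 0.4 s
  expect_equal(driven_spikes(trials, c(0, 400), 10, correction = "none"), 12)
  # pure spontaneous activity drives ~0 after correction
  site <- make_site(spont_hz = 30)
  site$speech_gain <- 0  # silence the evoked components entirely
  ev <- simulate_speech_trials(site, build_speech_catalog(), seed = 8,
                               n_repeats = 500)
  trials <- split(ev$t_ms, factor(ev$trial, levels = 0:499))
  d <- driven_spikes(trials, c(0, 400), spontaneous_rate(trials))
  # SE includes the baseline-estimate term: d = mean count - 0.4 * spont_hat
  se <- sqrt(30 * 0.4 / 500 + 0.4^2 * 30 / (500 * 0.1))
  expect_lt(abs(d), 3 * se)
})

test_that("onset latency summarises per-trial first spikes robustly", {
  trials <- replicate(6, c(7, 30, 80), simplify = FALSE)
  expect_equal(onset_latency(trials), 7)
  # invariant to adding spikes later than the current first spike
  more <- lapply(trials, function(t) c(t, 12, 95))
  expect_equal(onset_latency(more), onset_latency(trials))
  # pre-onset spikes are ignored; all-quiet returns NA
  expect_equal(onset_latency(list(c(-5, 9), c(-2, 11))), 10)
  expect_true(is.na(onset_latency(list(numeric(0), c(-10)))))
})

test_that("speech summary reproduces constructed and simulated structure", {
  cat <- build_stimulus_catalog()
  trials <- replicate(20, c(7, 200), simplify = FALSE)
  ds <- make_ds(list(dad_60 = trials), catalog = cat)
  sp <- speech_response_summary(ds, cat)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$onset_latency_ms, 7)
  expect_equal(sp$driven_full, 2)       # no baseline spikes -> no correction
  expect_equal(sp$driven_onset, 1)
  expect_equal(sp$driven_vowel, 1)
  # peak latency lands on the onset transient of a simulated site
  site <- make_site(onset_ms = 9, spont_hz = 5, rmax_hz = 300)
  ev <- simulate_speech_trials(site, cat$speech, seed = 11, n_repeats = 100)
  ev$site_id <- "s0001"
  ds2 <- spike_dataset(ev, ds$sites, catalog = cat)
  sp2 <- speech_response_summary(ds2, cat)
  lat <- sp2$peak_latency_ms[sp2$stimulus_id == "dad_60"]
  expect_gt(lat, site$onset_ms - 1)      # alpha-kernel peak ~ onset + 3 ms
  expect_lt(lat, site$onset_ms + 7)
})

test_that("window counts are additive before baseline correction", {
  ds <- cohort_fixture()
  s <- ds$sites$site_id[3]
  trials <- ds$events[ds$events$site_id == s &
                        ds$events$stimulus_id == "shad_60", ]
  tl <- split(trials$t_ms, factor(trials$trial, levels = 0:19))
  full <- driven_spikes(tl, c(0, 400), correction = "none")
  expect_equal(driven_spikes(tl, c(0, 40), correction = "none") +
                 driven_spikes(tl, c(40, 400), correction = "none"), full)
})

test_that("the simulated speech deficit appears in the summary medians", {
  ds <- cohort_fixture()
  sp <- speech_response_summary(ds)
  sp$group <- ds$sites$group[match(sp$site_id, ds$sites$site_id)]
  med <- tapply(sp$driven_full, sp$group, median)
  expect_lt(med[["vpa"]], med[["saline"]])
})
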