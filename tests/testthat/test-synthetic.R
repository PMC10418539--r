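test_that("cohort sampling is deterministic and respects the config", {
  cfg <- cohort_config(n_rats_per_group = 2, n_sites_per_rat = 5, seed = 9)
  s1 <- sample_cohort(cfg)
  s2 <- sample_cohort(cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 20)
  expect_equal(as.vector(table(s1$group)), c(10L, 10L))
  expect_true(mean(s1$speech_gain[s1$group == "vpa"]) <
                mean(s1$speech_gain[s1$group == "saline"]))
  expect_true(all(s1$cf_hz >= 1000 & s1$cf_hz <= 32000))
  expect_true(all(s1$bw40_oct > s1$bw10_oct))
  expect_error(cohort_config(n_rats_per_group = 0), ">= 1")
  expect_error(cohort_config(speech_gain_mean = c(saline = 1, vpa = 1.2)),
               "0, 1")
})

test_that("tone rate model is calibrated to threshold and bandwidths", {
  site <- make_site(cf_hz = 4000, threshold_db = 20, bw10_oct = 1,
                    bw40_oct = 1.7, rmax_hz = 200)
  # zero below threshold at CF
  expect_equal(tone_rate(site, 4000, 15), 0)
  # saturates near rmax at 75 dB
  expect_gt(tone_rate(site, 4000, 75), 0.95 * site$rmax_hz)
  # bandwidth calibration: threshold_at(cf * 2^(bw/2)) = threshold + 10/40
  expect_equal(tone_threshold_at(site, 4000 * 2^(1 / 2)), 30)
  expect_equal(tone_threshold_at(site, 4000 * 2^(1.7 / 2)), 60)
  expect_equal(tone_threshold_at(site, 4000 / 2^(1 / 2)), 30)
  expect_error(tone_rate(site, 500, 60), "grid")
  expect_error(tone_rate(site, 4000, 80), "grid")
})

test_that("tone sweep spikes match the closed-form expectation", {
  grid <- build_tone_grid()
  site <- make_site(cf_hz = 2000, threshold_db = 20, spont_hz = 0)
  ev <- simulate_tone_sweep(site, grid, seed = 1)
  # no spikes in below-threshold conditions when spontaneous rate is zero
  mu <- tone_rate(site, grid$freq_hz, grid$level_db)
  silent <- grid$stimulus_id[mu == 0]
  expect_false(any(ev$stimulus_id %in% silent))
  expect_true(all(ev$t_ms >= site$onset_ms))
  # determinism
  expect_identical(ev, simulate_tone_sweep(site, grid, seed = 1))
  # Monte-Carlo: replicate the CF/75-dB condition many times; the mean
  # count must match rate x 50 ms within 3 SE
  cond <- grid[abs(grid$freq_hz - 2000) < 1 & grid$level_db == 75, ]
  mini <- cond[rep(1, 400), ]
  mini$stimulus_id <- sprintf("tone_%04d", seq_len(400))
  ev2 <- simulate_tone_sweep(site, mini, seed = 2)
  counts <- tabulate(match(ev2$stimulus_id, mini$stimulus_id), 400)
  expected <- tone_rate(site, cond$freq_hz, 75) * 0.050
  se <- sqrt(expected / 400)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("speech simulation carries the gain, level and latency structure", {
  sp <- build_speech_catalog()
  # gain 0 with no spontaneous activity -> silence
  mute <- make_site(speech_gain = 0, spont_hz = 0)
  expect_equal(nrow(simulate_speech_trials(mute, sp, seed = 1)), 0)
  # driven count scales with speech_gain: vpa-like 0.7 gain site yields
  # ~0.7x the driven spikes of a matched full-gain site
  a <- make_site(speech_gain = 1, spont_hz = 0)
  b <- make_site(speech_gain = 0.7, spont_hz = 0)
  na <- nrow(simulate_speech_trials(a, sp, seed = 3, n_repeats = 400))
  nb <- nrow(simulate_speech_trials(b, sp, seed = 4, n_repeats = 400))
  expect_lt(abs(nb / na - 0.7), 0.05)
  # driven count rises monotonically with level for 'dad'
  ev <- simulate_speech_trials(a, sp, seed = 5, n_repeats = 300)
  n_lev <- vapply(c("dad_45", "dad_60", "dad_75"), function(id)
    sum(ev$stimulus_id == id), numeric(1))
  expect_true(all(diff(n_lev) > 0))
})

test_that("noise-train simulation phase-locks as designed", {
  spec <- build_noise_train_spec()
  # zero jitter, zero spontaneous -> all spikes at identical phase -> VS 1
  site0 <- make_site(jitter_ms = 0, spont_hz = 0)
  ev <- simulate_noise_train_trials(site0, spec, seed = 1)
  expect_equal(vector_strength(ev$t_ms, 10), 1)
  # wrapped-Gaussian closed form: E[VS] ~ exp(-(2 pi f sigma)^2 / 2)
  for (sigma in c(2, 5, 10)) {
    site <- make_site(jitter_ms = sigma, spont_hz = 0, rmax_hz = 400)
    ev <- simulate_noise_train_trials(site, spec, seed = sigma,
                                      n_repeats = 300)
    expect_lt(abs(vector_strength(ev$t_ms, 10) -
                    exp(-(2 * pi * 10 * sigma / 1000)^2 / 2)), 0.02)
  }
  # trial-averaged PSTH shows one response peak per burst
  site <- make_site(jitter_ms = 2, spont_hz = 5, rmax_hz = 300)
  ev <- simulate_noise_train_trials(site, spec, seed = 7)
  trials <- split(ev$t_ms, factor(ev$trial, levels = 0:19))
  p <- compute_psth(trials, 1, c(0, 600))
  for (on in spec$onsets_ms) {
    w <- p$t >= on & p$t < on + 50
    pk <- p$t[w][which.max(p$rates[w])]
    expect_lt(abs(pk - (on + site$onset_ms)), 5)
    expect_gt(max(p$rates[w]), 10 * site$spont_hz)
  }
})

test_that("full cohort simulation is deterministic and group-symmetric", {
  ds <- cohort_fixture()
  cfg <- cohort_fixture_config()
  ds2 <- simulate_cohort(cfg)
  expect_identical(ds$events, ds2$events)
  expect_identical(ds$sites, ds2$sites)
  # only the speech manipulation distinguishes groups
  sm <- ds$site_models
  expect_true(all(sm$latency_offset_ms[sm$group == "vpa"] == -1))
  expect_true(all(sm$latency_offset_ms[sm$group == "saline"] == 0))
  expect_equal(nrow(ds$sites), 20)
  v <- validate_dataset(ds)
  expect_false(any(v$level == "error"))
})
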