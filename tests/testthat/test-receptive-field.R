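# Independent reference implementation of the extraction procedure,
# written as literal loops (no shared code with the package internals).
oracle_extract <- function(counts, spont_expect, k = 2, min_cells = 5) {
  nr <- nrow(counts); nc <- ncol(counts)
  sm <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    acc <- 0; n <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
        acc <- acc + counts[ii, jj]; n <- n + 1
      }
    }
    sm[i, j] <- acc / n
  }
  resp <- sm > spont_expect + k * sqrt(spont_expect + 0.25)
  # label components by repeated neighbour propagation
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (cell in which(resp)) if (lab[cell] == 0L) {
    nxt <- nxt + 1L
    lab[cell] <- nxt
    repeat {
      grew <- FALSE
      for (c2 in which(resp & lab == 0L)) {
        i <- (c2 - 1) %% nr + 1; j <- (c2 - 1) %/% nr + 1
        nb <- c(if (i > 1) lab[i - 1, j], if (i < nr) lab[i + 1, j],
                if (j > 1) lab[i, j - 1], if (j < nc) lab[i, j + 1])
        if (any(nb == nxt)) { lab[c2] <- nxt; grew <- TRUE }
      }
      if (!grew) break
    }
  }
  if (nxt == 0L) return(list(responsive = FALSE))
  sizes <- tabulate(lab[lab > 0], nxt)
  comp <- lab == which.max(sizes)
  if (sum(comp) < min_cells) return(list(responsive = FALSE))
  levels_db <- seq(0, 75, 5)
  thr_col <- min(which(apply(comp, 2, any)))
  f <- which(comp[, thr_col])
  cf_idx <- f[(length(f) + 1) %/% 2]
  span <- function(col) {
    if (col > nc || !any(comp[, col])) return(NA_real_)
    rng <- range(which(comp[, col]))
    (rng[2] - rng[1]) * 0.0625
  }
  list(responsive = TRUE, threshold_db = levels_db[thr_col],
       cf_idx = cf_idx, bw10 = span(thr_col + 2), bw40 = span(thr_col + 8))
}

# Matrix with a single responsive column at 8 kHz (grid step 48) appearing
# at 20 dB and widening by +/-4 grid steps per 10 dB of level.
widening_matrix <- function(c0 = 4) {
  counts <- matrix(0, 81, 16)
  levels_db <- seq(0, 75, 5)
  for (j in seq_along(levels_db)) {
    l <- levels_db[j]
    if (l >= 20) {
      half <- round(4 * (l - 20) / 10)
      counts[max(1, 49 - half):min(81, 49 + half), j] <- c0
    }
  }
  counts
}

as_tuning <- function(counts, spont_expect = 0, site_id = "sX") {
  m <- list(counts = counts, freq_hz = 1000 * 2^(0.0625 * (0:80)),
            level_db = seq(0, 75, 5), evoked_window = c(0, 50),
            spont_expect = spont_expect,
            spont_hz = spont_expect / 0.05, site_id = site_id)
  class(m) <- "tuning_matrix"
  m
}

test_that("extraction matches an independent oracle on a constructed RF", {
  counts <- widening_matrix()
  m <- as_tuning(counts)
  rf <- extract_receptive_field(m)
  orc <- oracle_extract(counts, 0)
  expect_true(rf$responsive)
  expect_equal(rf$threshold_db, orc$threshold_db)
  expect_equal(rf$cf_hz, m$freq_hz[orc$cf_idx])
  expect_equal(rf$bw10_oct, orc$bw10)
  expect_equal(rf$bw40_oct, orc$bw40)
  # the constructed geometry: CF at 8 kHz, threshold 20 dB; the smoothed
  # responsive region is within one grid step of the nominal 0.5-oct span
  expect_equal(rf$cf_hz, 8000)
  expect_equal(rf$threshold_db, 20)
  expect_equal(rf$bw10_oct, 0.625)
  expect_lt(abs(rf$bw10_oct - 0.5), 0.0625 * 2 + 1e-9)
})

test_that("degenerate matrices are non-responsive", {
  rf <- extract_receptive_field(as_tuning(matrix(0, 81, 16)))
  expect_false(rf$responsive)
  expect_true(is.na(rf$cf_hz))
  # a corner speck: smoothing spreads it over only 4 cells, below the
  # minimum component size
  speck <- matrix(0, 81, 16); speck[1, 1] <- 50
  rf2 <- extract_receptive_field(as_tuning(speck))
  expect_false(rf2$responsive)
  expect_equal(rf2$n_component, 4)
})

test_that("extraction is scale-equivariant for a clean receptive field", {
  counts <- widening_matrix()
  rf1 <- extract_receptive_field(as_tuning(counts))
  rf2 <- extract_receptive_field(as_tuning(counts * 2))
  expect_equal(rf1$cf_hz, rf2$cf_hz)
  expect_equal(rf1$threshold_db, rf2$threshold_db)
})

test_that("tuning matrix counts conserve the evoked spikes", {
  ds <- cohort_fixture()
  s <- ds$sites$site_id[1]
  m <- build_tuning_matrix(ds, s)
  ev <- ds$events[ds$events$site_id == s &
                    startsWith(ds$events$stimulus_id, "tone_"), ]
  expect_equal(sum(m$counts), sum(ev$t_ms >= 0 & ev$t_ms < 50))
  # silent site -> all-zero matrix
  ds0 <- make_ds(list(tone_0001 = list(numeric(0), numeric(0))))
  expect_equal(sum(build_tuning_matrix(ds0, "s0001")$counts), 0)
  # events outside the grid are an error
  dsx <- make_ds(list(tone_9999 = list(5)))
  expect_error(build_tuning_matrix(dsx, "s0001"), "outside the grid")
})

test_that("receptive-field parameters recover the generative site model", {
  cfg <- cohort_config(n_rats_per_group = 1, n_sites_per_rat = 10,
                       rmax_mean_hz = 350, rmax_sd_hz = 0,
                       spont_mean_hz = 5, spont_shape = 10, seed = 31)
  ds <- simulate_cohort(cfg, stimuli = "tones")
  rf <- rf_table(ds, latencies = FALSE)
  sm <- ds$site_models
  expect_true(all(rf$responsive))
  # a site whose CF sits against the grid edge can lose part of its
  # responsive region to truncation; require 90% joint recovery
  ok <- abs(log2(rf$cf_hz / sm$cf_hz)) <= 0.25 &
    abs(rf$threshold_db - sm$threshold_db) <= 5
  expect_gte(mean(ok), 0.9)
})

test_that("tone latencies are ordered and track the generative onset", {
  cfg <- cohort_config(n_rats_per_group = 1, n_sites_per_rat = 8,
                       onset_mean_ms = 8, onset_sd_ms = 0,
                       rmax_mean_hz = 350, rmax_sd_hz = 0, seed = 13)
  ds <- simulate_cohort(cfg, stimuli = "tones")
  rf <- rf_table(ds, latencies = TRUE)
  # the moving-average smoothing advances the detected onset slightly
  expect_lt(abs(mean(rf$onset_ms) - 8), 2)
  expect_true(all(abs(rf$onset_ms - 8) <= 3))
  expect_true(all(rf$peak_ms >= rf$onset_ms))
  expect_true(all(rf$end_of_peak_ms > rf$peak_ms))
})

test_that("octave bins and the rate-intensity function summarise the grid", {
  uni <- as_tuning(matrix(3, 81, 16))
  expect_equal(unname(octave_binned_rates(uni)), rep(3, 5))
  expect_equal(unname(rate_intensity_function(uni)), rep(3, 16))
  zero <- as_tuning(matrix(0, 81, 16))
  expect_equal(unname(octave_binned_rates(zero)), rep(0, 5))
  # octave bins partition the 81 frequencies as 16+16+16+16+17
  k <- 0:80
  expect_equal(as.vector(table(pmin(k %/% 16, 4))), c(16L, 16L, 16L, 16L, 17L))
  # a low-CF site has its largest octave bin at the CF
  site <- make_site(cf_hz = 1500, spont_hz = 2, rmax_hz = 300)
  ev <- simulate_tone_sweep(site, build_tone_grid(), seed = 3)
  ev$site_id <- "s0001"
  ds <- spike_dataset(ev, data.frame(site_id = "s0001", rat_id = "r1",
                                     group = "saline", depth_um = 1000))
  m <- build_tuning_matrix(ds, "s0001")
  expect_equal(unname(which.max(octave_binned_rates(m))), 1L)
  # driven rate grows with level (monotone trend, within noise)
  rif <- rate_intensity_function(m)
  expect_gt(cor(seq_along(rif), rif, method = "spearman"), 0.8)
})

test_that("CF bands split at 8 kHz with unassigned for missing CF", {
  expect_equal(cf_band(c(1000, 8000, 8001, 32000, NA)),
               c("low", "low", "high", "high", "unassigned"))
})
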