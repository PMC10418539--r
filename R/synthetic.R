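#' Configuration for a synthetic two-group cohort
#'
#' Defines the generative model for a seeded cohort of multi-unit recording
#' sites nested within rats, split into a `saline` control group and a `vpa`
#' treated group.  The defaults encode the study conditions the analyses are
#' designed around: 20 repeats per speech/noise stimulus, one sweep per tone
#' condition, and a group effect confined to speech-evoked responses (a
#' multiplicative rate gain, default 0.7, and an onset-latency offset,
#' default -1 ms i.e. the treated group responds slightly *earlier*), while
#' tone and noise-train response parameters are drawn from identical
#' distributions in both groups.
#'
#' Site tuning parameters are drawn to match typical midbrain multi-unit
#' values: characteristic frequency log-uniform on 1-32 kHz, tone threshold
#' around 20 dB SPL, 10-dB bandwidth around 1.5 octaves, spontaneous rate
#' around 25 spikes/s, onset latency around 8 ms.
#'
#' @param n_rats_per_group,n_sites_per_rat Cohort size (counts >= 1).
#' @param n_repeats_speech,n_repeats_noise Trials per speech / noise-train
#'   stimulus.
#' @param speech_gain_mean Named vector, mean multiplicative speech gain per
#'   group (in (0, 1]).
#' @param speech_gain_sd,rat_gain_sd Site-level and rat-level (random effect)
#'   SD of the speech gain.
#' @param latency_offset_ms Named vector, group offset added to speech onset
#'   latency (may be negative).
#' @param threshold_mean_db,threshold_sd_db,bw10_mean_oct,bw10_sd_oct,bw40_extra_mean_oct,bw40_extra_sd_oct
#'   Tuning-parameter distributions (bw40 = bw10 + a positive increment).
#' @param spont_mean_hz,spont_shape Gamma-distributed spontaneous rate.
#' @param onset_mean_ms,onset_sd_ms Onset latency distribution.
#' @param rmax_mean_hz,rmax_sd_hz Peak driven rate distribution.
#' @param jitter_ms Gaussian spike-time jitter (SD) of noise-burst responses.
#' @param sigmoid_slope_db Slope of the rate-level sigmoid.
#' @param seed Master seed; the same config yields an identical cohort.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_rats_per_group = 5,
                          n_sites_per_rat = 20,
                          n_repeats_speech = 20,
                          n_repeats_noise = 20,
                          speech_gain_mean = c(saline = 1.0, vpa = 0.7),
                          speech_gain_sd = 0.10,
                          rat_gain_sd = 0.05,
                          latency_offset_ms = c(saline = 0, vpa = -1),
                          threshold_mean_db = 20, threshold_sd_db = 8,
                          bw10_mean_oct = 1.5, bw10_sd_oct = 0.3,
                          bw40_extra_mean_oct = 0.3, bw40_extra_sd_oct = 0.15,
                          spont_mean_hz = 25, spont_shape = 2,
                          onset_mean_ms = 8, onset_sd_ms = 1,
                          rmax_mean_hz = 200, rmax_sd_hz = 40,
                          jitter_ms = 4,
                          sigmoid_slope_db = 6,
                          seed = 1L) {
  if (n_rats_per_group < 1 || n_sites_per_rat < 1 ||
      n_repeats_speech < 1 || n_repeats_noise < 1)
    stop("all cohort counts must be >= 1")
  if (!all(c("saline", "vpa") %in% names(speech_gain_mean)))
    stop("speech_gain_mean must be named with groups 'saline' and 'vpa'")
  if (any(speech_gain_mean <= 0) || any(speech_gain_mean > 1))
    stop("speech_gain_mean must lie in (0, 1]")
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic cohort config: %d rats x %d sites per group\n",
    "  speech gain mean saline=%.2f vpa=%.2f; latency offset vpa=%+g ms\n",
    "  repeats: speech %d, noise %d; seed %d\n"),
    x$n_rats_per_group, x$n_sites_per_rat,
    x$speech_gain_mean[["saline"]], x$speech_gain_mean[["vpa"]],
    x$latency_offset_ms[["vpa"]], x$n_repeats_speech, x$n_repeats_noise,
    x$seed))
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Draw the site-model table for a cohort
#'
#' Samples per-site generative parameters under the master seed.  Sites are
#' nested within rats through a rat-level random effect on the speech gain;
#' all tone and noise-train parameters are drawn from the same distributions
#' in both groups.
#'
#' @param config A [cohort_config()].
#' @return Data frame (class `site_table`) with one row per site:
#'   `site_id`, `rat_id`, `group`, `depth_um`, `cf_hz`, `threshold_db`,
#'   `bw10_oct`, `bw40_oct`, `spont_hz`, `onset_ms`, `rmax_hz`,
#'   `speech_gain`, `latency_offset_ms`, `jitter_ms`.
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  groups <- c("saline", "vpa")
  n_per_rat <- config$n_sites_per_rat
  out <- list()
  idx <- 0L
  for (g in groups) {
    for (r in seq_len(config$n_rats_per_group)) {
      rat_eff <- stats::rnorm(1, 0, config$rat_gain_sd)
      n <- n_per_rat
      idx_site <- idx + seq_len(n)
      bw10 <- clamp(stats::rnorm(n, config$bw10_mean_oct, config$bw10_sd_oct),
                    0.4, 2.5)
      gain <- clamp(config$speech_gain_mean[[g]] + rat_eff +
                      stats::rnorm(n, 0, config$speech_gain_sd), 0.05, 1)
      out[[length(out) + 1L]] <- data.frame(
        site_id = sprintf("s%04d", idx_site),
        rat_id = sprintf("%s_r%02d", g, r),
        group = g,
        depth_um = 1000 + 200 * ((seq_len(n) - 1L) %% 21L),
        cf_hz = exp(stats::runif(n, log(1000), log(32000))),
        threshold_db = clamp(stats::rnorm(n, config$threshold_mean_db,
                                          config$threshold_sd_db), 0, 60),
        bw10_oct = bw10,
        bw40_oct = bw10 + pmax(stats::rnorm(n, config$bw40_extra_mean_oct,
                                            config$bw40_extra_sd_oct), 0.05),
        spont_hz = stats::rgamma(n, shape = config$spont_shape,
                                 scale = config$spont_mean_hz /
                                   config$spont_shape),
        onset_ms = clamp(stats::rnorm(n, config$onset_mean_ms,
                                      config$onset_sd_ms), 4, 14),
        rmax_hz = clamp(stats::rnorm(n, config$rmax_mean_hz,
                                     config$rmax_sd_hz), 60, 400),
        speech_gain = gain,
        latency_offset_ms = config$latency_offset_ms[[g]],
        jitter_ms = config$jitter_ms
      )
      idx <- idx + n
    }
  }
  sites <- do.call(rbind, out)
  rownames(sites) <- NULL
  class(sites) <- c("site_table", "data.frame")
  sites
}

# Tone threshold (dB SPL) as a function of frequency for one site: rises from
# the CF threshold as a power of octave distance, calibrated so the
# responsive region spans bw10_oct at threshold+10 dB and bw40_oct at
# threshold+40 dB (exponent log4 / log(bw40/bw10); the quadratic case is
# bw40 = 2 bw10).

#' Frequency-dependent tone threshold of a synthetic site
#'
#' @param site One row of a [sample_cohort()] table (data frame or list).
#' @param freq_hz Frequencies (Hz), vectorised.
#' @return Threshold in dB SPL at each frequency.
#' @export
tone_threshold_at <- function(site, freq_hz) {
  d <- octave_distance(site$cf_hz, freq_hz)
  p <- log(4) / log(site$bw40_oct / site$bw10_oct)
  site$threshold_db + 10 * (2 * d / site$bw10_oct)^p
}

#' Expected tone-evoked driven rate of a synthetic site
#'
#' Deterministic closed form: zero below the frequency-dependent threshold,
#' otherwise a sigmoid of level re threshold saturating at `rmax_hz`.
#' Identical in both groups (the group manipulation touches only speech).
#'
#' @inheritParams tone_threshold_at
#' @param level_db Levels (dB SPL), vectorised with `freq_hz`.
#' @param slope_db Sigmoid slope.
#' @return Driven rate in spikes/s.
#' @export
tone_rate <- function(site, freq_hz, level_db, slope_db = 6) {
  if (any(freq_hz < 1000 - 1e-9) || any(freq_hz > 32000 + 1e-9))
    stop("freq_hz outside the 1-32 kHz grid")
  if (any(level_db < 0) || any(level_db > 75))
    stop("level_db outside the 0-75 dB grid")
  thr <- tone_threshold_at(site, freq_hz)
  rate <- site$rmax_hz * stats::plogis((level_db - thr) / slope_db)
  rate[level_db < thr] <- 0
  rate
}

# Draw n spike times from the alpha-kernel (gamma shape 2) evoked-response
# profile, peaking tau ms after `lat`.
alpha_times <- function(n, lat, tau) lat + stats::rgamma(n, shape = 2, scale = tau)

#' Simulate one tone sweep for a site
#'
#' One trial per grid condition over the recorded window \[-100, 100) ms.
#' Spikes are an inhomogeneous Poisson process: homogeneous spontaneous
#' activity at `spont_hz` plus a driven alpha-kernel response (peak near
#' `onset_ms` + 5 ms) whose expected count equals
#' `tone_rate(...)` x the 50-ms evoked window.
#'
#' @param site One row of a site table.
#' @param grid Tone grid from [build_tone_grid()].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return Data frame of events: `stimulus_id`, `trial` (always 0), `t_ms`.
#' @export
simulate_tone_sweep <- function(site, grid, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as.data.frame(sim_tone_core(site, grid))
}

sim_tone_core <- function(site, grid) {
  mu <- tone_rate(site, grid$freq_hz, grid$level_db) * 0.050
  nd <- stats::rpois(nrow(grid), mu)
  td <- round(alpha_times(sum(nd), site$onset_ms, 5), 2)
  id_d <- rep(grid$stimulus_id, nd)
  keep <- td < 100
  ns <- stats::rpois(nrow(grid), site$spont_hz * 0.200)
  ts <- pmin(round(stats::runif(sum(ns), -100, 100), 2), 99.99)
  n <- sum(keep) + sum(ns)
  list(
    stimulus_id = c(id_d[keep], rep(grid$stimulus_id, ns)),
    trial = integer(n),
    t_ms = c(td[keep], ts)
  )
}

# Fixed perceptual/acoustic structure of the synthetic speech responses.
# Onset salience by consonant class, small per-consonant amplitude and
# latency differences (what makes pairs discriminable at 1-ms resolution),
# vowel-identity gains, and presentation-level scaling.
.speech_model <- list(
  class_salience = c(stop = 1.0, affricate = 0.85, fricative = 0.6),
  cons_amp = c(d = 1.0, g = 0.9, t = 0.8, ch = 1.0, j = 0.85,
               f = 1.0, h = 0.85, s = 0.7, sh = 0.6),
  cons_shift_ms = c(d = 0, g = 2.5, t = 5, ch = 0, j = 3,
                    f = 0, h = 2, s = 4, sh = 6),
  vowel_gain = c(a = 1.0, ee = 0.8, oo = 0.65),
  level_factor = c("45" = 0.6, "60" = 1.0, "75" = 1.3),
  onset_scale = 0.020,   # expected onset spikes per unit rmax at weight 1
  vowel_scale = 0.035    # expected vowel spikes per unit rmax at weight 1
)

# Expected onset / vowel spike counts per trial for every speech stimulus at
# one site (vectors aligned with the catalog rows).
speech_expected_counts <- function(site, speech) {
  m <- .speech_model
  x <- log2(site$cf_hz / 1000) / 5          # spectral position in [0, 1]
  onset_w <- 0.5 + x                        # high-CF sites weight the onset
  vowel_w <- 1.5 - x                        # low-CF sites weight the vowel
  lev <- m$level_factor[as.character(speech$level_db)]
  mu_on <- m$onset_scale * site$rmax_hz * site$speech_gain * onset_w *
    m$class_salience[speech$consonant_class] *
    m$cons_amp[speech$initial_consonant] * lev
  mu_vow <- m$vowel_scale * site$rmax_hz * site$speech_gain * vowel_w *
    m$vowel_gain[speech$vowel] * lev
  list(mu_on = unname(mu_on), mu_vow = unname(mu_vow),
       lat = site$onset_ms + site$latency_offset_ms +
         unname(m$cons_shift_ms[speech$initial_consonant]))
}

#' Simulate speech-sound trials for a site
#'
#' `n_repeats` trials per catalog stimulus over the recorded window
#' \[-100, 500) ms.  The driven profile is an onset transient confined to
#' 0-40 ms (alpha kernel at the site's onset latency plus a per-consonant
#' shift, amplitude scaled by consonant-class salience and presentation
#' level) plus a sustained vowel component uniform over 140-440 ms; both are
#' multiplied by the site's `speech_gain` and a CF-dependent spectral weight
#' (high-CF sites emphasise consonant onsets, low-CF sites the vowel).
#' Spontaneous spikes are superimposed throughout.
#'
#' @param site One row of a site table.
#' @param speech Speech catalog data frame from [build_speech_catalog()].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @param n_repeats Trials per stimulus.
#' @return Data frame of events: `stimulus_id`, `trial` (0-based), `t_ms`.
#' @export
simulate_speech_trials <- function(site, speech, seed = NULL,
                                   n_repeats = 20) {
  if (!is.null(seed)) set.seed(seed)
  as.data.frame(sim_speech_core(site, speech, n_repeats))
}

sim_speech_core <- function(site, speech, n_repeats) {
  ex <- speech_expected_counts(site, speech)
  ns <- nrow(speech)
  cells <- ns * n_repeats
  stim <- rep(speech$stimulus_id, each = n_repeats)
  trial <- rep(seq_len(n_repeats) - 1L, times = ns)

  n_on <- stats::rpois(cells, rep(ex$mu_on, each = n_repeats))
  t_on <- round(alpha_times(sum(n_on), rep(rep(ex$lat, each = n_repeats), n_on),
                            3), 2)
  keep <- t_on < 40 & t_on >= 0
  n_vow <- stats::rpois(cells, rep(ex$mu_vow, each = n_repeats))
  t_vow <- pmin(round(stats::runif(sum(n_vow), 140, 440), 2), 439.99)
  n_sp <- stats::rpois(cells, site$spont_hz * 0.600)
  t_sp <- pmin(round(stats::runif(sum(n_sp), -100, 500), 2), 499.99)

  list(
    stimulus_id = c(rep(stim, n_on)[keep], rep(stim, n_vow), rep(stim, n_sp)),
    trial = c(rep(trial, n_on)[keep], rep(trial, n_vow), rep(trial, n_sp)),
    t_ms = c(t_on[keep], t_vow, t_sp)
  )
}

#' Simulate noise-burst-train trials for a site
#'
#' `n_repeats` trials of the 10-Hz train over the recorded window
#' \[-100, 700) ms.  Each burst contributes Poisson-count driven spikes at
#' burst onset + the site's onset latency + Gaussian jitter (SD
#' `site$jitter_ms`); spontaneous activity is superimposed.  Parameters are
#' identical across groups by construction.
#'
#' @param site One row of a site table.
#' @param spec A [build_noise_train_spec()].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @param n_repeats Trials; defaults to the spec's repeat count.
#' @return Data frame of events: `stimulus_id`, `trial` (0-based), `t_ms`.
#' @export
simulate_noise_train_trials <- function(site, spec, seed = NULL,
                                        n_repeats = spec$n_repeats) {
  if (!is.null(seed)) set.seed(seed)
  as.data.frame(sim_noise_core(site, spec, n_repeats))
}

sim_noise_core <- function(site, spec, n_repeats) {
  mu_burst <- 0.012 * site$rmax_hz
  cells <- n_repeats * spec$n_bursts
  trial <- rep(seq_len(n_repeats) - 1L, each = spec$n_bursts)
  onset <- rep(spec$onsets_ms, times = n_repeats)
  nd <- stats::rpois(cells, mu_burst)
  td <- round(rep(onset, nd) + site$onset_ms +
                stats::rnorm(sum(nd), 0, site$jitter_ms), 2)
  keep <- td >= -100 & td < 700
  n_sp <- stats::rpois(n_repeats, site$spont_hz * 0.800)
  t_sp <- pmin(round(stats::runif(sum(n_sp), -100, 700), 2), 699.99)
  list(
    stimulus_id = rep(spec$stimulus_id, sum(keep) + sum(n_sp)),
    trial = c(rep(trial, nd)[keep], rep(seq_len(n_repeats) - 1L, n_sp)),
    t_ms = c(td[keep], t_sp)
  )
}

#' Simulate a complete two-group cohort dataset
#'
#' Draws the site table under the master seed and simulates, per site, the
#' tone sweep, the speech trials and the noise-train trials (selectable via
#' `stimuli` to keep targeted simulations cheap).  Fully deterministic:
#' the same config yields a byte-identical dataset.
#'
#' @param config A [cohort_config()].
#' @param stimuli Which stimulus families to simulate.
#' @param catalog Stimulus catalog (defaults to the canonical one).
#' @return A [spike_dataset()] whose `sites` table carries the recording
#'   metadata and whose `site_models` attribute keeps the full generative
#'   site table (not serialised by [write_dataset()]).
#' @export
simulate_cohort <- function(config = cohort_config(),
                            stimuli = c("tones", "speech", "noise"),
                            catalog = build_stimulus_catalog()) {
  stimuli <- match.arg(stimuli, c("tones", "speech", "noise"),
                       several.ok = TRUE)
  sites <- sample_cohort(config)  # also seeds the stream
  parts <- vector("list", nrow(sites) * 3L)
  n_site <- numeric(nrow(sites))
  k <- 0L
  for (i in seq_len(nrow(sites))) {
    site <- sites[i, ]
    for (fam in stimuli) {
      p <- switch(fam,
                  tones = sim_tone_core(site, catalog$tones),
                  speech = sim_speech_core(site, catalog$speech,
                                           config$n_repeats_speech),
                  noise = sim_noise_core(site, catalog$noise,
                                         config$n_repeats_noise))
      k <- k + 1L
      parts[[k]] <- p
      n_site[i] <- n_site[i] + length(p$t_ms)
    }
  }
  parts <- parts[seq_len(k)]
  events <- data.frame(
    site_id = rep(sites$site_id, n_site),
    stimulus_id = unlist(lapply(parts, `[[`, "stimulus_id"),
                         use.names = FALSE),
    trial = unlist(lapply(parts, `[[`, "trial"), use.names = FALSE),
    t_ms = unlist(lapply(parts, `[[`, "t_ms"), use.names = FALSE)
  )
  io_sites <- as.data.frame(sites)[, c("site_id", "rat_id", "group",
                                       "depth_um", "cf_hz")]
  spike_dataset(events, io_sites, catalog = catalog, site_models = sites)
}
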