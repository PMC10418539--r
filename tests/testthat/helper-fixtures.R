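# Shared fixtures, built once per test run.

.fixtures <- new.env()

# Small two-group cohort (10 sites/group) with all stimulus families.
cohort_fixture <- function() {
  if (is.null(.fixtures$ds)) {
    .fixtures$cfg <- cohort_config(n_rats_per_group = 2, n_sites_per_rat = 5,
                                   seed = 42)
    .fixtures$ds <- simulate_cohort(.fixtures$cfg)
  }
  .fixtures$ds
}

cohort_fixture_config <- function() {
  cohort_fixture()
  .fixtures$cfg
}

# One-row generative site table with explicit parameters.
make_site <- function(cf_hz = 8000, threshold_db = 20, bw10_oct = 1,
                      bw40_oct = 1.6, spont_hz = 20, onset_ms = 8,
                      rmax_hz = 200, speech_gain = 1, latency_offset_ms = 0,
                      jitter_ms = 4, group = "saline", site_id = "s0001",
                      rat_id = "saline_r01", depth_um = 1000) {
  data.frame(site_id = site_id, rat_id = rat_id, group = group,
             depth_um = depth_um, cf_hz = cf_hz, threshold_db = threshold_db,
             bw10_oct = bw10_oct, bw40_oct = bw40_oct, spont_hz = spont_hz,
             onset_ms = onset_ms, rmax_hz = rmax_hz,
             speech_gain = speech_gain,
             latency_offset_ms = latency_offset_ms, jitter_ms = jitter_ms)
}

# Build a spike_dataset from a named list of per-stimulus trial lists
# (each a list of spike-time vectors) for a single site.
make_ds <- function(trials_by_stim, site_id = "s0001", group = "saline",
                    catalog = NULL) {
  rows <- list()
  for (stim in names(trials_by_stim)) {
    trials <- trials_by_stim[[stim]]
    for (i in seq_along(trials)) {
      t <- trials[[i]]
      if (length(t))
        rows[[length(rows) + 1L]] <-
          data.frame(site_id = site_id, stimulus_id = stim,
                     trial = i - 1L, t_ms = t)
      else  # keep trial index occupied via a sentinel-free empty frame
        NULL
    }
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site_id = character(), stimulus_id = character(),
               trial = integer(), t_ms = numeric())
  sites <- data.frame(site_id = site_id, rat_id = paste0(group, "_r01"),
                      group = group, depth_um = 1000)
  spike_dataset(events, sites, catalog = catalog)
}
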