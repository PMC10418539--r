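#' Vector strength of phase locking
#'
#' Resultant length of spike phases on the stimulus cycle:
#' with `theta_i = 2 pi f t_i / 1000`,
#' `VS = sqrt((sum cos theta)^2 + (sum sin theta)^2) / n`.
#' 1 = perfect synchrony, 0 = uniform phases.
#'
#' @param t_ms Spike times in ms.
#' @param f_hz Modulation frequency (Hz), > 0.
#' @return VS in \[0, 1\]; `NA` (with a message) for an empty spike list.
#' @examples
#' vector_strength(c(0, 100, 200), 10)  # 1
#' vector_strength(c(0, 25, 50, 75), 10)  # 0
#' @export
vector_strength <- function(t_ms, f_hz) {
  if (f_hz <= 0) stop("f_hz must be positive")
  n <- length(t_ms)
  if (!n) {
    message("vector_strength: no spikes, returning NA")
    return(NA_real_)
  }
  th <- 2 * pi * f_hz * t_ms / 1000
  sqrt(sum(cos(th))^2 + sum(sin(th))^2) / n
}

#' Noise-burst-train response summary for a site
#'
#' Driven rate per burst (mean per-trial baseline-corrected count over
#' `[0, 600)` ms divided by the 6 bursts), latency of the first response
#' peak (argmax of the smoothed 1-ms pooled PSTH in `[0, 100)` ms), and
#' vector strength at the train rate over all spikes in `[0, 600)` ms
#' (spontaneous spikes included unless `driven_only`).
#'
#' @param ds A [spike_dataset()].
#' @param site_id Site.
#' @param spec A [build_noise_train_spec()].
#' @param driven_only If `TRUE`, the vector strength uses only spikes in the
#'   driven windows `burst onset + [0, 50)` ms instead of the full train.
#' @return One-row data frame: `site_id`, `driven_rate` (spikes/burst),
#'   `first_peak_ms`, `vector_strength`, `n_spikes_analyzed`, `spont_hz`.
#' @export
train_response <- function(ds, site_id, spec = build_noise_train_spec(),
                           driven_only = FALSE) {
  trials <- get_trials(ds, site_id, spec$stimulus_id,
                       n_trials = spec$n_repeats)
  train_response_from_trials(trials, site_id, spec, driven_only)
}

train_response_from_trials <- function(trials, site_id, spec,
                                       driven_only = FALSE) {
  if (!length(trials) || !sum(lengths(trials)))
    stop("site ", site_id, " has no events for stimulus ", spec$stimulus_id)
  spont <- spontaneous_rate(trials)
  dur_s <- spec$n_bursts / spec$rate_hz
  win <- c(0, 1000 * dur_s)
  rate <- driven_spikes(trials, win, spont) / spec$n_bursts
  p <- compute_psth(trials, 1, c(0, 100))
  sm <- smooth_ma(p$rates, 5)
  cand <- which(sm == max(sm))  # flat smoothed maxima: take the rawest peak
  first_peak <- p$t[cand[which.max(p$rates[cand])]] + 0.5
  t_all <- unlist(trials, use.names = FALSE)
  t_vs <- t_all[t_all >= win[1] & t_all < win[2]]
  if (driven_only) {
    period <- 1000 / spec$rate_hz
    t_vs <- t_vs[(t_vs %% period) < 50]
  }
  vs <- vector_strength(t_vs, spec$rate_hz)
  data.frame(site_id = site_id, driven_rate = rate,
             first_peak_ms = first_peak, vector_strength = vs,
             n_spikes_analyzed = length(t_vs), spont_hz = spont)
}

#' Noise-burst-train summary for every site
#'
#' @param ds A [spike_dataset()].
#' @param spec A [build_noise_train_spec()].
#' @param sites Site ids (default: all sites with train events).
#' @return Data frame, one row per site, as [train_response()], plus `group`.
#' @export
train_response_table <- function(ds, spec = build_noise_train_spec(),
                                 sites = NULL) {
  ev <- ds$events[ds$events$stimulus_id == spec$stimulus_id, ]
  if (is.null(sites)) sites <- intersect(ds$sites$site_id, ev$site_id)
  by_site <- split(seq_len(nrow(ev)), factor(ev$site_id, levels = sites))
  out <- do.call(rbind, lapply(sites, function(s) {
    e <- ev[by_site[[s]], ]
    trials <- split(e$t_ms,
                    factor(e$trial, levels = seq_len(spec$n_repeats) - 1L))
    train_response_from_trials(trials, s, spec)
  }))
  out$group <- ds$sites$group[match(out$site_id, ds$sites$site_id)]
  out
}
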