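#' Peri-stimulus time histogram
#'
#' Trial-averaged firing rate in half-open bins `[t, t + bin_ms)` over a
#' window relative to stimulus onset.
#'
#' @param trials List of numeric spike-time vectors (ms), one per trial;
#'   empty trials count in the average.
#' @param bin_ms Bin width (ms); must divide the window length.
#' @param window `c(start, end)` in ms; bins cover `[start, end)`.
#' @return Object of class `psth`: `bin_ms`, `window`, `rates` (spikes/s per
#'   bin), `counts`, `n_trials`, `t` (bin left edges).
#' @examples
#' p <- compute_psth(list(c(0.5), c(0.5)), bin_ms = 1, window = c(0, 2))
#' p$rates  # 1000, 0
#' @export
compute_psth <- function(trials, bin_ms, window) {
  if (!length(trials)) stop("empty trial list")
  len <- diff(window)
  nb <- len / bin_ms
  if (abs(nb - round(nb)) > 1e-9) stop("bin_ms must divide the window length")
  nb <- as.integer(round(nb))
  t <- unlist(trials, use.names = FALSE)
  b <- floor((t - window[1]) / bin_ms) + 1
  counts <- tabulate(b[b >= 1 & b <= nb & t >= window[1] & t < window[2]], nb)
  p <- list(bin_ms = bin_ms, window = window, counts = counts,
            rates = counts / (length(trials) * bin_ms / 1000),
            n_trials = length(trials),
            t = window[1] + (seq_len(nb) - 1) * bin_ms)
  class(p) <- "psth"
  p
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("PSTH: [%g, %g) ms, %g-ms bins, %d trials, peak %.1f spikes/s\n",
              x$window[1], x$window[2], x$bin_ms, x$n_trials, max(x$rates)))
  invisible(x)
}

# Edge-truncated centred moving average (k odd).
smooth_ma <- function(x, k = 5) {
  h <- (k - 1) / 2
  n <- length(x)
  cs <- cumsum(x)
  hi <- pmin(seq_len(n) + h, n)
  lo <- pmax(seq_len(n) - h, 1)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1)
}

#' Spontaneous firing rate from the pre-stimulus baseline
#'
#' @param trials List of spike-time vectors (ms).
#' @param baseline Baseline window, default `[-100, 0)` ms.
#' @return Pooled rate in spikes/s.
#' @export
spontaneous_rate <- function(trials, baseline = c(-100, 0)) {
  dur <- diff(baseline)
  if (dur <= 0) stop("baseline window must have positive length")
  t <- unlist(trials, use.names = FALSE)
  sum(t >= baseline[1] & t < baseline[2]) / (length(trials) * dur / 1000)
}

#' Baseline-corrected driven spikes per presentation
#'
#' Mean spike count per trial inside `window`, minus the count expected from
#' the spontaneous rate over the same duration (set
#' `correction = "none"` for the raw mean count).  May be negative when the
#' evoked count dips below the spontaneous expectation.
#'
#' @param trials List of spike-time vectors (ms).
#' @param window Response window `c(start, end)` ms.
#' @param spont_hz Spontaneous rate (spikes/s).
#' @param correction `"subtract"` (default) or `"none"`.
#' @return Driven spikes per presentation.
#' @export
driven_spikes <- function(trials, window, spont_hz = 0,
                          correction = c("subtract", "none")) {
  correction <- match.arg(correction)
  t <- unlist(trials, use.names = FALSE)
  m <- sum(t >= window[1] & t < window[2]) / length(trials)
  if (correction == "subtract") m <- m - spont_hz * diff(window) / 1000
  m
}

#' First-spike (onset) latency
#'
#' Latency of the first spike after stimulus onset, searched in
#' `(0, search_max_ms]`, summarised across trials by the median (default),
#' mean, or the first supra-zero bin of the pooled PSTH.
#'
#' @param trials List of spike-time vectors (ms).
#' @param search_max_ms Upper bound of the first-spike search.
#' @param method Across-trial summary.
#' @return Latency in ms (`NA` if no trial has a spike in the window).
#' @export
onset_latency <- function(trials, search_max_ms = 100,
                          method = c("median", "mean", "pooled")) {
  method <- match.arg(method)
  if (method == "pooled") {
    t <- unlist(trials, use.names = FALSE)
    t <- t[t > 0 & t <= search_max_ms]
    return(if (length(t)) min(t) else NA_real_)
  }
  first <- vapply(trials, function(t) {
    t <- t[t > 0 & t <= search_max_ms]
    if (length(t)) min(t) else NA_real_
  }, numeric(1))
  if (all(is.na(first))) return(NA_real_)
  if (method == "median") stats::median(first, na.rm = TRUE)
  else mean(first, na.rm = TRUE)
}

#' Peak-response latency from the smoothed 1-ms PSTH
#'
#' Argmax of the 1-ms PSTH after a centred 5-point moving average
#' (edge-truncated); ties resolve to the earliest bin.  Returned as the bin
#' centre.
#'
#' @param trials List of spike-time vectors (ms).
#' @param window Search window, default `[0, 400)` ms.
#' @param smooth_pts Moving-average length (odd).
#' @return Latency in ms.
#' @export
peak_latency <- function(trials, window = c(0, 400), smooth_pts = 5) {
  p <- compute_psth(trials, 1, window)
  sm <- smooth_ma(p$rates, smooth_pts)
  p$t[which.max(sm)] + 0.5
}

#' Per-site, per-stimulus speech response summary
#'
#' For every (site, speech stimulus) present in the dataset: driven spikes
#' per presentation over the full 400-ms sound (`[0, 400)` ms), the 40-ms
#' consonant onset (`[0, 40)`), and the vowel portion (`[140, 440)`); the
#' onset latency (median across trials of each trial's first spike in
#' `(0, 100]` ms) and peak latency (smoothed 1-ms PSTH argmax).  The
#' spontaneous rate is estimated per site from the pooled `[-100, 0)` ms
#' baseline across all of that site's speech trials.
#'
#' Sites lacking a catalog stimulus simply contribute no row for it (a
#' message is emitted).
#'
#' @param ds A [spike_dataset()].
#' @param catalog Stimulus catalog (defaults to the dataset's).
#' @param correction Baseline correction for driven counts.
#' @param latency_method Across-trial onset-latency summary.
#' @return Data frame: `site_id`, `stimulus_id`, `driven_full`,
#'   `driven_onset`, `driven_vowel`, `onset_latency_ms`, `peak_latency_ms`,
#'   `spont_hz`, `n_trials`.
#' @export
speech_response_summary <- function(ds, catalog = ds$catalog,
                                    correction = c("subtract", "none"),
                                    latency_method = "median") {
  correction <- match.arg(correction)
  if (is.null(catalog)) catalog <- build_stimulus_catalog()
  n_rep <- catalog$n_repeats$speech
  ev <- ds$events[ds$events$stimulus_id %in% catalog$speech$stimulus_id, ]
  if (!nrow(ev)) stop("dataset contains no speech events")

  cell_f <- interaction(ev$site_id, ev$stimulus_id, drop = TRUE, sep = "\r")
  cells <- levels(cell_f)
  parts <- do.call(rbind, strsplit(cells, "\r", fixed = TRUE))
  site <- parts[, 1]; stim <- parts[, 2]
  ci <- as.integer(cell_f)
  nc <- length(cells)

  missing <- nrow(ds$sites) * nrow(catalog$speech) - nc
  if (missing > 0)
    message(missing, " site x stimulus combination(s) without events: ",
            "rows omitted")

  count_in <- function(a, b) {
    sel <- ev$t_ms >= a & ev$t_ms < b
    tabulate(ci[sel], nc)
  }
  c_full <- count_in(0, 400)
  c_on <- count_in(0, 40)
  c_vow <- count_in(140, 440)
  c_base <- count_in(-100, 0)

  # per-site spontaneous rate pooled over that site's speech baselines
  n_cells_site <- tapply(rep(1L, nc), site, sum)
  base_site <- tapply(c_base, site, sum)
  spont_site <- base_site / (n_cells_site * n_rep * 0.1)
  spont <- as.numeric(spont_site[site])

  corr <- if (correction == "subtract") 1 else 0
  driven_full <- c_full / n_rep - corr * spont * 0.400
  driven_onset <- c_on / n_rep - corr * spont * 0.040
  driven_vowel <- c_vow / n_rep - corr * spont * 0.300

  # onset latency: first spike per trial in (0, 100], median across trials
  sel <- ev$t_ms > 0 & ev$t_ms <= 100
  o <- order(ci[sel], ev$trial[sel], ev$t_ms[sel])
  ct <- paste(ci[sel][o], ev$trial[sel][o])
  first_t <- ev$t_ms[sel][o][!duplicated(ct)]
  first_cell <- ci[sel][o][!duplicated(ct)]
  lat_fun <- if (latency_method == "mean") mean else stats::median
  onset_lat <- rep(NA_real_, nc)
  lat <- tapply(first_t, factor(first_cell, levels = seq_len(nc)), lat_fun)
  onset_lat[as.integer(names(lat))] <- as.numeric(lat)

  # peak latency: smoothed 1-ms PSTH over [0, 400) per cell
  selp <- ev$t_ms >= 0 & ev$t_ms < 400
  bin <- floor(ev$t_ms[selp]) + 1L
  m <- matrix(tabulate(bin + 400L * (ci[selp] - 1L), 400L * nc), nrow = 400)
  cs <- apply(m, 2, cumsum)
  dim(cs) <- dim(m)
  h <- 2L
  hi <- pmin(seq_len(400L) + h, 400L)
  lo <- pmax(seq_len(400L) - h, 1L)
  sm <- (cs[hi, , drop = FALSE] -
           rbind(0, cs)[lo, , drop = FALSE]) / (hi - lo + 1)
  peak_lat <- (max.col(t(sm), ties.method = "first") - 1) + 0.5

  out <- data.frame(
    site_id = site, stimulus_id = stim,
    driven_full = driven_full, driven_onset = driven_onset,
    driven_vowel = driven_vowel,
    onset_latency_ms = onset_lat, peak_latency_ms = peak_lat,
    spont_hz = spont, n_trials = n_rep
  )
  out <- out[order(out$site_id, out$stimulus_id), ]
  rownames(out) <- NULL
  out
}
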