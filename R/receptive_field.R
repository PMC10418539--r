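#' Build the 81 x 16 tone tuning matrix for a site
#'
#' Evoked spike counts (`[0, 50)` ms after tone onset by default) for every
#' grid condition, arranged frequency x level.  Conditions without spikes
#' hold zero; tone events referencing conditions outside the grid are an
#' error.  The expected baseline count per condition (`spont_expect`) is
#' estimated from the pooled `[-100, 0)` ms pre-stimulus baseline of the
#' whole sweep, scaled to the evoked-window duration.
#'
#' @param ds A [spike_dataset()].
#' @param site_id Site to extract.
#' @param grid Tone grid ([build_tone_grid()]).
#' @param evoked_window Evoked counting window (ms).
#' @return Object of class `tuning_matrix`: `counts` (81 x 16), `freq_hz`,
#'   `level_db`, `evoked_window`, `spont_expect`, `spont_hz`, `site_id`.
#' @export
build_tuning_matrix <- function(ds, site_id, grid = build_tone_grid(),
                                evoked_window = c(0, 50)) {
  ev <- ds$events[ds$events$site_id == site_id &
                    startsWith(ds$events$stimulus_id, "tone_"), ]
  tuning_matrix_from_events(ev, site_id, grid, evoked_window)
}

# Internal: tuning matrix from one site's pre-subset tone events.
tuning_matrix_from_events <- function(ev, site_id, grid, evoked_window) {
  idx <- match(ev$stimulus_id, grid$stimulus_id)
  if (anyNA(idx))
    stop("tone events outside the grid: ",
         paste(unique(ev$stimulus_id[is.na(idx)]), collapse = ", "))
  nf <- length(unique(grid$freq_step))
  nl <- length(unique(grid$level_db))
  sel <- ev$t_ms >= evoked_window[1] & ev$t_ms < evoked_window[2]
  cnt <- tabulate(idx[sel], nrow(grid))
  # grid is frequency-major with level fastest -> fill level-wise then t()
  counts <- t(matrix(cnt, nrow = nl, ncol = nf))
  base <- sum(ev$t_ms >= -100 & ev$t_ms < 0)
  spont_hz <- base / (nrow(grid) * 0.1)
  m <- list(counts = counts,
            freq_hz = unique(grid$freq_hz),
            level_db = sort(unique(grid$level_db)),
            evoked_window = evoked_window,
            spont_expect = spont_hz * diff(evoked_window) / 1000,
            spont_hz = spont_hz,
            site_id = site_id)
  class(m) <- "tuning_matrix"
  m
}

#' @export
print.tuning_matrix <- function(x, ...) {
  cat(sprintf(
    "Tuning matrix %s: %d x %d, %d evoked spikes, spont %.1f Hz\n",
    x$site_id, nrow(x$counts), ncol(x$counts), sum(x$counts), x$spont_hz))
  invisible(x)
}

# 3x3 box filter with edge truncation (mean over the in-bounds neighbourhood).
box3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  s <- matrix(0, nr, nc); n <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    ri <- max(1, 1 + di):min(nr, nr + di)
    rj <- max(1, 1 + dj):min(nc, nc + dj)
    si <- ri - di; sj <- rj - dj
    s[ri, rj] <- s[ri, rj] + m[si, sj]
    n[ri, rj] <- n[ri, rj] + 1
  }
  s / n
}

# Largest 4-connected component of a logical matrix; returns a logical
# matrix (all FALSE if no TRUE cells).  Ties go to the component whose first
# cell comes first in column-major order (deterministic).
largest_component <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  best <- matrix(FALSE, nr, nc); best_n <- 0L
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start]) next
    cur <- cur + 1L
    queue <- start
    comp <- integer(0)
    lab[start] <- cur
    while (length(queue)) {
      cell <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, cell)
      i <- (cell - 1L) %% nr + 1L
      j <- (cell - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          nb <- (jj - 1L) * nr + ii
          if (mask[nb] && !lab[nb]) {
            lab[nb] <- cur
            queue <- c(queue, nb)
          }
        }
      }
    }
    if (length(comp) > best_n) {
      best_n <- length(comp)
      best[] <- FALSE
      best[comp] <- TRUE
    }
  }
  best
}

#' Extract receptive-field properties from a tuning matrix
#'
#' The extraction procedure: (1) smooth the count matrix with an
#' edge-truncated 3 x 3 box filter; (2) mark a cell responsive when its
#' smoothed count exceeds `spont_expect + criterion_k * sqrt(spont_expect +
#' 0.25)` (a variance-stabilised Poisson criterion); (3) keep the largest
#' 4-connected responsive component; (4) response threshold = lowest level
#' in the component, CF = frequency of the responsive cell at that level
#' (ties: median frequency index, lower of two middles); (5) BW10/BW40 =
#' octave span of component cells at threshold + 10 / + 40 dB (`NA` when
#' that level exceeds the 75-dB grid ceiling or the component has no cell
#' there); (6) the site is non-responsive when the component covers fewer
#' than `min_component` cells, in which case all tuning fields are `NA`.
#'
#' @param m A [build_tuning_matrix()].
#' @param criterion_k Criterion multiplier (default 2).
#' @param min_component Minimum component size (cells).
#' @return Object of class `receptive_field` with fields `site_id`,
#'   `responsive`, `cf_hz`, `threshold_db`, `bw10_oct`, `bw40_oct`,
#'   `spont_hz`, `n_component`, and the logical `component` matrix.
#' @export
extract_receptive_field <- function(m, criterion_k = 2, min_component = 5) {
  stopifnot(inherits(m, "tuning_matrix"))
  sm <- box3(m$counts)
  crit <- m$spont_expect + criterion_k * sqrt(m$spont_expect + 0.25)
  comp <- largest_component(sm > crit)
  rf <- list(site_id = m$site_id, responsive = FALSE,
             cf_hz = NA_real_, threshold_db = NA_real_,
             bw10_oct = NA_real_, bw40_oct = NA_real_,
             spont_hz = m$spont_hz, n_component = sum(comp),
             component = comp)
  class(rf) <- "receptive_field"
  if (sum(comp) < min_component) return(rf)
  rf$responsive <- TRUE
  lev_idx <- which(colSums(comp) > 0)
  thr_col <- lev_idx[1]
  rf$threshold_db <- m$level_db[thr_col]
  fidx <- which(comp[, thr_col])
  rf$cf_hz <- m$freq_hz[fidx[(length(fidx) + 1L) %/% 2L]]
  span_at <- function(level) {
    if (level > max(m$level_db)) return(NA_real_)
    col <- match(level, m$level_db)
    f <- which(comp[, col])
    if (!length(f)) return(NA_real_)
    (max(f) - min(f)) * 0.0625
  }
  rf$bw10_oct <- span_at(rf$threshold_db + 10)
  rf$bw40_oct <- span_at(rf$threshold_db + 40)
  rf
}

#' @export
print.receptive_field <- function(x, ...) {
  if (!x$responsive) {
    cat(sprintf("Receptive field %s: non-responsive (%d cells)\n",
                x$site_id, x$n_component))
  } else {
    cat(sprintf(
      "Receptive field %s: CF %.0f Hz, threshold %g dB, BW10 %s, BW40 %s oct, spont %.1f Hz\n",
      x$site_id, x$cf_hz, x$threshold_db,
      format(x$bw10_oct), format(x$bw40_oct), x$spont_hz))
  }
  invisible(x)
}

#' Tone-response latencies for a responsive site
#'
#' Pools spikes from all conditions in the receptive-field component into a
#' 1-ms PSTH over `[-100, 100)` ms, smooths it (5-point moving average) and
#' reads off: onset latency = first post-onset bin exceeding the baseline
#' mean + 3 SD of the smoothed baseline bins; peak latency = argmax from the
#' onset on; end of peak = first bin after the peak falling below halfway
#' between baseline and peak.  Bin centres are returned.
#'
#' @param ds A [spike_dataset()].
#' @param site_id Site.
#' @param rf Its [extract_receptive_field()] (must be responsive).
#' @param grid Tone grid.
#' @return Named numeric: `onset_ms`, `peak_ms`, `end_of_peak_ms` (the
#'   latter two `NA` if the onset criterion is never crossed).
#' @export
tone_latencies <- function(ds, site_id, rf, grid = build_tone_grid()) {
  ev <- ds$events[ds$events$site_id == site_id &
                    startsWith(ds$events$stimulus_id, "tone_"), ]
  tone_latencies_from_events(ev, site_id, rf, grid)
}

tone_latencies_from_events <- function(ev, site_id, rf, grid) {
  stopifnot(inherits(rf, "receptive_field"))
  if (!rf$responsive) stop("site ", site_id, " is not responsive")
  nf <- nrow(rf$component)
  cond <- which(rf$component)  # column-major: freq fast within level
  fi <- (cond - 1L) %% nf + 1L
  li <- (cond - 1L) %/% nf + 1L
  ids <- grid$stimulus_id[(fi - 1L) * 16L + li]
  ev <- ev[ev$stimulus_id %in% ids, ]
  p <- compute_psth(split(ev$t_ms, factor(ev$stimulus_id, levels = ids)),
                    1, c(-100, 100))
  sm <- smooth_ma(p$rates, 5)
  base <- sm[p$t < 0]
  crit <- mean(base) + 3 * stats::sd(base)
  post <- which(p$t >= 0)
  on_i <- post[which(sm[post] > crit)[1]]
  if (is.na(on_i))
    return(c(onset_ms = NA_real_, peak_ms = NA_real_,
             end_of_peak_ms = NA_real_))
  pk_rel <- which.max(sm[on_i:length(sm)])
  pk_i <- on_i + pk_rel - 1L
  half <- mean(base) + 0.5 * (sm[pk_i] - mean(base))
  after <- which(sm > -Inf & seq_along(sm) > pk_i & sm < half)[1]
  c(onset_ms = p$t[on_i] + 0.5, peak_ms = p$t[pk_i] + 0.5,
    end_of_peak_ms = if (is.na(after)) NA_real_ else p$t[after] + 0.5)
}

#' Mean evoked spikes per tone in one-octave frequency bins
#'
#' Bins the 81 grid frequencies into \[1-2), \[2-4), \[4-8), \[8-16),
#' \[16-32\] kHz (16 + 16 + 16 + 16 + 17 frequencies) and averages the
#' evoked-window spike count per tone within each bin.
#'
#' @param m A [build_tuning_matrix()].
#' @return Named numeric of length 5.
#' @export
octave_binned_rates <- function(m) {
  k <- seq_len(nrow(m$counts)) - 1L
  bin <- pmin(k %/% 16L, 4L)
  v <- tapply(rowMeans(m$counts), bin, mean)
  stats::setNames(as.numeric(v),
                  c("1-2 kHz", "2-4 kHz", "4-8 kHz", "8-16 kHz", "16-32 kHz"))
}

#' Rate-intensity function
#'
#' Mean evoked spikes per tone at each of the 16 levels, averaged over all
#' 81 frequencies.
#'
#' @param m A [build_tuning_matrix()].
#' @return Named numeric of length 16 (names are levels in dB).
#' @export
rate_intensity_function <- function(m) {
  stats::setNames(colMeans(m$counts), m$level_db)
}

#' CF band assignment for classifier reporting
#'
#' Low band = CF in 1-8 kHz (inclusive at 8 kHz), high band = above 8 kHz;
#' `NA` CF (non-responsive site) is `"unassigned"`.
#'
#' @param cf_hz Characteristic frequencies (Hz), vectorised.
#' @return Character vector in `{"low", "high", "unassigned"}`.
#' @export
cf_band <- function(cf_hz) {
  out <- ifelse(is.na(cf_hz), "unassigned",
                ifelse(cf_hz <= 8000, "low", "high"))
  as.character(out)
}

#' Receptive-field table for every site
#'
#' Runs [build_tuning_matrix()] + [extract_receptive_field()] (and, for
#' responsive sites, [tone_latencies()]) over the dataset's sites.  Also
#' reports the mean baseline-corrected evoked count per tone
#' (`tone_driven`), the summary used for tone-response group comparisons.
#'
#' @param ds A [spike_dataset()].
#' @param grid Tone grid.
#' @param sites Site ids (default: all).
#' @param latencies Compute pooled-PSTH latencies too (slower).
#' @return Data frame, one row per site: `site_id`, `group`, `responsive`,
#'   `cf_hz`, `cf_band`, `threshold_db`, `bw10_oct`, `bw40_oct`,
#'   `onset_ms`, `peak_ms`, `end_of_peak_ms`, `spont_hz`, `tone_driven`.
#' @export
rf_table <- function(ds, grid = build_tone_grid(), sites = ds$sites$site_id,
                     latencies = TRUE) {
  tone_ev <- ds$events[startsWith(ds$events$stimulus_id, "tone_"), ]
  by_site <- split(seq_len(nrow(tone_ev)),
                   factor(tone_ev$site_id, levels = sites))
  rows <- lapply(sites, function(s) {
    ev <- tone_ev[by_site[[s]], ]
    m <- tuning_matrix_from_events(ev, s, grid, c(0, 50))
    rf <- extract_receptive_field(m)
    lat <- c(onset_ms = NA_real_, peak_ms = NA_real_,
             end_of_peak_ms = NA_real_)
    if (latencies && rf$responsive)
      lat <- tone_latencies_from_events(ev, s, rf, grid)
    data.frame(site_id = s, responsive = rf$responsive, cf_hz = rf$cf_hz,
               cf_band = cf_band(rf$cf_hz), threshold_db = rf$threshold_db,
               bw10_oct = rf$bw10_oct, bw40_oct = rf$bw40_oct,
               onset_ms = lat[["onset_ms"]], peak_ms = lat[["peak_ms"]],
               end_of_peak_ms = lat[["end_of_peak_ms"]],
               spont_hz = rf$spont_hz,
               tone_driven = mean(m$counts) - m$spont_expect)
  })
  out <- do.call(rbind, rows)
  out$group <- ds$sites$group[match(out$site_id, ds$sites$site_id)]
  out[, c("site_id", "group", setdiff(names(out), c("site_id", "group")))]
}
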