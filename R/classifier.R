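#' Classifier binning schemes
#'
#' The consonant scheme bins the 40-ms onset response at 1-ms precision
#' (40 bins over `[0, 40)` ms); the vowel scheme uses a single 300-ms bin
#' over the vowel portion (`[140, 440)` ms).
#'
#' @param name `"consonant"` or `"vowel"`.
#' @return Object of class `binning_scheme`: `name`, `window`, `bin_ms`,
#'   `n_bins`.
#' @export
binning_scheme <- function(name = c("consonant", "vowel")) {
  name <- match.arg(name)
  s <- switch(name,
              consonant = list(name = "consonant", window = c(0, 40),
                               bin_ms = 1, n_bins = 40L),
              vowel = list(name = "vowel", window = c(140, 440),
                           bin_ms = 300, n_bins = 1L))
  class(s) <- "binning_scheme"
  s
}

#' Bin one trial's spike train under a scheme
#'
#' Half-open bins `[t, t + bin)`; spikes outside the scheme window are
#' ignored.
#'
#' @param spikes Numeric spike times (ms).
#' @param scheme A [binning_scheme()].
#' @return Integer count vector of length `scheme$n_bins`.
#' @export
bin_trial <- function(spikes, scheme) {
  b <- floor((spikes - scheme$window[1]) / scheme$bin_ms) + 1
  keep <- spikes >= scheme$window[1] & spikes < scheme$window[2]
  tabulate(b[keep], scheme$n_bins)
}

#' Leave-one-out nearest-neighbor classification of a sound pair
#'
#' Each single trial is held out in turn and assigned to the sound whose
#' PSTH template it is closest to in Euclidean distance on the binned count
#' vectors.  The held-out sound's template is the per-bin mean of its
#' remaining trials (the "remaining 19 repeats" at 20 trials); the competing
#' sound's template is the mean of all of its trials
#' (`template = "symmetric"` drops one matched trial from the competitor
#' instead).  Exact distance ties are broken by a seeded fair coin, which
#' preserves the 2.5%-step accuracy lattice at 20 repeats per sound.
#'
#' @param trials_a,trials_b Lists of spike-time vectors, one per trial
#'   (>= 2 trials each).
#' @param scheme A [binning_scheme()].
#' @param seed Optional seed for tie coins; `NULL` uses the current stream.
#' @param template `"heldout_vs_all"` (default) or `"symmetric"`.
#' @return Object of class `pair_accuracy`: `accuracy_pct`,
#'   `n_trials_classified`, `n_correct`, `n_ties`, `scheme`.
#' @export
classify_pair <- function(trials_a, trials_b, scheme,
                          seed = NULL,
                          template = c("heldout_vs_all", "symmetric")) {
  template <- match.arg(template)
  if (length(trials_a) < 2 || length(trials_b) < 2)
    stop("need at least 2 trials per sound")
  if (!is.null(seed)) set.seed(seed)
  Xa <- vapply(trials_a, bin_trial, numeric(scheme$n_bins), scheme = scheme)
  Xb <- vapply(trials_b, bin_trial, numeric(scheme$n_bins), scheme = scheme)
  dim(Xa) <- c(scheme$n_bins, length(trials_a))
  dim(Xb) <- c(scheme$n_bins, length(trials_b))
  run_side <- function(X_own, X_other) {
    n <- ncol(X_own)
    s_own <- rowSums(X_own)
    t_other_all <- rowMeans(X_other)
    correct <- 0L; ties <- 0L
    for (i in seq_len(n)) {
      x <- X_own[, i]
      t_own <- (s_own - x) / (n - 1)
      t_other <- if (template == "symmetric") {
        j <- ((i - 1L) %% ncol(X_other)) + 1L
        (rowSums(X_other) - X_other[, j]) / (ncol(X_other) - 1)
      } else t_other_all
      d_own <- sum((x - t_own)^2)
      d_other <- sum((x - t_other)^2)
      if (d_own < d_other) correct <- correct + 1L
      else if (d_own == d_other) {
        ties <- ties + 1L
        correct <- correct + stats::rbinom(1, 1, 0.5)
      }
    }
    c(correct, ties)
  }
  ra <- run_side(Xa, Xb)
  rb <- run_side(Xb, Xa)
  n_tot <- length(trials_a) + length(trials_b)
  res <- list(accuracy_pct = 100 * (ra[1] + rb[1]) / n_tot,
              n_trials_classified = n_tot,
              n_correct = ra[1] + rb[1],
              n_ties = ra[2] + rb[2],
              scheme = scheme$name)
  class(res) <- "pair_accuracy"
  res
}

#' @export
print.pair_accuracy <- function(x, ...) {
  cat(sprintf("Pair accuracy: %.1f%% (%d/%d correct, %d tie(s), %s scheme)\n",
              x$accuracy_pct, x$n_correct, x$n_trials_classified, x$n_ties,
              x$scheme))
  invisible(x)
}

#' Run the pair classifier across sites and pair sets
#'
#' Classifies every pair in every [pair_sets()] entry for every site,
#' using the consonant scheme for consonant sets and the vowel scheme for
#' the vowel set, and attaches each site's CF band (from `rf`, a
#' [rf_table()] or any data frame with `site_id` and `cf_hz`).  Pairs whose
#' stimuli are absent at a site are skipped with a message.
#'
#' @param ds A [spike_dataset()].
#' @param catalog Stimulus catalog (defaults to the dataset's).
#' @param sets Pair sets ([pair_sets()]).
#' @param rf Optional CF source for band labels.
#' @param seed Optional seed for tie coins.
#' @param sites Site ids (default: all).
#' @return Data frame: `site_id`, `group`, `set`, `pair`, `scheme`,
#'   `accuracy_pct`, `n_trials_classified`, `n_ties`, `cf_band`.
#' @export
classify_all <- function(ds, catalog = ds$catalog, sets = pair_sets(),
                         rf = NULL, seed = NULL, sites = ds$sites$site_id) {
  if (is.null(catalog)) catalog <- build_stimulus_catalog()
  if (!is.null(seed)) set.seed(seed)
  n_rep <- catalog$n_repeats$speech
  need <- unique(unlist(lapply(sets, function(s) as.vector(s$pairs))))
  ev <- ds$events[ds$events$stimulus_id %in% need &
                    ds$events$site_id %in% sites, ]
  key <- interaction(ev$site_id, ev$stimulus_id, drop = TRUE, sep = "\r")
  tr_lists <- split(seq_len(nrow(ev)), key)
  trials_of <- function(site, stim) {
    k <- paste(site, stim, sep = "\r")
    idx <- tr_lists[[k]]
    if (is.null(idx)) return(NULL)
    split(ev$t_ms[idx], factor(ev$trial[idx], levels = seq_len(n_rep) - 1L))
  }
  bands <- if (!is.null(rf))
    stats::setNames(cf_band(rf$cf_hz), rf$site_id) else NULL
  schemes <- list(consonant = binning_scheme("consonant"),
                  vowel = binning_scheme("vowel"))
  out <- list()
  n_skipped <- 0L
  for (site in sites) {
    for (set in sets) {
      sch <- schemes[[set$scheme]]
      for (r in seq_len(nrow(set$pairs))) {
        a <- set$pairs[r, 1]; b <- set$pairs[r, 2]
        ta <- trials_of(site, a); tb <- trials_of(site, b)
        if (is.null(ta) || is.null(tb)) {
          n_skipped <- n_skipped + 1L
          next
        }
        acc <- classify_pair(ta, tb, sch)
        out[[length(out) + 1L]] <- data.frame(
          site_id = site, set = set$name, pair = paste(a, b, sep = "|"),
          scheme = set$scheme, accuracy_pct = acc$accuracy_pct,
          n_trials_classified = acc$n_trials_classified,
          n_ties = acc$n_ties,
          cf_band = if (is.null(bands)) "unassigned"
                    else unname(bands[site]) %||% "unassigned"
        )
      }
    }
  }
  if (n_skipped)
    message(n_skipped, " pair(s) skipped for missing stimuli")
  res <- do.call(rbind, out)
  res$group <- ds$sites$group[match(res$site_id, ds$sites$site_id)]
  res$cf_band[is.na(res$cf_band)] <- "unassigned"
  res[, c("site_id", "group", "set", "pair", "scheme", "accuracy_pct",
          "n_trials_classified", "n_ties", "cf_band")]
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a
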