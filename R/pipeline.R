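#' Run the full analysis pipeline
#'
#' End-to-end orchestration: simulate (or accept) a spike dataset, then
#' compute the per-site metric tables — speech responses, receptive fields,
#' noise-train responses, classifier pair accuracies — and the group
#' comparisons: speech driven rates (full / onset / vowel windows) and
#' onset latency, the tone driven rate, the train driven rate, first-peak
#' latency and vector strength, and the median classifier accuracy per pair
#' set (stop-consonant accuracy additionally split by CF band).  Fully
#' deterministic under the config seed.
#'
#' @param config A [cohort_config()]; ignored when `ds` is supplied.
#' @param ds Optional existing [spike_dataset()].
#' @param sets Classifier pair sets.
#' @param n_boot Bootstrap resamples for median CIs.
#' @param ci Compute bootstrap CIs for group medians.
#' @param out_dir Optional directory; when given the metric tables are
#'   written as CSV and the comparison summary as JSON via [write_report()].
#' @return Object of class `ic_report`: `tables` (speech, rf, train, pairs),
#'   `comparisons` (list of [compare_metric()] results), `config`,
#'   `n_sites`.
#' @export
run_pipeline <- function(config = cohort_config(), ds = NULL,
                         sets = pair_sets(), n_boot = 50000, ci = TRUE,
                         out_dir = NULL) {
  if (is.null(ds)) ds <- simulate_cohort(config)
  catalog <- ds$catalog
  if (is.null(catalog)) catalog <- build_stimulus_catalog()
  issues <- validate_dataset(ds, catalog)
  if (any(issues$level == "error"))
    stop("dataset failed validation:\n",
         paste(issues$message[issues$level == "error"], collapse = "\n"))

  speech <- speech_response_summary(ds, catalog)
  rf <- rf_table(ds)
  train <- train_response_table(ds, catalog$noise)
  pairs <- classify_all(ds, catalog, sets, rf = rf,
                        seed = config$seed + 1L)

  grp <- ds$sites$group[match(ds$sites$site_id, ds$sites$site_id)]
  names(grp) <- ds$sites$site_id
  site_mean <- function(df, value, subset = TRUE) {
    d <- df[subset, ]
    v <- tapply(d[[value]], d$site_id, mean, na.rm = TRUE)
    data.frame(site_id = names(v), value = as.numeric(v),
               group = unname(grp[names(v)]))
  }
  cmp <- function(tab, metric)
    compare_metric(tab$value, tab$group, metric, n_boot = n_boot, ci = ci)

  sp60 <- speech$stimulus_id %in%
    catalog$speech$stimulus_id[catalog$speech$level_db == 60]
  comparisons <- list(
    speech_driven_full = cmp(site_mean(speech, "driven_full", sp60),
                             "speech driven spikes, 0-400 ms"),
    speech_driven_onset = cmp(site_mean(speech, "driven_onset", sp60),
                              "speech driven spikes, consonant 0-40 ms"),
    speech_driven_vowel = cmp(site_mean(speech, "driven_vowel", sp60),
                              "speech driven spikes, vowel 140-440 ms"),
    speech_onset_latency = cmp(site_mean(speech, "onset_latency_ms", sp60),
                               "speech onset latency (ms)"),
    tone_driven = cmp(site_mean(rf, "tone_driven"),
                      "tone driven spikes per condition"),
    train_driven_rate = cmp(site_mean(train, "driven_rate"),
                            "noise-train driven spikes per burst"),
    train_first_peak = cmp(site_mean(train, "first_peak_ms"),
                           "noise-train first-peak latency (ms)"),
    train_vector_strength = cmp(site_mean(train, "vector_strength"),
                                "noise-train vector strength")
  )
  for (set in unique(pairs$set)) {
    comparisons[[paste0("classifier_", set)]] <-
      cmp(site_mean(pairs, "accuracy_pct", pairs$set == set),
          sprintf("classifier accuracy, %s (%%)", set))
  }
  if ("stops" %in% pairs$set) {
    for (band in c("low", "high")) {
      sub <- pairs$set == "stops" & pairs$cf_band == band
      if (sum(sub))
        comparisons[[paste0("classifier_stops_", band)]] <-
          cmp(site_mean(pairs, "accuracy_pct", sub),
              sprintf("classifier accuracy, stops, %s-CF sites (%%)", band))
    }
  }

  report <- list(tables = list(speech = speech, rf = rf, train = train,
                               pairs = pairs),
                 comparisons = comparisons, config = config,
                 n_sites = nrow(ds$sites))
  class(report) <- "ic_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.ic_report <- function(x, ...) {
  cat(sprintf("IC analysis report: %d sites\n", x$n_sites))
  cat("Group comparisons (", x$comparisons[[1]]$groups[1], " vs ",
      x$comparisons[[1]]$groups[2], "):\n", sep = "")
  for (cmp in x$comparisons) print(cmp)
  invisible(x)
}

#' @export
summary.ic_report <- function(object, ...) {
  rows <- lapply(names(object$comparisons), function(nm) {
    c <- object$comparisons[[nm]]
    data.frame(comparison = nm, metric = c$metric,
               n_saline = c$n[1], n_vpa = c$n[2],
               median_saline = c$median[1], median_vpa = c$median[2],
               test = c$test, statistic = c$statistic, p_value = c$p_value,
               direction = c$direction)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a pipeline report bundle to disk
#'
#' Per-site metric tables as CSV (`speech.csv`, `rf.csv`, `train.csv`,
#' `pairs.csv`) and the group-comparison summary as versioned JSON
#' (`summary.json`).
#'
#' @param report An [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ic_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$tables))
    utils::write.csv(report$tables[[nm]],
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  summ <- list(schema = "icspike-report-1",
               n_sites = report$n_sites,
               comparisons = lapply(report$comparisons, function(c)
                 list(metric = c$metric, groups = c$groups, n = c$n,
                      median = c$median,
                      ci95 = lapply(c$ci95, as.numeric),
                      test = c$test, statistic = c$statistic,
                      p_value = c$p_value, direction = c$direction)))
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
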