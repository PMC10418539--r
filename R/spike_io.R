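#' Spike-event dataset
#'
#' Container for multi-unit spike events and site metadata.  `events` holds
#' one row per spike with times in ms relative to stimulus onset (stored at
#' 0.01-ms resolution); `sites` holds one row per recording site.  Events
#' are kept in the canonical sort order (site, stimulus, trial, time) so
#' identical datasets serialise byte-identically.
#'
#' @param events Data frame: `site_id`, `stimulus_id`, `trial` (0-based
#'   integer), `t_ms`.
#' @param sites Data frame: `site_id`, `rat_id`, `group` (`"saline"` or
#'   `"vpa"`), `depth_um`, optionally `cf_hz`.
#' @param catalog Optional [build_stimulus_catalog()].
#' @param site_models Optional generative site table (synthetic cohorts).
#' @return Object of class `spike_dataset`.
#' @export
spike_dataset <- function(events, sites, catalog = NULL, site_models = NULL) {
  need_e <- c("site_id", "stimulus_id", "trial", "t_ms")
  need_s <- c("site_id", "rat_id", "group", "depth_um")
  if (!all(need_e %in% names(events)))
    stop("events must have columns: ", paste(need_e, collapse = ", "))
  if (!all(need_s %in% names(sites)))
    stop("sites must have columns: ", paste(need_s, collapse = ", "))
  events$site_id <- as.character(events$site_id)
  events$stimulus_id <- as.character(events$stimulus_id)
  events$trial <- as.integer(events$trial)
  events$t_ms <- round(as.numeric(events$t_ms), 2)
  sites$site_id <- as.character(sites$site_id)
  bad <- setdiff(unique(events$site_id), sites$site_id)
  if (length(bad))
    stop("events reference unknown site(s): ", paste(bad, collapse = ", "))
  bad_g <- setdiff(unique(sites$group), c("saline", "vpa"))
  if (length(bad_g))
    stop("unknown group label(s): ", paste(bad_g, collapse = ", "))
  o <- order(events$site_id, events$stimulus_id, events$trial, events$t_ms,
             method = "radix")
  events <- events[o, need_e, drop = FALSE]
  rownames(events) <- NULL
  sites <- sites[order(sites$site_id), , drop = FALSE]
  rownames(sites) <- NULL
  ds <- list(events = events, sites = sites, catalog = catalog,
             site_models = site_models)
  class(ds) <- "spike_dataset"
  ds
}

#' @export
print.spike_dataset <- function(x, ...) {
  ng <- table(x$sites$group)
  cat(sprintf("Spike dataset: %d events, %d sites (%s), %d stimuli\n",
              nrow(x$events), nrow(x$sites),
              paste(sprintf("%s %d", names(ng), ng), collapse = ", "),
              length(unique(x$events$stimulus_id))))
  invisible(x)
}

.events_header <- "# icspike events v1"
.sites_header <- "# icspike sites v1"

#' Write / read a spike dataset as delimited text
#'
#' Writes `events.csv` and `sites.csv` (schema-versioned, '#'-commented
#' header line) plus `catalog.yaml` when a catalog is attached.  Because
#' events are canonically sorted and times quantised to 0.01 ms, writing the
#' same dataset twice yields byte-identical files, and
#' `read_dataset(write_dataset(ds))` reproduces `ds` exactly.
#'
#' @param ds A [spike_dataset()].
#' @param dir Directory to write into (created if needed).
#' @return `dir`, invisibly (write); the dataset (read).
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "spike_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, path, header) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  }
  ev <- ds$events
  ev$t_ms <- sprintf("%.2f", ev$t_ms)
  wr(ev, file.path(dir, "events.csv"), .events_header)
  wr(ds$sites, file.path(dir, "sites.csv"), .sites_header)
  if (!is.null(ds$catalog))
    write_catalog(ds$catalog, file.path(dir, "catalog.yaml"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  ep <- file.path(dir, "events.csv")
  sp <- file.path(dir, "sites.csv")
  if (!file.exists(ep) || !file.exists(sp))
    stop("dataset directory must contain events.csv and sites.csv")
  chk <- function(path, header) {
    if (!identical(readLines(path, n = 1), header))
      stop(basename(path), ": unrecognised schema header")
  }
  chk(ep, .events_header); chk(sp, .sites_header)
  events <- utils::read.csv(ep, comment.char = "#",
                            colClasses = c(site_id = "character",
                                           stimulus_id = "character",
                                           trial = "integer",
                                           t_ms = "numeric"))
  sites <- utils::read.csv(sp, comment.char = "#",
                           colClasses = c(site_id = "character"))
  cp <- file.path(dir, "catalog.yaml")
  catalog <- if (file.exists(cp)) read_catalog(cp) else NULL
  spike_dataset(events, sites, catalog = catalog)
}

#' Validate a spike dataset
#'
#' Report-based checks of the dataset invariants: known site references,
#' legal group labels, non-negative trial indices, spike times inside the
#' recorded window of each stimulus family, and (warning-level) per-stimulus
#' speech repeat counts different from the expected 20.
#'
#' @param ds A [spike_dataset()].
#' @param catalog Catalog used for windows/repeats; defaults to the one
#'   attached to `ds`.
#' @return Data frame of class `validation_report` with columns `level`
#'   (`"error"`/`"warning"`), `check`, `message`; zero rows when clean.
#' @export
validate_dataset <- function(ds, catalog = ds$catalog) {
  stopifnot(inherits(ds, "spike_dataset"))
  issues <- list()
  add <- function(level, check, message)
    issues[[length(issues) + 1L]] <<- data.frame(level = level, check = check,
                                                 message = message)
  bad <- setdiff(unique(ds$events$site_id), ds$sites$site_id)
  if (length(bad))
    add("error", "site_ref", paste("events reference unknown site(s):",
                                   paste(bad, collapse = ", ")))
  bad_g <- setdiff(unique(ds$sites$group), c("saline", "vpa"))
  if (length(bad_g))
    add("error", "group_label", paste("unknown group label(s):",
                                      paste(bad_g, collapse = ", ")))
  if (any(ds$events$trial < 0))
    add("error", "trial_index", "negative trial indices present")
  if (!is.null(catalog)) {
    w <- window_for(catalog, ds$events$stimulus_id)
    out <- ds$events$t_ms < w[, "start"] | ds$events$t_ms >= w[, "end"]
    if (any(out))
      add("error", "window",
          sprintf("%d event(s) outside the recorded window (e.g. %s t=%g ms)",
                  sum(out), ds$events$stimulus_id[which(out)[1]],
                  ds$events$t_ms[which(out)[1]]))
    sp_ids <- catalog$speech$stimulus_id
    ev <- ds$events[ds$events$stimulus_id %in% sp_ids, ]
    if (nrow(ev)) {
      n_obs <- tapply(ev$trial, list(ev$site_id, ev$stimulus_id),
                      function(tr) max(tr) + 1L)
      low <- which(!is.na(n_obs) & n_obs != catalog$n_repeats$speech,
                   arr.ind = TRUE)
      for (j in seq_len(nrow(low)))
        add("warning", "repeat_count",
            sprintf("site %s stimulus %s: %d observed repeats (expected %d)",
                    rownames(n_obs)[low[j, 1]], colnames(n_obs)[low[j, 2]],
                    n_obs[low[j, , drop = FALSE]], catalog$n_repeats$speech))
    }
  }
  rep <- if (length(issues)) do.call(rbind, issues) else
    data.frame(level = character(), check = character(),
               message = character())
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("Dataset valid: no issues found\n")
  } else {
    cat(sprintf("Dataset validation: %d error(s), %d warning(s)\n",
                sum(x$level == "error"), sum(x$level == "warning")))
    for (i in seq_len(nrow(x)))
      cat(sprintf("  [%s] %s: %s\n", x$level[i], x$check[i], x$message[i]))
  }
  invisible(x)
}

# Spike-time list (one numeric vector per trial, empty trials included) for
# one site x stimulus.  n_trials fixes the list length so trailing silent
# trials are represented.
get_trials <- function(ds, site_id, stimulus_id, n_trials = NULL) {
  ev <- ds$events[ds$events$site_id == site_id &
                    ds$events$stimulus_id == stimulus_id, ]
  if (is.null(n_trials))
    n_trials <- if (nrow(ev)) max(ev$trial) + 1L else 0L
  split(ev$t_ms, factor(ev$trial, levels = seq_len(n_trials) - 1L))
}
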