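#' Build the tone frequency x intensity grid
#'
#' Enumerates the full tone search grid used for receptive-field mapping:
#' 81 frequencies from 1 to 32 kHz in 0.0625-octave steps crossed with 16
#' intensities from 0 to 75 dB SPL in 5-dB steps, i.e. 1,296 conditions.
#' Each condition is presented once per site (a single sweep).
#'
#' @return A data frame with one row per condition, ordered by
#'   (frequency, level): `index` (1..1296), `freq_step` (0..80, octave step
#'   index from 1 kHz), `freq_hz`, `level_db`, and `stimulus_id`
#'   (`"tone_0001"` ...).
#' @examples
#' grid <- build_tone_grid()
#' nrow(grid)            # 1296
#' range(grid$freq_hz)   # 1000 ... 32000
#' @export
build_tone_grid <- function() {
  k <- 0:80
  freq <- 1000 * 2^(0.0625 * k)
  level <- seq(0, 75, by = 5)
  grid <- data.frame(
    index = seq_len(length(k) * length(level)),
    freq_step = rep(k, each = length(level)),
    freq_hz = rep(freq, each = length(level)),
    level_db = rep(level, times = length(k))
  )
  grid$stimulus_id <- sprintf("tone_%04d", grid$index)
  grid
}

#' Build the speech-sound catalog
#'
#' The speech battery is 15 consonant-vowel-consonant presentations: 11 words
#' ('chad', 'dad', 'deed', 'dood', 'fad', 'gad', 'had', 'jad', 'sad', 'shad',
#' 'tad') at 60 dB SPL, plus 'dad' and 'shad' additionally at 45 and 75 dB.
#' Words differ in the initial consonant (classed by manner of articulation:
#' stops d/g/t, affricates ch/j, fricatives f/h/s/sh) or in the vowel
#' (-ad / -eed / -ood).
#'
#' @return Data frame with columns `word`, `initial_consonant`,
#'   `consonant_class`, `vowel`, `level_db`, `stimulus_id` (`"<word>_<dB>"`).
#' @export
build_speech_catalog <- function() {
  words <- c("chad", "dad", "deed", "dood", "fad", "gad",
             "had", "jad", "sad", "shad", "tad")
  onset_of <- function(w) {
    if (startsWith(w, "ch")) "ch" else if (startsWith(w, "sh")) "sh"
    else substr(w, 1, 1)
  }
  class_of <- c(d = "stop", g = "stop", t = "stop",
                ch = "affricate", j = "affricate",
                f = "fricative", h = "fricative", s = "fricative",
                sh = "fricative")
  vowel_of <- function(w) {
    if (endsWith(w, "eed")) "ee" else if (endsWith(w, "ood")) "oo" else "a"
  }
  word <- c(words, rep(c("dad", "shad"), each = 2))
  level <- c(rep(60, length(words)), rep(c(45, 75), times = 2))
  cons <- vapply(word, onset_of, character(1))
  cat <- data.frame(
    word = word,
    initial_consonant = unname(cons),
    consonant_class = unname(class_of[cons]),
    vowel = vapply(word, vowel_of, character(1)),
    level_db = level,
    stimulus_id = paste0(word, "_", level),
    row.names = NULL
  )
  cat <- cat[order(cat$word, cat$level_db), , drop = FALSE]
  rownames(cat) <- NULL
  cat
}

#' Noise-burst train specification
#'
#' Six 25-ms broadband noise bursts presented at 10 Hz (onsets every 100 ms),
#' 20 repeats per site; the probe for temporal-following / phase-locking
#' analyses.
#'
#' @param n_bursts,burst_dur_ms,rate_hz,n_repeats Train parameters; defaults
#'   are the standard battery.
#' @return An object of class `noise_train_spec`: list with the parameters,
#'   the burst onset times `onsets_ms`, and `stimulus_id`.
#' @export
build_noise_train_spec <- function(n_bursts = 6, burst_dur_ms = 25,
                                   rate_hz = 10, n_repeats = 20) {
  stopifnot(n_bursts >= 1, rate_hz > 0, burst_dur_ms > 0, n_repeats >= 1)
  spec <- list(
    n_bursts = as.integer(n_bursts),
    burst_dur_ms = burst_dur_ms,
    rate_hz = rate_hz,
    n_repeats = as.integer(n_repeats),
    onsets_ms = (seq_len(n_bursts) - 1) * (1000 / rate_hz),
    stimulus_id = sprintf("train_%ghz", rate_hz)
  )
  class(spec) <- "noise_train_spec"
  spec
}

#' @export
print.noise_train_spec <- function(x, ...) {
  cat(sprintf("Noise-burst train: %d x %g-ms bursts at %g Hz, %d repeats\n",
              x$n_bursts, x$burst_dur_ms, x$rate_hz, x$n_repeats))
  invisible(x)
}

#' Distance between two frequencies in octaves
#'
#' @param f1,f2 Frequencies in Hz (positive; vectorised).
#' @return `|log2(f2/f1)|`.
#' @examples
#' octave_distance(1000, 2000)   # 1
#' octave_distance(1000, 32000)  # 5
#' @export
octave_distance <- function(f1, f2) {
  if (any(f1 <= 0) || any(f2 <= 0))
    stop("frequencies must be positive")
  abs(log2(f2 / f1))
}

#' Speech-sound pair sets for neural discrimination
#'
#' The within-class consonant pairs and the vowel pairs the classifier is run
#' on, all at the 60-dB presentations: 3 stop pairs (d/g/t), 1 affricate pair
#' (ch/j), 6 fricative pairs (f/h/s/sh), and 3 vowel pairs
#' (dad/deed/dood).  Consonant sets use the consonant binning scheme, the
#' vowel set the vowel scheme (see [binning_scheme()]).
#'
#' @param all_consonant_pairs If `TRUE`, replace the three within-class
#'   consonant sets by a single set of every pair of 60-dB words that differ
#'   in the initial consonant (52 pairs).
#' @return Named list of pair sets; each has `name`, `scheme`
#'   (`"consonant"` or `"vowel"`), and `pairs`, a 2-column character matrix
#'   of stimulus ids.
#' @export
pair_sets <- function(all_consonant_pairs = FALSE) {
  id <- function(w) paste0(w, "_60")
  mk <- function(name, scheme, words_a, words_b) {
    list(name = name, scheme = scheme,
         pairs = cbind(a = id(words_a), b = id(words_b)))
  }
  pairs_of <- function(words) t(utils::combn(words, 2))
  if (all_consonant_pairs) {
    sp <- build_speech_catalog()
    p <- pairs_of(c("chad", "dad", "deed", "dood", "fad", "gad",
                    "had", "jad", "sad", "shad", "tad"))
    ic <- sp$initial_consonant[match(p, sp$word)]
    dim(ic) <- dim(p)
    p <- p[ic[, 1] != ic[, 2], , drop = FALSE]  # must differ in the consonant
    cons <- list(all_consonants = mk("all_consonants", "consonant",
                                     p[, 1], p[, 2]))
  } else {
    ps <- pairs_of(c("dad", "gad", "tad"))
    pf <- pairs_of(c("fad", "had", "sad", "shad"))
    cons <- list(
      stops = mk("stops", "consonant", ps[, 1], ps[, 2]),
      affricates = mk("affricates", "consonant", "chad", "jad"),
      fricatives = mk("fricatives", "consonant", pf[, 1], pf[, 2])
    )
  }
  pv <- pairs_of(c("dad", "deed", "dood"))
  c(cons, list(vowels = mk("vowels", "vowel", pv[, 1], pv[, 2])))
}

#' Assemble the full stimulus catalog
#'
#' Bundles the tone grid, the speech catalog and the noise-train spec with
#' the recorded analysis windows (relative to stimulus onset) and repeat
#' counts for each stimulus family.
#'
#' @return Object of class `stimulus_catalog`.
#' @export
build_stimulus_catalog <- function() {
  cat <- list(
    schema = "icspike-catalog-1",
    tones = build_tone_grid(),
    speech = build_speech_catalog(),
    noise = build_noise_train_spec(),
    windows = list(tone = c(-100, 100), speech = c(-100, 500),
                   noise = c(-100, 700)),
    n_repeats = list(tone = 1L, speech = 20L, noise = 20L)
  )
  class(cat) <- "stimulus_catalog"
  cat
}

#' @export
print.stimulus_catalog <- function(x, ...) {
  cat("Stimulus catalog (", x$schema, ")\n", sep = "")
  cat(sprintf("  tones : %d conditions, %g-%g kHz, %g-%g dB\n",
              nrow(x$tones), min(x$tones$freq_hz) / 1000,
              max(x$tones$freq_hz) / 1000,
              min(x$tones$level_db), max(x$tones$level_db)))
  cat(sprintf("  speech: %d stimuli (%d words), %d repeats\n",
              nrow(x$speech), length(unique(x$speech$word)),
              x$n_repeats$speech))
  cat(sprintf("  noise : %d bursts at %g Hz, %d repeats\n",
              x$noise$n_bursts, x$noise$rate_hz, x$n_repeats$noise))
  invisible(x)
}

# Stimulus family ("tone" / "speech" / "noise") for each stimulus id.
stimulus_family <- function(stimulus_id) {
  fam <- rep(NA_character_, length(stimulus_id))
  fam[startsWith(stimulus_id, "tone_")] <- "tone"
  fam[startsWith(stimulus_id, "train_")] <- "noise"
  fam[is.na(fam)] <- "speech"
  fam
}

# Recorded window for each stimulus id, as a 2-column matrix.
window_for <- function(catalog, stimulus_id) {
  fam <- stimulus_family(stimulus_id)
  w <- catalog$windows
  cbind(start = vapply(fam, function(f) w[[f]][1], numeric(1)),
        end = vapply(fam, function(f) w[[f]][2], numeric(1)))
}

#' Write / read a stimulus catalog as YAML
#'
#' Serialises the catalog (schema-versioned) so analysis configuration is
#' inspectable and diffable; [read_catalog()] restores the classed object.
#'
#' @param catalog A `stimulus_catalog`.
#' @param path File path.
#' @return `path` (write) or the catalog (read).
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "stimulus_catalog"))
  x <- unclass(catalog)
  x$noise <- unclass(x$noise)
  x$tones <- as.list(x$tones[c("freq_hz", "level_db", "stimulus_id")])
  x$speech <- lapply(as.list(x$speech), as.vector)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  x <- yaml::read_yaml(path)
  if (!identical(x$schema, "icspike-catalog-1"))
    stop("unrecognised catalog schema: ", x$schema)
  cat <- build_stimulus_catalog()
  stored <- data.frame(x$tones)
  if (nrow(stored) != nrow(cat$tones) ||
      !isTRUE(all.equal(stored$freq_hz, cat$tones$freq_hz)))
    stop("stored tone grid does not match the canonical grid")
  cat$speech <- data.frame(x$speech)
  cat$noise <- do.call(build_noise_train_spec,
                       x$noise[c("n_bursts", "burst_dur_ms", "rate_hz",
                                 "n_repeats")])
  cat$windows <- lapply(x$windows, as.numeric)
  cat$n_repeats <- lapply(x$n_repeats, as.integer)
  cat
}
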