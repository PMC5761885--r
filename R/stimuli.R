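#' Experiment stimulus configuration
#'
#' Per-condition trial counts, tempo set and level calibration for the
#' two published designs.  Each experiment presents 148 concatenated
#' rhythms per accent type (296 in total).  Conditions are numbered in
#' table order over the used (missing beats, off-beat accents) cells.
#'
#' @param experiment 1 or 2.
#' @return List of class `"experiment_config"` with elements
#'   `experiment`, `conditions` (data frame with per-type trial counts),
#'   `ioi_ms` (tempo set), `accent_delta_db` (intensity accent step),
#'   `temporal_offset_db` (overall temporal-rhythm attenuation) and
#'   `lead_silence_ms`.
#' @export
experiment_config <- function(experiment = 1) {
  experiment <- as.integer(match.arg(as.character(experiment), c("1", "2")))
  if (experiment == 1L) {
    cond <- data.frame(
      condition = 1:10,
      missing_beats    = c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L),
      off_beat_accents = c(0L, 0L, 1L, 2L, 1L, 2L, 3L, 3L, 4L, 5L),
      n_trials = c(24L, 15L, 15L, 15L, 15L, 15L, 15L, 12L, 12L, 10L)
    )
  } else {
    cond <- data.frame(
      condition = c(1L, 2L, 3L, 5L, 6L, 7L, 8L, 9L),
      missing_beats    = c(0L, 1L, 1L, 2L, 2L, 2L, 3L, 3L),
      off_beat_accents = c(0L, 0L, 1L, 1L, 2L, 3L, 3L, 4L),
      n_trials = c(28L, 24L, 24L, 18L, 18L, 18L, 10L, 8L)
    )
  }
  cond$category <- mapply(condition_category, cond$missing_beats,
                          cond$off_beat_accents)
  structure(list(experiment = experiment,
                 conditions = cond,
                 ioi_ms = c(140L, 145L, 150L, 155L, 160L),
                 accent_delta_db = 8.5,
                 temporal_offset_db = -0.8,
                 lead_silence_ms = 500),
            class = "experiment_config")
}

# Draw `n` ordered pairs of distinct patterns from `ids`, cycling through
# a reshuffled pool so that every pattern is used as evenly as possible
# before any is reused (the "as much variety as possible" rule).
draw_variety_pairs <- function(ids, n) {
  pool <- sample(ids)
  take <- function() {
    if (length(pool) == 0L) pool <<- sample(ids)
    x <- pool[1L]
    pool <<- pool[-1L]
    x
  }
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    a <- take()
    b <- take()
    guard <- 0L
    while (b == a) {           # never pair a pattern with itself
      pool <- c(pool, b)
      b <- take()
      guard <- guard + 1L
      if (guard > 10L * length(ids)) stop("cannot form a distinct pair")
    }
    pairs[[i]] <- c(a, b)
  }
  pairs
}

#' Build the concatenated stimulus set for an experiment
#'
#' For every used condition and accent type, draws the configured number
#' of trials.  A trial concatenates two distinct same-condition patterns
#' (16 + 16 grid positions) and appends a closing tone on the following downbeat
#' for 33 positions in all, preserving grid isochronicity.  Temporal
#' trials take their onsets from the two event masks; intensity trials
#' sound every position and carry the two accent masks.  Each trial is
#' assigned a tempo drawn uniformly from the configured tempo set.
#'
#' @param enumeration Result of [enumerate_experiment()].
#' @param config An [experiment_config()].
#' @param seed Integer seed; the build is a pure function of
#'   (enumeration, config, seed).
#' @return Data frame of class `"stimulus_set"`, one row per trial:
#'   `trial_id`, `accent_type`, `condition`, `missing_beats`,
#'   `off_beat_accents`, `category`, `pattern_a`, `pattern_b`,
#'   `events_a/b`, `accents_a/b`, `ioi_ms`.
#' @export
build_experiment_stimuli <- function(enumeration,
                                     config = experiment_config(1),
                                     seed = 1L) {
  stopifnot(inherits(config, "experiment_config"))
  cond <- config$conditions
  tab <- enumeration$conditions
  pat <- enumeration$space$patterns
  int <- enumeration$intensity
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(cond))) {
    mb <- cond$missing_beats[i]; ob <- cond$off_beat_accents[i]
    used <- tab$used[tab$missing_beats == mb & tab$off_beat_accents == ob]
    if (length(used) == 0L || !used)
      stop(sprintf("condition (%d missing, %d off-beat) is not used %s",
                   mb, ob, "under the enumeration inclusion rule"))
    for (type in c("temporal", "intensity")) {
      if (type == "temporal") {
        sel <- pat[pat$missing_beats == mb & pat$off_beat_accents == ob, ]
        ev <- stats::setNames(sel$events, sel$pattern_id)
        ac <- stats::setNames(sel$accents, sel$pattern_id)
      } else {
        sel <- int[int$missing_beats == mb & int$off_beat_accents == ob, ]
        ev <- stats::setNames(strrep("1", 16L)[rep(1L, nrow(sel))],
                              sel$pattern_id)
        ac <- stats::setNames(sel$accents, sel$pattern_id)
      }
      if (nrow(sel) < 2L)
        stop("need at least two distinct patterns per condition and type")
      pairs <- draw_variety_pairs(sel$pattern_id, cond$n_trials[i])
      ioi <- sample(config$ioi_ms, cond$n_trials[i], replace = TRUE)
      for (k in seq_along(pairs)) {
        p <- pairs[[k]]
        rows[[length(rows) + 1L]] <- data.frame(
          accent_type = type, condition = cond$condition[i],
          missing_beats = mb, off_beat_accents = ob,
          category = cond$category[i],
          pattern_a = p[1L], pattern_b = p[2L],
          events_a = ev[[p[1L]]], events_b = ev[[p[2L]]],
          accents_a = ac[[p[1L]]], accents_b = ac[[p[2L]]],
          ioi_ms = ioi[k], stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$accent_type, out$condition), ]
  out$trial_id <- sprintf("e%d_%s_%03d", config$experiment,
                          substr(out$accent_type, 1L, 1L),
                          stats::ave(seq_len(nrow(out)), out$accent_type,
                                     FUN = seq_along))
  rownames(out) <- NULL
  structure(out[, c("trial_id", setdiff(names(out), "trial_id"))],
            class = c("stimulus_set", "data.frame"))
}

#' Expand a trial into its 33-position grid
#'
#' @param trial One row of a [build_experiment_stimuli()] result.
#' @return Character vector of length 33 over `"accented"`,
#'   `"unaccented"`, `"silence"`.  The closing tone is rendered as an
#'   accented (isolated) tone.
#' @export
trial_grid <- function(trial) {
  ev <- c(as_grid_pattern(trial$events_a), as_grid_pattern(trial$events_b), 1L)
  ac <- c(as_grid_pattern(trial$accents_a), as_grid_pattern(trial$accents_b), 1L)
  ifelse(ev == 0L, "silence", ifelse(ac == 1L, "accented", "unaccented"))
}

#' Onset schedule of a trial
#'
#' Converts a trial's 33-position grid into onset times and levels.
#' Position k sounds at `lead_silence_ms + (k - 1) * ioi_ms`.  Levels are
#' in dB relative to the accented-intensity reference: intensity trials
#' play accented tones at 0 dB and unaccented tones 8.5 dB below;
#' temporal trials play every tone at -0.8 dB so that the two rhythm
#' types match in overall loudness.  The closing tone follows the same
#' rule as the trial's other tones (it is an isolated, hence accented,
#' tone: 0 dB in intensity trials, -0.8 dB in temporal trials).
#'
#' @param trial One row of a stimulus set.
#' @param ioi_ms Grid inter-onset interval in ms; defaults to the
#'   trial's assigned tempo.
#' @param config An [experiment_config()] providing the calibration.
#' @return Data frame `position`, `time_ms`, `level_db`, plus attribute
#'   `lead_silence_ms`.
#' @export
schedule_onsets <- function(trial, ioi_ms = trial$ioi_ms,
                            config = experiment_config(1)) {
  if (!ioi_ms %in% config$ioi_ms)
    stop("ioi_ms must be one of the configured tempi")
  grid <- trial_grid(trial)
  pos <- which(grid != "silence")
  level <- if (trial$accent_type == "intensity") {
    ifelse(grid[pos] == "accented", 0, -config$accent_delta_db)
  } else {
    rep(config$temporal_offset_db, length(pos))
  }
  out <- data.frame(position = pos,
                    time_ms = config$lead_silence_ms + (pos - 1L) * ioi_ms,
                    level_db = level)
  attr(out, "lead_silence_ms") <- config$lead_silence_ms
  out
}

# Short percussive click: exponentially decaying 2 kHz tone burst.
click_wave <- function(sample_rate, duration_ms = 30, freq_hz = 2000,
                       decay_ms = 8) {
  t <- seq(0, duration_ms / 1000, by = 1 / sample_rate)
  sin(2 * pi * freq_hz * t) * exp(-t / (decay_ms / 1000))
}

#' Render an onset schedule to a mono WAV file
#'
#' Each onset places a click scaled by `10^(level_db / 20)` relative to a
#' reference amplitude of -6 dBFS.  The leading silence of the schedule
#' is preserved as zero samples.
#'
#' @param schedule A [schedule_onsets()] result (possibly empty).
#' @param path Output path.
#' @param sample_rate Samples per second (>= 8000).
#' @param duration_ms Click length; must not exceed the smallest gap
#'   between onsets.
#' @return Invisibly, the number of samples written.
#' @export
render_wav <- function(schedule, path, sample_rate = 44100,
                       duration_ms = 30) {
  stopifnot(sample_rate >= 8000)
  lead <- attr(schedule, "lead_silence_ms")
  if (is.null(lead)) lead <- 500
  if (nrow(schedule) > 1L &&
      any(diff(schedule$time_ms) < duration_ms))
    stop("click duration exceeds the smallest inter-onset gap")
  click <- click_wave(sample_rate, duration_ms)
  total_ms <- if (nrow(schedule)) max(schedule$time_ms) + duration_ms + 50
              else lead
  n <- ceiling(total_ms / 1000 * sample_rate)
  x <- numeric(n)
  ref <- 10^(-6 / 20)                        # -6 dBFS headroom
  for (i in seq_len(nrow(schedule))) {
    at <- round(schedule$time_ms[i] / 1000 * sample_rate) + 1L
    idx <- at:(at + length(click) - 1L)
    x[idx] <- x[idx] + click * ref * 10^(schedule$level_db[i] / 20)
  }
  if (max(abs(x)) > 1) x <- x / max(abs(x))  # guard, not expected
  write_wav_pcm16(x, path, sample_rate)
  invisible(n)
}

# Minimal RIFF/WAVE writer, 16-bit PCM mono.
write_wav_pcm16 <- function(x, path, sample_rate) {
  pcm <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_len <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_len, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Write or read a stimulus manifest
#'
#' @param stimuli A [build_experiment_stimuli()] result.
#' @param path File path (tab-separated text).
#' @export
write_stimulus_manifest <- function(stimuli, path) {
  utils::write.table(stimuli, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_manifest
#' @export
read_stimulus_manifest <- function(path) {
  cls <- c(events_a = "character", events_b = "character",
           accents_a = "character", accents_b = "character")
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = cls, stringsAsFactors = FALSE)
  class(out) <- c("stimulus_set", "data.frame")
  out
}
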