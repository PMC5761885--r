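#' Constraint presets for pattern enumeration
#'
#' Returns the constraint set used to select temporal rhythms.  The
#' experiment presets are:
#' \describe{
#'   \item{1}{at most five consecutive tones, at most three consecutive
#'     silences, exactly six accents, the four 4-position beat segments
#'     pairwise distinct, and no unaccented tone on a beat position.}
#'   \item{2}{as preset 1 plus: at most three consecutive tones (counting
#'     the virtual downbeat that follows the pattern) and note values of
#'     exactly five sixteenths, two eighths, one dotted eighth and one
#'     quarter (cyclic inter-onset gaps \code{1,1,1,1,1,2,2,3,4}).}
#' }
#'
#' @param experiment 1 or 2.
#' @param run_convention Accent run convention, see
#'   [assign_temporal_accents()].
#' @return A list of class `"constraint_set"`.
#' @export
constraint_set <- function(experiment = 1,
                           run_convention = "next_downbeat") {
  experiment <- match.arg(as.character(experiment), c("1", "2"))
  cs <- list(
    experiment = as.integer(experiment),
    max_event_run = 5L,
    max_silence_run = 3L,
    required_accents = 6L,
    distinct_beat_quarters = TRUE,
    no_unaccented_beats = TRUE,
    required_interval_multiset = NULL,
    event_run_counts_next_downbeat = FALSE,
    run_convention = run_convention
  )
  if (experiment == "2") {
    cs$max_event_run <- 3L
    cs$required_interval_multiset <- c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 3L, 4L)
    cs$event_run_counts_next_downbeat <- TRUE
  }
  class(cs) <- "constraint_set"
  cs
}

# All 16-position masks with 9 onsets and an onset at position 1, as a
# 6435 x 16 integer matrix (one row per mask).
all_candidate_masks <- function() {
  ch <- utils::combn(15L, 8L)
  n <- ncol(ch)
  m <- matrix(0L, nrow = n, ncol = GRID_LEN)
  m[, 1L] <- 1L
  m[cbind(rep(seq_len(n), each = 8L), as.vector(ch) + 1L)] <- 1L
  m
}

# Vectorised accent assignment under the next_downbeat convention for a
# mask matrix: append a virtual onset column, sweep run lengths, mark run
# ends, and place accents per run length.  Returns a matrix of the same
# shape as `masks`.
accent_matrix_next_downbeat <- function(masks) {
  n <- nrow(masks)
  e <- cbind(masks, 1L)                    # virtual downbeat at col 17
  len <- matrix(0L, n, GRID_LEN + 1L)
  len[, 1L] <- e[, 1L]
  for (j in 2:(GRID_LEN + 1L)) len[, j] <- e[, j] * (len[, j - 1L] + 1L)
  acc <- matrix(0L, n, GRID_LEN + 1L)
  for (j in seq_len(GRID_LEN + 1L)) {
    is_end <- e[, j] == 1L &
      (if (j == GRID_LEN + 1L) TRUE else e[, j + 1L] == 0L)
    l <- len[, j]
    # run end itself is accented for lengths 1 (isolated), 2 (second of
    # pair) and >= 3 (last of run)
    acc[is_end, j] <- 1L
    # first of a run of three or more
    long <- is_end & l >= 3L
    if (any(long)) acc[cbind(which(long), j - l[long] + 1L)] <- 1L
  }
  acc[, seq_len(GRID_LEN), drop = FALSE]
}

# Row-wise maximum run length of `value` in a mask matrix; optionally
# counting the virtual downbeat after position 16 for event runs.
max_run_matrix <- function(masks, value = 1L, next_downbeat = FALSE) {
  e <- if (value == 1L) masks else 1L - masks
  if (next_downbeat && value == 1L) e <- cbind(e, 1L)
  n <- nrow(e)
  len <- matrix(0L, n, ncol(e))
  len[, 1L] <- e[, 1L]
  for (j in 2:ncol(e)) len[, j] <- e[, j] * (len[, j - 1L] + 1L)
  apply(len, 1L, max)
}

# TRUE where the four 4-position beat segments are pairwise distinct.
distinct_quarters <- function(masks) {
  pow <- c(8L, 4L, 2L, 1L)
  q <- vapply(0:3, function(b)
    as.vector(masks[, 4L * b + 1:4, drop = FALSE] %*% pow),
    numeric(nrow(masks)))
  if (nrow(masks) == 1L) q <- matrix(q, nrow = 1L)
  q[, 1] != q[, 2] & q[, 1] != q[, 3] & q[, 1] != q[, 4] &
    q[, 2] != q[, 3] & q[, 2] != q[, 4] & q[, 3] != q[, 4]
}

#' Enumerate the space of valid temporal rhythms
#'
#' Iterates all 6435 16-position masks with nine onsets and an onset at
#' position 1, assigns temporal accents, applies the constraint set and
#' classifies every surviving pattern by its counterevidence condition.
#'
#' @param constraints A [constraint_set()].
#' @return An object of class `"rhythm_space"`: a list with `patterns`
#'   (data frame with `pattern_id`, `events`, `accents`, `missing_beats`,
#'   `off_beat_accents`, `category`), `constraints`, and `counts` (per
#'   condition).
#' @examples
#' \donttest{
#' sp <- enumerate_space(constraint_set(1))
#' nrow(sp$patterns)  # 670
#' }
#' @export
enumerate_space <- function(constraints = constraint_set(1)) {
  stopifnot(inherits(constraints, "constraint_set"))
  masks <- all_candidate_masks()
  keep <- max_run_matrix(masks, 1L,
                         constraints$event_run_counts_next_downbeat) <=
    constraints$max_event_run
  keep <- keep & max_run_matrix(masks, 0L) <= constraints$max_silence_run
  if (!is.null(constraints$required_interval_multiset)) {
    ref <- sort(constraints$required_interval_multiset)
    keep[keep] <- vapply(which(keep), function(i) {
      identical(sort(interval_multiset(masks[i, ])), ref)
    }, logical(1))
  }
  if (isTRUE(constraints$distinct_beat_quarters))
    keep <- keep & distinct_quarters(masks)
  masks <- masks[keep, , drop = FALSE]
  acc <- accent_matrix_next_downbeat(masks)
  keep <- rowSums(acc) == constraints$required_accents
  if (isTRUE(constraints$no_unaccented_beats)) {
    unacc <- masks[, BEAT_POSITIONS, drop = FALSE] == 1L &
      acc[, BEAT_POSITIONS, drop = FALSE] == 0L
    keep <- keep & rowSums(unacc) == 0L
  }
  masks <- masks[keep, , drop = FALSE]
  acc <- acc[keep, , drop = FALSE]
  mb <- rowSums(masks[, BEAT_POSITIONS, drop = FALSE] == 0L)
  ob <- rowSums(acc[, OFFBEAT_POSITIONS, drop = FALSE])
  pat <- data.frame(
    pattern_id = sprintf("t%d_%04d", constraints$experiment,
                         seq_len(nrow(masks))),
    events = apply(masks, 1L, paste, collapse = ""),
    accents = apply(acc, 1L, paste, collapse = ""),
    missing_beats = as.integer(mb),
    off_beat_accents = as.integer(ob),
    stringsAsFactors = FALSE
  )
  pat$category <- mapply(condition_category, pat$missing_beats,
                         pat$off_beat_accents)
  counts <- as.data.frame(table(missing_beats = pat$missing_beats,
                                off_beat_accents = pat$off_beat_accents),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0L, ]
  structure(list(patterns = pat, constraints = constraints,
                 counts = counts),
            class = "rhythm_space")
}

#' @export
print.rhythm_space <- function(x, ...) {
  cat(sprintf("rhythm space: %d temporal patterns (experiment preset %d)\n",
              nrow(x$patterns), x$constraints$experiment))
  invisible(x)
}

#' Enumerate the space of valid intensity rhythms
#'
#' Intensity rhythms place a tone on every grid position and realise the
#' accent structure by loudness, so their accent masks are the distinct
#' accent masks achievable by temporal grouping.  Unlike temporal
#' rhythms, an intensity rhythm may carry an unaccented tone on a beat --
#' that is exactly how a beat goes "missing" when every position sounds
#' -- but the downbeat (position 1) is always accented.  The source set
#' is therefore every nine-onset pattern with an onset at position 1 that
#' satisfies the run-length constraints, carries exactly six accents, and
#' has an accent on position 1.
#'
#' @param constraints A [constraint_set()].  Only the Experiment-1 run
#'   constraints act on the source patterns; the note-value constraints
#'   of preset 2 concern tone timing and do not apply to isochronous
#'   intensity rhythms.
#' @return Data frame with one row per distinct accent mask: `accents`,
#'   `missing_beats` (unaccented beat positions), `off_beat_accents`,
#'   `category`.
#' @export
enumerate_intensity_space <- function(constraints = constraint_set(1)) {
  base <- constraint_set(1)        # run constraints shared by both presets
  masks <- all_candidate_masks()
  keep <- max_run_matrix(masks, 1L) <= base$max_event_run &
    max_run_matrix(masks, 0L) <= base$max_silence_run
  masks <- masks[keep, , drop = FALSE]
  acc <- accent_matrix_next_downbeat(masks)
  keep <- rowSums(acc) == base$required_accents & acc[, 1L] == 1L
  acc <- acc[keep, , drop = FALSE]
  key <- apply(acc, 1L, paste, collapse = "")
  acc <- acc[!duplicated(key), , drop = FALSE]
  mb <- 4L - rowSums(acc[, BEAT_POSITIONS, drop = FALSE])
  ob <- rowSums(acc[, OFFBEAT_POSITIONS, drop = FALSE])
  out <- data.frame(
    accents = apply(acc, 1L, paste, collapse = ""),
    missing_beats = as.integer(mb),
    off_beat_accents = as.integer(ob),
    stringsAsFactors = FALSE
  )
  out$category <- mapply(condition_category, out$missing_beats,
                         out$off_beat_accents)
  out$pattern_id <- sprintf("i_%03d", seq_len(nrow(out)))
  out[order(out$missing_beats, out$off_beat_accents, out$accents),
      c("pattern_id", "accents", "missing_beats", "off_beat_accents",
        "category")]
}

#' Project a temporal space onto per-condition intensity pattern sets
#'
#' For each condition of the temporal space, collects the set of distinct
#' accent masks over that condition's patterns.  The condition label is
#' preserved because the projection leaves accent positions unchanged.
#'
#' @param space A [enumerate_space()] result.
#' @return Data frame like [enumerate_intensity_space()], restricted to
#'   masks realised inside `space`.
#' @export
project_to_intensity <- function(space) {
  stopifnot(inherits(space, "rhythm_space"))
  pat <- space$patterns
  key <- paste(pat$missing_beats, pat$off_beat_accents, pat$accents)
  pat <- pat[!duplicated(key), ]
  data.frame(accents = pat$accents,
             missing_beats = pat$missing_beats,
             off_beat_accents = pat$off_beat_accents,
             category = pat$category,
             stringsAsFactors = FALSE)
}

#' Condition table in the layout of the published enumeration tables
#'
#' Crosses the temporal space with the intensity space and reports, per
#' (missing beats, off-beat accents) condition: the number of temporal
#' patterns, the number of distinct intensity patterns, the few/some/many
#' category, and whether the condition is used (both counts at least
#' `min_patterns`).
#'
#' @param space Temporal space from [enumerate_space()].
#' @param intensity Intensity patterns from [enumerate_intensity_space()].
#'   Intensity rhythms are not subject to the tone-timing constraints of
#'   preset 2, so the same intensity space serves both experiments.
#' @param min_patterns Minimum pattern count for a condition to be used
#'   (6 in both published experiments).
#' @return Data frame with columns `missing_beats`, `off_beat_accents`,
#'   `temporal`, `intensity`, `category`, `used`.
#' @export
tabulate_conditions <- function(space,
                                intensity = enumerate_intensity_space(),
                                min_patterns = 6) {
  stopifnot(inherits(space, "rhythm_space"))
  pat <- space$patterns
  cells <- unique(rbind(
    unique(pat[, c("missing_beats", "off_beat_accents")]),
    unique(intensity[, c("missing_beats", "off_beat_accents")])
  ))
  cells <- cells[order(cells$missing_beats, cells$off_beat_accents), ]
  tcount <- icount <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    tcount[i] <- sum(pat$missing_beats == cells$missing_beats[i] &
                       pat$off_beat_accents == cells$off_beat_accents[i])
    icount[i] <- sum(intensity$missing_beats == cells$missing_beats[i] &
                       intensity$off_beat_accents == cells$off_beat_accents[i])
  }
  out <- data.frame(
    missing_beats = cells$missing_beats,
    off_beat_accents = cells$off_beat_accents,
    temporal = tcount,
    intensity = icount,
    category = mapply(condition_category, cells$missing_beats,
                      cells$off_beat_accents),
    stringsAsFactors = FALSE
  )
  out$used <- out$temporal >= min_patterns & out$intensity >= min_patterns &
    out$category != "not_used"
  rownames(out) <- NULL
  out
}

#' One-call enumeration of an experiment's pattern spaces
#'
#' Convenience wrapper running [enumerate_space()],
#' [enumerate_intensity_space()] and [tabulate_conditions()] for an
#' experiment preset.
#'
#' @param experiment 1 or 2.
#' @param min_patterns Inclusion threshold, see [tabulate_conditions()].
#' @return List with `space`, `intensity`, `conditions`.
#' @export
enumerate_experiment <- function(experiment = 1, min_patterns = 6) {
  space <- enumerate_space(constraint_set(experiment))
  intensity <- enumerate_intensity_space()
  list(space = space,
       intensity = intensity,
       conditions = tabulate_conditions(space, intensity, min_patterns))
}

#' Write or read a pattern manifest
#'
#' The manifest is a tab-separated table with one row per pattern:
#' pattern id, 16-character event string, 16-character accent string,
#' missing beats, off-beat accents, category and the experiment preset.
#'
#' @param space A [enumerate_space()] result.
#' @param path File path.
#' @return `read_pattern_manifest()` returns the manifest data frame.
#' @export
write_pattern_manifest <- function(space, path) {
  stopifnot(inherits(space, "rhythm_space"))
  pat <- space$patterns
  pat$experiment <- space$constraints$experiment
  utils::write.table(pat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pattern_manifest
#' @export
read_pattern_manifest <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(events = "character",
                                   accents = "character"),
                    stringsAsFactors = FALSE)
}
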