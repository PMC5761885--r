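#' @keywords internal
"_PACKAGE"

# Grid geometry shared across the package.  Positions are 1-based.
BEAT_POSITIONS <- c(1L, 5L, 9L, 13L)
OFFBEAT_POSITIONS <- seq(2L, 16L, by = 2L)
AMBIGUOUS_POSITIONS <- c(3L, 7L, 11L, 15L)
GRID_LEN <- 16L

#' Parse and format 16-position grid patterns
#'
#' A grid pattern is a binary vector of length 16 in which 1 marks a tone
#' onset and 0 a silence.  Patterns may be given as integer/logical vectors
#' or as 16-character strings such as `"1110100110010010"`.
#'
#' @param x A length-16 binary vector or a 16-character string of 0s and 1s.
#' @return `as_grid_pattern()` returns an integer vector of length 16;
#'   `format_grid_pattern()` returns the 16-character string form.
#' @examples
#' as_grid_pattern("1000100010001000")
#' format_grid_pattern(c(1, rep(0, 15)))
#' @export
as_grid_pattern <- function(x) {
  if (is.character(x)) {
    if (length(x) != 1L || nchar(x) != GRID_LEN)
      stop("pattern string must have exactly 16 characters")
    x <- as.integer(strsplit(x, "")[[1L]])
  }
  x <- as.integer(x)
  if (length(x) != GRID_LEN || anyNA(x) || !all(x %in% c(0L, 1L)))
    stop("a grid pattern is a binary vector of length 16")
  x
}

#' @rdname as_grid_pattern
#' @export
format_grid_pattern <- function(x) paste(as_grid_pattern(x), collapse = "")

#' Assign temporal accents to a grid pattern
#'
#' Implements the grouping-accent rule of Povel and Essens: an isolated
#' tone is accented, the second of a pair of consecutive tones is accented,
#' and the first and last tones of a run of three or more are accented.
#'
#' Because the 16-position pattern is never heard in isolation -- in the
#' experiment it is always followed either by a second pattern (which
#' starts with a tone) or by the closing tone on the downbeat -- the
#' default `"next_downbeat"` convention scans runs over the pattern plus a
#' virtual onset at position 17; accents that fall on the virtual position
#' are discarded.  This is the convention that reproduces the published
#' enumeration tables.  `"linear"` treats the pattern as preceded and
#' followed by silence; `"cyclic"` lets runs wrap from position 16 to 1.
#'
#' @param events A grid pattern (see [as_grid_pattern()]).
#' @param run_convention One of `"next_downbeat"`, `"linear"`, `"cyclic"`.
#' @return Integer vector of length 16; 1 marks an accented onset.
#'   Accents are always a subset of the onsets.
#' @examples
#' ev <- as_grid_pattern("1100011100001000")
#' assign_temporal_accents(ev)
#' @export
assign_temporal_accents <- function(events,
                                    run_convention = c("next_downbeat",
                                                       "linear", "cyclic")) {
  run_convention <- match.arg(run_convention)
  events <- as_grid_pattern(events)
  if (all(events == 1L) || all(events == 0L))
    stop("pattern must contain at least one onset and one silence")
  runs <- pattern_runs(events, run_convention)
  acc <- integer(GRID_LEN)
  for (i in seq_len(nrow(runs))) {
    if (runs$value[i] != 1L) next
    len <- runs$length[i]
    pos <- ((runs$start[i] - 1L + seq_len(len) - 1L) %% runs$modulus[i]) + 1L
    hit <- if (len == 1L) pos else if (len == 2L) pos[2L] else pos[c(1L, len)]
    hit <- hit[hit <= GRID_LEN]   # drop accents on the virtual downbeat
    acc[hit] <- 1L
  }
  acc
}

# Run decomposition of a binary vector under the three boundary
# conventions.  Returns value/length/start plus the modulus used so that
# cyclic runs can be unwrapped by the caller.
pattern_runs <- function(v, run_convention = "linear") {
  n <- length(v)
  if (run_convention == "next_downbeat") {
    v <- c(v, 1L)
    r <- rle(v)
    start <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
    return(data.frame(value = r$values, length = r$lengths, start = start,
                      modulus = n + 1L))
  }
  if (run_convention == "cyclic" && !all(v == v[1L])) {
    b <- which(v != v[c(n, seq_len(n - 1L))])[1L]
    vr <- v[c(b:n, seq_len(b - 1L))]
    r <- rle(vr)
    start <- ((cumsum(c(1L, r$lengths))[seq_along(r$lengths)] - 1L +
                 b - 1L) %% n) + 1L
    return(data.frame(value = r$values, length = r$lengths, start = start,
                      modulus = n))
  }
  r <- rle(v)
  start <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
  data.frame(value = r$values, length = r$lengths, start = start,
             modulus = n)
}

# Longest run of `value` under a convention; 0 when absent.
max_run_length <- function(v, value, run_convention = "linear") {
  runs <- pattern_runs(v, run_convention)
  if (run_convention == "next_downbeat") {
    # only event runs gain from the virtual onset; a silence run cannot
    # include it
    if (value == 0L) runs <- pattern_runs(v, "linear")
  }
  len <- runs$length[runs$value == value]
  if (length(len) == 0L) 0L else max(len)
}

#' Cyclic inter-onset intervals of a grid pattern
#'
#' Returns the gaps (in grid units) between successive onsets, closing the
#' loop from the final onset back to the first across the 16-position
#' boundary, so that the gaps always sum to 16 and there are as many gaps
#' as onsets.  In musical terms the gaps are the note values: a gap of 1
#' is a sixteenth note, 2 an eighth, 3 a dotted eighth, 4 a quarter.
#'
#' @param events A grid pattern.
#' @return Integer vector of gaps, one per onset, in pattern order.
#' @examples
#' interval_multiset(as_grid_pattern("1000100010001000"))  # 4 4 4 4
#' @export
interval_multiset <- function(events) {
  events <- as_grid_pattern(events)
  onsets <- which(events == 1L)
  if (length(onsets) == 0L) stop("pattern has no onsets")
  diff(c(onsets, onsets[1L] + GRID_LEN))
}

# Mapping from (missing beats, off-beat accents) to the few/some/many
# category used in the analysis.  Combinations outside the mapping are
# labelled "not_used".
CONDITION_CATEGORIES <- data.frame(
  missing_beats    = c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L),
  off_beat_accents = c(0L, 0L, 1L, 2L, 1L, 2L, 3L, 3L, 4L, 5L),
  category = c("few", "few", "some", "many", "few", "some", "many",
               "few", "some", "many"),
  stringsAsFactors = FALSE
)

#' Classify a pattern by counterevidence on and off the beat
#'
#' Counts the counterevidence a pattern holds against a four-beat duple
#' reading of the grid: *missing beats* are silent positions among the
#' beat positions 1, 5, 9, 13, and *off-beat accents* are accents on the
#' even positions 2, 4, ..., 16.  The ambiguous positions 3, 7, 11, 15
#' (on the beat under an eight-beat reading) contribute to neither count.
#' The off-beat count is mapped to a few/some/many category whose meaning
#' depends on the missing-beat count; combinations outside the published
#' design are labelled `"not_used"`.
#'
#' @param events A grid pattern.
#' @param accents Accent mask as returned by [assign_temporal_accents()].
#' @return A list with `missing_beats`, `off_beat_accents`, `category`,
#'   and `ambiguous_accents` (accent count on positions 3/7/11/15,
#'   exposed for inspection only).
#' @export
classify_condition <- function(events, accents) {
  events <- as_grid_pattern(events)
  accents <- as_grid_pattern(accents)
  if (any(accents == 1L & events == 0L))
    stop("accent on a silent position")
  mb <- sum(events[BEAT_POSITIONS] == 0L)
  ob <- sum(accents[OFFBEAT_POSITIONS] == 1L)
  list(missing_beats = mb,
       off_beat_accents = ob,
       category = condition_category(mb, ob),
       ambiguous_accents = sum(accents[AMBIGUOUS_POSITIONS] == 1L))
}

condition_category <- function(missing_beats, off_beat_accents) {
  m <- CONDITION_CATEGORIES
  hit <- m$missing_beats == missing_beats &
    m$off_beat_accents == off_beat_accents
  if (any(hit)) m$category[hit] else "not_used"
}
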