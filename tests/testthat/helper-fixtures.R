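# Shared fixtures, built once per test run.  Everything is generated in
# code; nothing is read from disk.

enum1 <- function() {
  if (is.null(.fixture_env$enum1))
    .fixture_env$enum1 <- enumerate_experiment(1)
  .fixture_env$enum1
}

enum2 <- function() {
  if (is.null(.fixture_env$enum2))
    .fixture_env$enum2 <- enumerate_experiment(2)
  .fixture_env$enum2
}

stimuli1 <- function() {
  if (is.null(.fixture_env$stim1))
    .fixture_env$stim1 <- build_experiment_stimuli(enum1(),
                                                   experiment_config(1),
                                                   seed = 20240917)
  .fixture_env$stim1
}

# small, quickly fit synthetic panel used by several model tests
small_ratings <- function() {
  if (is.null(.fixture_env$small)) {
    pars <- simulation_params("exp1", n_participants = 12,
                              ratings_range = c(50, 80))
    .fixture_env$small <- simulate_ratings(pars, stimuli1(), seed = 11)
  }
  .fixture_env$small
}

.fixture_env <- new.env(parent = emptyenv())

# independent run-scanning oracle for accent assignment: scans the
# pattern followed by the next downbeat with rle() and applies the
# grouping rule run by run (deliberately different code from the
# vectorised production path)
oracle_accents <- function(ev) {
  r <- rle(c(ev, 1L))
  acc <- integer(17)
  pos <- 1L
  for (i in seq_along(r$lengths)) {
    len <- r$lengths[i]
    if (r$values[i] == 1L) {
      if (len == 1L) acc[pos] <- 1L
      else if (len == 2L) acc[pos + 1L] <- 1L
      else acc[c(pos, pos + len - 1L)] <- 1L
    }
    pos <- pos + len
  }
  acc[1:16]
}
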