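test_that("the Experiment-1 stimulus set has the published shape", {
  st <- stimuli1()
  expect_equal(nrow(st), 296L)
  expect_equal(as.vector(table(st$accent_type)), c(148L, 148L))
  cfg <- experiment_config(1)
  counts <- stats::aggregate(trial_id ~ condition + accent_type, st, length)
  counts <- merge(counts, cfg$conditions[, c("condition", "n_trials")])
  expect_equal(counts$trial_id, counts$n_trials)
  expect_equal(nrow(counts), 20L)   # 10 conditions x 2 accent types
  # every trial concatenates two distinct patterns of its own condition
  expect_true(all(st$pattern_a != st$pattern_b))
  grid_lens <- vapply(seq_len(nrow(st)), function(i)
    length(trial_grid(st[i, ])), 0L)
  expect_true(all(grid_lens == 33L))
  # intensity trials sound on every grid position
  iv <- st[st$accent_type == "intensity", ]
  expect_true(all(iv$events_a == strrep("1", 16)))
  # tempo assignment covers the whole tempo set
  expect_setequal(unique(st$ioi_ms), cfg$ioi_ms)
})

test_that("the stimulus build is reproducible and seed-sensitive", {
  e <- enum1()
  a <- build_experiment_stimuli(e, experiment_config(1), seed = 5)
  b <- build_experiment_stimuli(e, experiment_config(1), seed = 5)
  c <- build_experiment_stimuli(e, experiment_config(1), seed = 6)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("requesting a not-used condition fails loudly", {
  e <- enum1()
  cfg <- experiment_config(1)
  cfg$conditions <- rbind(cfg$conditions,
                          data.frame(condition = 99L, missing_beats = 2L,
                                     off_beat_accents = 0L, n_trials = 5L,
                                     category = "not_used"))
  expect_error(build_experiment_stimuli(e, cfg, seed = 1), "not used")
})

test_that("onset schedules encode tempo, lead silence and level calibration", {
  st <- stimuli1()
  tmp <- st[st$accent_type == "temporal", ][1, ]
  ity <- st[st$accent_type == "intensity", ][1, ]
  sc <- schedule_onsets(tmp, ioi_ms = 150)
  expect_equal(sc$time_ms[1], 500)
  expect_equal(sc$time_ms[sc$position == 5] - sc$time_ms[sc$position == 1],
               600)
  # two nine-onset halves plus the closing tone
  expect_equal(nrow(sc), 19L)
  expect_true(all(sc$level_db == -0.8))
  sci <- schedule_onsets(ity, ioi_ms = 150)
  expect_equal(nrow(sci), 33L)
  expect_equal(sort(unique(sci$level_db)), c(-8.5, 0))
  expect_error(schedule_onsets(tmp, ioi_ms = 100), "tempi")
})

test_that("rendered audio starts silent and respects the accent step", {
  st <- stimuli1()
  ity <- st[st$accent_type == "intensity", ][1, ]
  sc <- schedule_onsets(ity, ioi_ms = 150)
  path <- withr::local_tempfile(fileext = ".wav")
  render_wav(sc, path, sample_rate = 22050)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 44)
  expect_equal(rawToChar(header[1:4]), "RIFF")
  expect_equal(rawToChar(header[9:16]), "WAVEfmt ")
  samples <- readBin(con, "integer", 5e6, size = 2, endian = "little")
  lead <- samples[seq_len(0.5 * 22050) - 1]
  expect_true(all(lead == 0))
  expect_true(max(abs(samples)) <= 32767)
  # accented / unaccented peak ratio equals the 8.5 dB step
  acc_pos <- sc$time_ms[sc$level_db == 0] / 1000 * 22050
  un_pos <- sc$time_ms[sc$level_db == -8.5] / 1000 * 22050
  peak <- function(at) max(abs(samples[(at + 1):(at + 600)]))
  ratio <- peak(acc_pos[1]) / peak(un_pos[1])
  expect_equal(ratio, 10^(8.5 / 20), tolerance = 0.01)
  # an empty schedule renders lead silence only
  empty <- data.frame(position = integer(0), time_ms = numeric(0),
                      level_db = numeric(0))
  attr(empty, "lead_silence_ms") <- 500
  n <- render_wav(empty, path, sample_rate = 8000)
  expect_equal(n, 4000)
  # overlapping clicks are rejected
  bad <- data.frame(position = 1:2, time_ms = c(500, 510),
                    level_db = c(0, 0))
  expect_error(render_wav(bad, path), "duration")
})

test_that("stimulus manifests round-trip losslessly", {
  st <- stimuli1()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stimulus_manifest(st, path)
  back <- read_stimulus_manifest(path)
  expect_equal(as.data.frame(back), as.data.frame(st))
})
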