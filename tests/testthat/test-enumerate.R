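table1 <- data.frame(
  missing_beats    = c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 3L, 3L, 3L, 3L),
  off_beat_accents = c(0L, 0L, 1L, 2L, 0L, 1L, 2L, 3L, 4L, 2L, 3L, 4L, 5L),
  temporal  = c(12L, 36L, 98L, 56L, 11L, 65L, 143L, 111L, 18L, 10L, 37L,
                53L, 20L),
  intensity = c(6L, 6L, 18L, 6L, 3L, 12L, 22L, 16L, 3L, 2L, 8L, 12L, 6L)
)

test_that("Experiment-1 enumeration reproduces the published table", {
  e <- enum1()
  expect_equal(nrow(e$space$patterns), 670L)
  expect_equal(nrow(e$intensity), 120L)
  tab <- e$conditions
  expect_equal(nrow(tab), 13L)
  m <- merge(tab, table1, by = c("missing_beats", "off_beat_accents"))
  expect_equal(m$temporal.x, m$temporal.y)
  expect_equal(m$intensity.x, m$intensity.y)
  expect_equal(sum(tab$used), 10L)
  # the three excluded cells
  notused <- tab[!tab$used, ]
  expect_equal(notused$temporal, c(11L, 18L, 10L))
  expect_equal(notused$intensity, c(3L, 3L, 2L))
})

test_that("Experiment-2 enumeration is stable under the run convention", {
  e <- enum2()
  tab <- e$conditions
  # structural zeros: three conditions become impossible under the
  # tightened note-value constraints
  zero <- tab$temporal[(tab$missing_beats * 10 + tab$off_beat_accents)
                       %in% c(12, 24, 35)]
  expect_equal(zero, c(0L, 0L, 0L))
  # counts under the package's convention (regression values computed
  # with an independent prototype of the same rules)
  expect_equal(nrow(e$space$patterns), 105L)
  got <- tab$temporal[order(tab$missing_beats, tab$off_beat_accents)]
  expect_equal(got, c(12L, 18L, 10L, 0L, 10L, 14L, 14L, 7L, 0L, 4L, 7L,
                      9L, 0L))
  # intensity rhythms are isochronous, so their space is shared with
  # Experiment 1
  expect_equal(tab$intensity, table1$intensity)
  expect_equal(sum(tab$used), 8L)
})

test_that("Experiment-2 patterns satisfy their extra constraints and nest in Experiment 1", {
  e1 <- enum1(); e2 <- enum2()
  expect_true(all(e2$space$patterns$events %in% e1$space$patterns$events))
  ref <- sort(c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 3L, 4L))
  for (s in e2$space$patterns$events) {
    ev <- as_grid_pattern(s)
    expect_identical(sort(interval_multiset(ev)), ref)
    expect_lte(beatgrid:::max_run_length(ev, 1L, "next_downbeat"), 3L)
  }
})

test_that("intensity projection never exceeds the temporal count", {
  for (e in list(enum1(), enum2())) {
    proj <- project_to_intensity(e$space)
    agg <- merge(
      stats::aggregate(cbind(n_proj = accents) ~ missing_beats +
                         off_beat_accents, proj, length),
      stats::aggregate(cbind(n_temp = events) ~ missing_beats +
                         off_beat_accents, e$space$patterns, length))
    expect_true(all(agg$n_proj <= agg$n_temp))
    # a condition with a single temporal pattern projects to its own mask
    singles <- agg[agg$n_temp == 1L, ]
    if (nrow(singles)) expect_true(all(singles$n_proj == 1L))
  }
})

test_that("the inclusion filter responds to min_patterns", {
  e <- enum1()
  all_used <- tabulate_conditions(e$space, e$intensity, min_patterns = 0)
  expect_true(all(all_used$used[all_used$category != "not_used"]))
  none <- tabulate_conditions(e$space, e$intensity, min_patterns = 1e6)
  expect_false(any(none$used))
})

test_that("an unsatisfiable accent requirement empties the space", {
  cs <- constraint_set(1)
  cs$required_accents <- 10L
  expect_equal(nrow(enumerate_space(cs)$patterns), 0L)
})

test_that("pattern manifests round-trip through disk", {
  e <- enum2()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pattern_manifest(e$space, path)
  back <- read_pattern_manifest(path)
  expect_equal(back$events, e$space$patterns$events)
  expect_equal(back$accents, e$space$patterns$accents)
  expect_equal(back$missing_beats, e$space$patterns$missing_beats)
})
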