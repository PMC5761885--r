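test_that("grouping accents follow the isolated / pair / run rule", {
  # isolated tone inside silence
  ev <- integer(16); ev[5] <- 1L
  expect_equal(which(assign_temporal_accents(ev) == 1L), 5L)
  # pair: second tone accented
  ev <- integer(16); ev[1:2] <- 1L
  expect_equal(which(assign_temporal_accents(ev) == 1L), 2L)
  # run of five: first and last accented
  ev <- integer(16); ev[1:5] <- 1L
  expect_equal(which(assign_temporal_accents(ev) == 1L), c(1L, 5L))
  # all-onset and all-silence patterns have no run structure
  expect_error(assign_temporal_accents(rep(1L, 16)), "onset")
  expect_error(assign_temporal_accents(rep(0L, 16)), "onset")
})

test_that("boundary conventions differ exactly at the pattern edges", {
  # trailing pair: under the next-downbeat convention the pair extends
  # into a run of three whose final accent falls on the virtual
  # position, so neither tone is accented; linearly the 16th is
  ev <- integer(16); ev[c(1, 15, 16)] <- 1L
  nd <- assign_temporal_accents(ev, "next_downbeat")
  li <- assign_temporal_accents(ev, "linear")
  expect_equal(which(nd == 1L), c(1L, 15L))
  expect_equal(which(li == 1L), c(1L, 16L))
  # cyclic wrap joins 15,16 with 1
  cy <- assign_temporal_accents(ev, "cyclic")
  expect_equal(which(cy == 1L), c(1L, 15L))
})

test_that("accent structure matches an independent run-scanning oracle", {
  # every 16-position mask with nine onsets (not only those starting
  # with one); checks positions, not just counts
  combs <- combn(16, 9)
  masks <- t(apply(combs, 2, function(ix) { v <- integer(16); v[ix] <- 1L; v }))
  expect_equal(nrow(masks), 11440L)
  acc_all <- beatgrid:::accent_matrix_next_downbeat(masks)
  acc_oracle <- t(apply(masks, 1L, oracle_accents))
  expect_equal(unname(acc_all), unname(acc_oracle))
  # closed-form count over the run decomposition: an interior run
  # contributes 1 accent if its length is 1 or 2, else 2; the trailing
  # run merged with the virtual downbeat contributes 1 accent when the
  # merged length reaches 3 (its first tone), else 0
  run_counts <- apply(masks, 1L, function(ev) {
    r <- rle(c(ev, 1L))
    len <- r$lengths[r$values == 1L]
    last <- length(len)                    # run holding the virtual onset
    interior <- len[-last]
    sum(interior <= 2L) + 2L * sum(interior >= 3L) + (len[last] >= 3L)
  })
  expect_equal(unname(rowSums(acc_all)), unname(run_counts))
})

test_that("interval multiset is the cyclic gap sequence", {
  expect_equal(interval_multiset(as_grid_pattern("1000100010001000")),
               c(4L, 4L, 4L, 4L))
  # conservation: 9 onsets give 9 gaps summing to 16
  set.seed(42)
  for (i in 1:25) {
    ev <- integer(16); ev[sample(16, 9)] <- 1L
    g <- interval_multiset(ev)
    expect_length(g, 9L)
    expect_equal(sum(g), 16L)
  }
  expect_error(interval_multiset(rep(0L, 16)), "onset")
})

test_that("condition classification counts beats and even positions", {
  # strictly metric: accents on all four beats plus two ambiguous slots
  ev <- as_grid_pattern("1010100010101000")
  ac <- ev
  cl <- classify_condition(ev, ac)
  expect_equal(cl$missing_beats, 0L)
  expect_equal(cl$off_beat_accents, 0L)
  expect_equal(cl$category, "few")
  # beats 5, 9, 13 silent; five accents on even positions
  ev <- as_grid_pattern("1101010101000000")
  ac <- as_grid_pattern("1101010101000000")
  cl <- classify_condition(ev, ac)
  expect_equal(cl$missing_beats, 3L)
  expect_equal(cl$off_beat_accents, 5L)
  expect_equal(cl$category, "many")
  # the published category mapping
  expect_equal(beatgrid:::condition_category(2, 3), "many")
  expect_equal(beatgrid:::condition_category(2, 0), "not_used")
  expect_equal(beatgrid:::condition_category(3, 3), "few")
  # ambiguous positions never enter either count
  ev <- as_grid_pattern("1010001000100010")
  ac <- as_grid_pattern("1010001000100010")
  cl <- classify_condition(ev, ac)
  expect_equal(cl$ambiguous_accents, 4L)   # accents on 3, 7, 11, 15
  expect_equal(cl$off_beat_accents, sum(ac[seq(2, 16, 2)]))
  # accents must sit on onsets
  expect_error(classify_condition(as_grid_pattern("1000000000000000"),
                                  as_grid_pattern("0100000000000000")),
               "silent")
})
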