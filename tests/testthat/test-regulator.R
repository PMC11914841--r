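test_that("success rate is hits over target trials, false positives excluded", {
  expect_equal(success_rate(make_block(18, 6)), 0.75)
  expect_equal(success_rate(make_block(24, 0)), 1)
  expect_equal(success_rate(make_block(12, 12, n_fp = 5)), 0.5)
})

test_that("success-rate bands partition [0, 1] with boundaries in the middle band", {
  expect_identical(classify_block(0.80), "too_easy")
  expect_identical(classify_block(0.60), "difficult")
  expect_identical(classify_block(0.40), "too_difficult")
  expect_identical(classify_block(0.75), "difficult")
  expect_identical(classify_block(0.50), "difficult")
  for (r in seq(0, 1, by = 0.01)) {
    v <- classify_block(r)
    expect_true(v %in% c("too_easy", "difficult", "too_difficult"))
  }
  expect_error(classify_block(1.2), "\\[0, 1\\]")
})

test_that("diagnostics compute omission and false-positive structure", {
  st <- easiest_state()                       # extent 0.4, periphery > 0.24
  b <- make_block(2, 3, state = st, az_om = 0.3, el_om = 0)
  d <- diagnose(b)
  expect_equal(d$omission_periphery_share, 1)
  expect_equal(d$fp_low_salience_share, 0)    # empty-set convention
  expect_equal(d$omission_fraction, 0.6)

  # 6-trial mixed fixture, hand-enumerated: 3 hits, 2 omissions (one
  # peripheral at az=.3, one central at az=.1), 1 low-salience FP
  tr <- rbind(make_trials(n_hit = 3),
              make_trials(n_om = 1, az_om = 0.3),
              make_trials(n_om = 1, az_om = 0.1),
              make_trials(n_fp = 1, fp_low = 1))
  d2 <- diagnose(block_log(1, tr, st))
  expect_equal(d2$success_rate, 3 / 5)
  expect_equal(d2$omission_fraction, 2 / 5)
  expect_equal(d2$omission_periphery_share, 1 / 2)
  expect_equal(d2$false_positive_count, 1)
  expect_equal(d2$fp_low_salience_share, 1)
})

test_that("adjustment follows the decision table and clamps at bounds", {
  hard <- hardest_state()
  d_easy <- diagnose(make_block(24, 0, state = hard))
  unchanged <- adjust(hard, "too_easy", d_easy)
  expect_equal(total_difficulty(unchanged), total_difficulty(hard))

  # peripheral omissions shrink the area and restore one cue stage
  st <- difficulty_state(area_level = 3, exposure_level = 2,
                         cue_mode = "none")
  d_per <- diagnose(make_block(1, 4, state = st, az_om = 0.5))
  expect_equal(d_per$omission_periphery_share, 1)
  adj <- adjust(st, "too_difficult", d_per)
  expect_equal(adj$area_level, 2L)
  expect_identical(adj$cue_mode, "auditory_spatial")

  # low-salience false positives reduce the salience mix
  st2 <- difficulty_state(salience_mix = 0.5, n_distractors = 8)
  d_fp <- diagnose(make_block(2, 3, n_fp = 4, fp_low = 4, state = st2))
  adj2 <- adjust(st2, "too_difficult", d_fp)
  expect_equal(adj2$salience_mix, 0.25)

  # in-band verdicts leave the total difficulty index unchanged
  st3 <- difficulty_state(exposure_level = 3, area_level = 2)
  d_mid <- diagnose(make_block(3, 2, state = st3, az_om = 0.2))
  adj3 <- adjust(st3, "difficult", d_mid)
  expect_equal(total_difficulty(adj3), total_difficulty(st3))
})

test_that("repeated verdicts reach the bounds in finitely many steps", {
  st <- easiest_state()
  d <- diagnose(make_block(24, 0, state = st))
  for (i in 1:60) st <- adjust(st, "too_easy", d)
  expect_equal(total_difficulty(st), total_difficulty(hardest_state()))

  st2 <- hardest_state()
  d2 <- diagnose(make_block(1, 23, state = st2, az_om = 0.2))
  for (i in 1:60) st2 <- adjust(st2, "too_difficult", d2)
  expect_equal(total_difficulty(st2), 0)

  # bounds are never violated along the way
  st3 <- easiest_state()
  for (i in 1:40) {
    st3 <- adjust(st3, sample(c("too_easy", "too_difficult"), 1),
                  diagnose(make_block(2, 2, state = st3, az_om = 0.3)))
    expect_gte(st3$exposure_level, 0); expect_lte(st3$exposure_level, 6)
    expect_gte(st3$area_level, 0); expect_lte(st3$area_level, 6)
    expect_gte(st3$n_distractors, 0); expect_lte(st3$n_distractors, 23)
    expect_gte(st3$salience_mix, 0); expect_lte(st3$salience_mix, 1)
  }
})

test_that("block size grows monotonically with difficulty within 1..24", {
  expect_equal(trials_for_block(easiest_state()), 4L)
  expect_equal(trials_for_block(hardest_state()), 24L)
  idx <- c(0, 1, 2.5, 4, 6, 8, 10, 15, 21.75)
  sizes <- sapply(idx, function(i) {
    lev <- min(6L, floor(i))
    st <- difficulty_state(exposure_level = lev,
                           area_level = min(6L, max(0L, floor(i) - 6L)),
                           n_distractors = round(min(23, max(0, (i - 12) * 4))),
                           salience_mix = if (i > 21) 1 else 0,
                           cue_mode = if (i >= 21) "none"
                                      else "visual_and_auditory")
    trials_for_block(st)
  })
  expect_true(all(diff(sizes) >= 0))
  expect_true(all(sizes >= 1 & sizes <= 24))
})

test_that("block logs enforce the trial-event invariants", {
  tr <- make_trials(n_hit = 2)
  tr$latency[1] <- NA                         # hit without latency
  expect_error(block_log(1, tr, easiest_state()), "latency")
  tr2 <- rbind(make_trials(n_hit = 1), make_trials(n_fp = 1))
  tr2$salience[2] <- "none"                   # false positive needs salience
  expect_error(block_log(1, tr2, easiest_state()), "salience")
  # a block of only distractor strikes has no target trials
  expect_error(block_log(1, make_trials(n_fp = 2, fp_low = 1),
                         easiest_state()), "1 to 24")
})
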