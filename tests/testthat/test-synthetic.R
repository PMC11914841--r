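test_that("success probability is logistic in the skill-difficulty gap", {
  st <- difficulty_state(exposure_level = 2, area_level = 2)   # index 4
  learner <- learner_profile(baseline_skill = 4, asymptote_skill = 4,
                             learning_rate = 0)
  expect_equal(success_probability(learner, st, 0), 0.5)
  expect_equal(success_probability(learner, st, 50), 0.5)      # no learning

  grow <- learner_profile(baseline_skill = 4, asymptote_skill = 10,
                          learning_rate = 0.1)
  p <- sapply(0:30, function(b) success_probability(grow, st, b))
  expect_true(all(diff(p) > 0))

  # strictly decreasing over a difficulty sweep at fixed practice
  ps <- sapply(0:6, function(l)
    success_probability(grow, difficulty_state(exposure_level = l), 5))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0 & ps < 1))
})

test_that("simulated blocks honour forced probabilities and seeds", {
  sure <- learner_profile(baseline_skill = 1000, asymptote_skill = 1000,
                          learning_rate = 0, fp_propensity = 0)
  st <- difficulty_state(n_distractors = 10, salience_mix = 0.5)
  set.seed(1)
  b <- simulate_block(sure, st, 1)
  expect_true(all(b$trials$kind == "hit"))

  set.seed(42); b1 <- simulate_block(sure, st, 1)
  set.seed(42); b2 <- simulate_block(sure, st, 1)
  expect_identical(b1, b2)
})

test_that("empirical hit fraction matches the specified probability", {
  st <- easiest_state()                                    # index 0
  learner <- learner_profile(baseline_skill = 1, asymptote_skill = 1,
                             learning_rate = 0, slope = 1,
                             fp_propensity = 0, periphery_penalty = 0)
  p <- stats::plogis(1)
  set.seed(7)
  hits <- 0; n <- 0
  while (n < 10000) {
    b <- simulate_block(learner, st, 1)
    k <- b$trials$kind
    hits <- hits + sum(k == "hit"); n <- n + length(k)
  }
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(hits / n - p), 2 * se)
})

test_that("generated trajectories obey their spec and reproduce closed forms", {
  line <- ideal_line(c(0, 0, 0), c(0.3, 0, 0))
  clean <- generate_trajectory(
    trajectory_gen_spec(line, duration = 2, mean_speed = 0.15,
                        n_submovements = 1, seed = 6))
  expect_lt(path_error(clean, line), 0.05)
  # SPARC equals the single-burst value computed from the analytic profile
  t <- clean$t
  v_an <- minjerk_speed(t, 0.3, 2)
  ss_an <- structure(data.frame(t = t, v = v_an), nominal_rate = 60,
                     class = c("speed_series", "data.frame"))
  expect_equal(sparc(speed_profile(clean)), sparc(ss_an), tolerance = 0.02)

  dev <- generate_trajectory(
    trajectory_gen_spec(line, duration = 2, mean_speed = 0.15,
                        deviation_amp = 2, seed = 6))
  expect_equal(path_error(dev, line), 2 / sqrt(2), tolerance = 0.02)

  s1 <- generate_trajectory(trajectory_gen_spec(line, seed = 9,
                                                noise_sd = 0.2))
  s2 <- generate_trajectory(trajectory_gen_spec(line, seed = 9,
                                                noise_sd = 0.2))
  s3 <- generate_trajectory(trajectory_gen_spec(line, seed = 10,
                                                noise_sd = 0.2))
  expect_identical(s1, s2)
  expect_false(identical(s1$x, s3$x))

  expect_error(generate_trajectory(
    trajectory_gen_spec(line, duration = 0.05)), "8 samples")
})

test_that("trajectory generation is monotone in its difficulty knobs", {
  circ <- ideal_circle(radius = 0.15)
  errs <- sapply(c(0.5, 1, 2, 3), function(a)
    path_error(generate_trajectory(
      trajectory_gen_spec(circ, duration = 3, mean_speed = 0.3,
                          deviation_amp = a, seed = 3)), circ))
  expect_true(all(diff(errs) > 0))

  sp <- sapply(1:4, function(ns)
    sparc(speed_profile(generate_trajectory(
      trajectory_gen_spec(circ, duration = 3, mean_speed = 0.3,
                          n_submovements = ns, seed = 3)))))
  expect_true(all(diff(sp) < 0))

  line <- ideal_line(c(0, 0, 0), c(0.3, 0, 0))
  sat_slow <- compute_sat(generate_trajectory(
    trajectory_gen_spec(line, duration = 2, mean_speed = 0.15,
                        deviation_amp = 1, seed = 4)), line)
  sat_fast <- compute_sat(generate_trajectory(
    trajectory_gen_spec(line, duration = 1, mean_speed = 0.3,
                        deviation_amp = 1, seed = 4)), line)
  expect_gt(sat_fast, sat_slow)
})

test_that("cohorts reproduce degenerate and typed outcomes", {
  oc <- default_cohort_outcomes()
  oc$d_t1 <- 0; oc$d_t2 <- 0; oc$noise_sd <- 1e-12
  tab <- generate_cohort(cohort_spec(n_participants = 6, outcomes = oc,
                                     seed = 5))
  wide <- outcome_wide(tab, "sat_line")
  expect_equal(wide[, "T0"], wide[, "T1"], tolerance = 1e-9)
  expect_equal(wide[, "T0"], wide[, "T2"], tolerance = 1e-9)

  tab2 <- generate_cohort(cohort_spec(n_participants = 20, seed = 8))
  bbt <- tab2$value[tab2$outcome_name == "bbt_vr"]
  expect_true(all(bbt >= 0))
  expect_true(all(bbt == round(bbt)))

  t_a <- generate_cohort(cohort_spec(seed = 21))
  t_b <- generate_cohort(cohort_spec(seed = 21))
  t_c <- generate_cohort(cohort_spec(seed = 22))
  expect_identical(t_a, t_b)
  expect_false(identical(t_a$value, t_c$value))
})
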