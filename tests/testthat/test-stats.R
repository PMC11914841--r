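wide_fixture_4x3 <- function() {
  # 4 participants x 3 time points, values chosen by hand
  matrix(c(2, 4, 3, 5,
           4, 5, 5, 7,
           5, 6, 6, 8),
         nrow = 4, dimnames = list(paste0("P", 1:4), c("T0", "T1", "T2")))
}

test_that("repeated-measures ANOVA matches the direct decomposition", {
  w <- wide_fixture_4x3()
  res <- rm_anova(w)
  oracle <- rm_anova_oracle(w)
  expect_equal(res$statistic, oracle$F, tolerance = 1e-12)
  expect_equal(res$df, c(2, 6))
  expect_equal(res$p_value, oracle$p, tolerance = 1e-12)
  expect_equal(res$effect_size_value, oracle$eta2, tolerance = 1e-12)

  same <- matrix(rep(c(1, 4, 2, 3), 3), nrow = 4,
                 dimnames = list(paste0("P", 1:4), c("T0", "T1", "T2")))
  expect_equal(rm_anova(same)$statistic, 0)
})

test_that("ANOVA F is invariant to per-participant constants", {
  w <- wide_fixture_4x3()
  shifted <- w + matrix(c(10, -3, 0.5, 100), 4, 3)
  expect_equal(rm_anova(shifted)$statistic, rm_anova(w)$statistic,
               tolerance = 1e-9)
})

test_that("Friedman chi-square matches hand-computed ranks", {
  w3 <- matrix(c(1, 2, 5,
                 2, 3, 6,
                 3, 1, 4),
               nrow = 3, byrow = FALSE,
               dimnames = list(paste0("P", 1:3), c("T0", "T1", "T2")))
  # hand ranks per row -> rank sums, chi2 = 12/(n k (k+1)) sum Rj^2 - 3n(k+1)
  res <- friedman_rm(w3)
  expect_equal(res$statistic, friedman_oracle(w3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$effect_size_value, res$statistic / (3 * 2))

  # strictly increasing for all 20 participants: maximal chi2 = 2n
  up <- matrix(rep(c(1, 2, 3), each = 20), 20,
               dimnames = list(sprintf("P%02d", 1:20), c("T0", "T1", "T2")))
  expect_equal(friedman_rm(up)$statistic, 2 * 20, tolerance = 1e-12)
  expect_equal(friedman_rm(up)$statistic, friedman_oracle(up))

  same <- matrix(rep(c(1, 4, 2), 3), nrow = 3,
                 dimnames = list(paste0("P", 1:3), c("T0", "T1", "T2")))
  expect_equal(friedman_rm(same)$statistic, 0)
})

test_that("Friedman chi-square is invariant to monotone transforms", {
  set.seed(31)
  w <- matrix(stats::rlnorm(30), 10, 3,
              dimnames = list(sprintf("P%02d", 1:10), c("T0", "T1", "T2")))
  base <- friedman_rm(w)$statistic
  expect_equal(friedman_rm(exp(w))$statistic, base, tolerance = 1e-12)
  expect_equal(friedman_rm(w^3)$statistic, base, tolerance = 1e-12)
})

test_that("normality gate routes by Shapiro-Wilk and flags constants", {
  set.seed(12)
  w <- matrix(stats::rnorm(60), 20, 3,
              dimnames = list(sprintf("P%02d", 1:20), c("T0", "T1", "T2")))
  g <- normality_gate(w)
  expect_true(g$route %in% c("parametric", "nonparametric"))
  expect_length(g$shapiro_p, 3)

  wc <- w; wc[, 2] <- 5
  expect_warning(gc <- normality_gate(wc), "constant")
  expect_identical(gc$route, "nonparametric")

  # Monte-Carlo: the gate routes as the marginal Shapiro tests dictate
  routes_norm <- routes_lnorm <- logical(100)
  set.seed(99)
  for (i in 1:100) {
    wn <- matrix(stats::rnorm(60), 20, 3,
                 dimnames = list(sprintf("P%02d", 1:20), c("T0", "T1", "T2")))
    wl <- matrix(stats::rlnorm(60, sdlog = 1), 20, 3,
                 dimnames = dimnames(wn))
    routes_norm[i] <- normality_gate(wn)$route == "parametric"
    routes_lnorm[i] <- normality_gate(wl)$route == "nonparametric"
  }
  # all-three-pass probability under normality is (1 - alpha)^3 ~ 0.857
  expect_gt(mean(routes_norm), 0.75)
  expect_lt(mean(routes_norm), 0.95)
  expect_gt(mean(routes_lnorm), 0.9)
})

test_that("parametric post hocs match the paired-t closed form", {
  a <- c(3.1, 4.2, 2.8, 5.0, 3.9)
  b <- c(3.9, 4.8, 3.1, 6.2, 4.1)
  w <- cbind(T0 = a, T1 = b, T2 = b + 0.5)
  rownames(w) <- paste0("P", 1:5)
  ph <- posthoc(w, "parametric")
  d <- b - a
  t_hand <- mean(d) / (stats::sd(d) / sqrt(5))
  row01 <- ph[ph$contrast == "T0vT1", ]
  expect_equal(row01$statistic, t_hand, tolerance = 1e-10)
  p_raw <- 2 * stats::pt(abs(t_hand), 4, lower.tail = FALSE)
  expect_equal(row01$adjusted_p, min(1, 3 * p_raw), tolerance = 1e-10)
  j <- 1 - 3 / (4 * 4 - 1)
  expect_equal(row01$effect_size_value, j * mean(d) / stats::sd(d),
               tolerance = 1e-10)

  # identical columns give adjusted p = 1 and d = 0
  w2 <- cbind(T0 = a, T1 = a, T2 = b)
  ph2 <- posthoc(w2, "parametric")
  expect_equal(ph2[ph2$contrast == "T0vT1", "adjusted_p"], 1)
  expect_equal(ph2[ph2$contrast == "T0vT1", "effect_size_value"], 0)
})

test_that("nonparametric post hocs use rank sums with the Tukey tail", {
  set.seed(5)
  w <- matrix(stats::rnorm(60), 20, 3,
              dimnames = list(sprintf("P%02d", 1:20), c("T0", "T1", "T2")))
  w[, 2] <- w[, 2] + 1.5
  ph <- posthoc(w, "nonparametric")
  expect_setequal(ph$contrast, c("T0vT1", "T0vT2", "T1vT2"))
  # hand-computed statistic for one contrast
  rs <- colSums(t(apply(w, 1, rank)))
  q_hand <- abs(rs["T1"] - rs["T0"]) / sqrt(20 * 3 * 4 / 12) * sqrt(2)
  row <- ph[ph$contrast == "T0vT1", ]
  expect_equal(row$statistic, unname(q_hand), tolerance = 1e-12)
  expect_equal(row$adjusted_p, 1 - stats::ptukey(q_hand, 3, Inf),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(row$effect_size_value, unname(q_hand / sqrt(2) / sqrt(20)),
               tolerance = 1e-12)
  expect_true(all(ph$adjusted_p >= 0 & ph$adjusted_p <= 1))
})

test_that("the full study analysis isolates outcomes and reports both routes", {
  tab <- generate_cohort(cohort_spec(n_participants = 20, seed = 14))
  rep <- run_study_analysis(tab)
  expect_setequal(rep$omnibus$outcome, default_cohort_outcomes()$outcome)
  expect_true(all(rep$omnibus$p_value >= 0 & rep$omnibus$p_value <= 1))
  expect_true(all(rep$pairwise$adjusted_p >= 0 & rep$pairwise$adjusted_p <= 1))
  # the configured strong effects are detected, the null reaction time is not
  omn <- rep$omnibus
  expect_true(omn$significant[omn$outcome == "sat_line"])
  expect_false(omn$significant[omn$outcome == "reaction_time_ms"])

  # a broken outcome must not abort the others
  bad <- tab[!(tab$outcome_name == "sat_line" & tab$time_point != "T0"), ]
  rep2 <- run_study_analysis(bad)
  expect_true("sat_line" %in% names(rep2$errors))
  expect_true("bbt_vr" %in% rep2$omnibus$outcome)

  expect_error(run_study_analysis(tab[0, ]), "empty")
})
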