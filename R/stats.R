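#' Reshape one outcome of an outcome table to wide complete cases
#'
#' @param table An `outcome_table`.
#' @param outcome Outcome name to extract.
#' @return Matrix participants x time points (T0, T1, T2), complete
#'   cases only, with attribute `"n_dropped"` giving the listwise
#'   deletion count.
#' @export
outcome_wide <- function(table, outcome) {
  sub <- table[table$outcome_name == outcome, , drop = FALSE]
  if (!nrow(sub))
    stop(sprintf("outcome '%s' not present in table", outcome),
         call. = FALSE)
  tps <- sort(unique(sub$time_point))
  ids <- unique(sub$participant_id)
  m <- matrix(NA_real_, length(ids), length(tps),
              dimnames = list(ids, tps))
  m[cbind(match(sub$participant_id, ids), match(sub$time_point, tps))] <-
    sub$value
  keep <- stats::complete.cases(m)
  out <- m[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Normality gate for the repeated-measures analysis
#'
#' Runs a Shapiro-Wilk test on each time point's values; the analysis
#' route is parametric only when every time point passes (p > alpha).
#' A constant column is routed nonparametric with a warning, since
#' normality is untestable there.
#'
#' @param wide Matrix participants x time points (see [outcome_wide()]).
#' @param alpha Gate level, default 0.05.
#' @return List with `route` (`"parametric"` or `"nonparametric"`) and
#'   `shapiro_p` (per-time-point p values, `NA` for constant columns).
#' @export
normality_gate <- function(wide, alpha = 0.05) {
  if (nrow(wide) < 3)
    stop("normality_gate: need at least 3 complete cases", call. = FALSE)
  p <- apply(wide, 2L, function(col) {
    if (stats::sd(col) == 0) NA_real_ else stats::shapiro.test(col)$p.value
  })
  if (anyNA(p)) {
    warning("constant values at one or more time points; ",
            "routing nonparametric", call. = FALSE)
    route <- "nonparametric"
  } else {
    route <- if (all(p > alpha)) "parametric" else "nonparametric"
  }
  list(route = route, shapiro_p = p)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject one-way ANOVA over the time points, fitted with
#' [stats::aov()] using a participant error stratum; degrees of freedom
#' are `(k - 1, (n - 1)(k - 1))`. The effect size is partial eta squared,
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param wide Matrix participants x time points, complete cases.
#' @return List of class `test_result`: `test_name`, `statistic`, `df`
#'   (length 2), `p_value`, `effect_size_name` (`"eta2"`),
#'   `effect_size_value`, `n`.
#' @export
rm_anova <- function(wide) {
  n <- nrow(wide); k <- ncol(wide)
  if (n < 3) stop("rm_anova: need at least 3 participants", call. = FALSE)
  long <- data.frame(
    value = as.vector(wide),
    time = factor(rep(colnames(wide), each = n)),
    id = factor(rep(rownames(wide), k)))
  fit <- stats::aov(value ~ time + Error(id), data = long)
  tab <- summary(fit)[["Error: Within"]][[1L]]
  ss_t <- tab["time", "Sum Sq"]
  ss_e <- tab["Residuals", "Sum Sq"]
  f <- tab["time", "F value"]
  # identical columns leave only rounding noise in both sums of squares
  eps <- 1e-12 * max(1, sum(wide^2))
  degen <- is.na(f) || (ss_t < eps && ss_e < eps)
  structure(list(test_name = "rm_anova",
                 statistic = if (degen) 0 else f,
                 df = c(k - 1, (n - 1) * (k - 1)),
                 p_value = if (degen) 1 else tab["time", "Pr(>F)"],
                 effect_size_name = "eta2",
                 effect_size_value = if (degen) 0 else ss_t / (ss_t + ss_e),
                 n = n),
            class = "test_result")
}

#' Friedman test over the time points
#'
#' Friedman rank test (mid-ranks for ties, via [stats::friedman.test()])
#' with `k - 1` degrees of freedom. The effect size is epsilon squared
#' under the `chi^2 / (n (k - 1))` convention (equivalent to Kendall's
#' W); the convention is recorded in the result.
#'
#' @param wide Matrix participants x time points, complete cases.
#' @return A `test_result` with `effect_size_name = "epsilon2"` and
#'   `effect_size_note` naming the convention.
#' @export
friedman_rm <- function(wide) {
  n <- nrow(wide); k <- ncol(wide)
  if (n < 3) stop("friedman_rm: need at least 3 participants", call. = FALSE)
  ft <- stats::friedman.test(wide)
  chi <- unname(ft$statistic)
  if (is.na(chi)) chi <- 0
  structure(list(test_name = "friedman",
                 statistic = chi,
                 df = k - 1,
                 p_value = if (is.na(ft$p.value)) 1 else ft$p.value,
                 effect_size_name = "epsilon2",
                 effect_size_value = chi / (n * (k - 1)),
                 effect_size_note = "epsilon2 = chi2 / (n (k - 1))",
                 n = n),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: stat %.3f, df %s, p %.4g, %s %.3f\n",
              x$test_name, x$statistic,
              paste(x$df, collapse = ","), x$p_value,
              x$effect_size_name, x$effect_size_value))
  invisible(x)
}

# paired t contrast with Bonferroni adjustment and small-sample
# corrected paired Cohen d; computed in closed form so that degenerate
# (zero-variance) differences are well defined instead of an error
paired_contrast <- function(a, b, m) {
  d <- a - b
  n <- length(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (mean(d) == 0) return(list(statistic = 0, p = 1, adj_p = 1,
                                  effect = 0))
    return(list(statistic = sign(mean(d)) * Inf, p = 0, adj_p = 0,
                effect = sign(mean(d)) * Inf))
  }
  t_stat <- mean(d) / (sdd / sqrt(n))
  p <- 2 * stats::pt(abs(t_stat), n - 1, lower.tail = FALSE)
  j <- 1 - 3 / (4 * (n - 1) - 1)               # Hedges correction
  list(statistic = t_stat, p = p, adj_p = min(1, m * p),
       effect = j * mean(d) / sdd)
}

#' Post-hoc pairwise comparisons across time points
#'
#' Parametric route: paired t tests for every time-point pair with
#' Bonferroni-adjusted p values and the small-sample (Hedges-corrected)
#' paired Cohen d. Nonparametric route: the Tukey-style studentized-range
#' statistic on Friedman rank sums,
#' `q = |R_i - R_j| / sqrt(n k (k + 1) / 12) * sqrt(2)` referred to the
#' studentized range distribution with `k` groups and infinite df, with
#' effect size Cohen `r = |z| / sqrt(n)` where `z = q / sqrt(2)`.
#'
#' @param wide Matrix participants x time points, complete cases.
#' @param route `"parametric"` or `"nonparametric"` (from
#'   [normality_gate()]).
#' @return Data frame with one row per contrast: `contrast`,
#'   `statistic`, `adjusted_p`, `effect_size_name`, `effect_size_value`.
#' @export
posthoc <- function(wide, route = c("parametric", "nonparametric")) {
  route <- match.arg(route)
  k <- ncol(wide); n <- nrow(wide)
  pairs <- utils::combn(colnames(wide), 2L)
  if (route == "parametric") {
    m <- ncol(pairs)
    rows <- apply(pairs, 2L, function(pr) {
      ct <- paired_contrast(wide[, pr[2L]], wide[, pr[1L]], m)
      data.frame(contrast = paste0(pr[1L], "v", pr[2L]),
                 statistic = ct$statistic, adjusted_p = ct$adj_p,
                 effect_size_name = "cohen_d",
                 effect_size_value = ct$effect,
                 stringsAsFactors = FALSE)
    })
  } else {
    ranks <- t(apply(wide, 1L, rank))          # mid-ranks within participant
    rs <- colSums(ranks)
    se <- sqrt(n * k * (k + 1) / 12)
    rows <- apply(pairs, 2L, function(pr) {
      q <- abs(rs[pr[2L]] - rs[pr[1L]]) / se * sqrt(2)
      z <- q / sqrt(2)
      data.frame(contrast = paste0(pr[1L], "v", pr[2L]),
                 statistic = unname(q),
                 adjusted_p = 1 - stats::ptukey(q, k, Inf),
                 effect_size_name = "cohen_r",
                 effect_size_value = unname(z / sqrt(n)),
                 stringsAsFactors = FALSE)
    })
  }
  do.call(rbind, rows)
}

#' Run the full gated repeated-measures analysis of an outcome table
#'
#' For every outcome in the table: listwise deletion to complete cases,
#' Shapiro-Wilk normality gate, then either one-way repeated-measures
#' ANOVA with Bonferroni-adjusted paired t post hocs (parametric route)
#' or the Friedman test with Tukey-style rank post hocs (nonparametric
#' route), at level `alpha`. A failure in one outcome is recorded and
#' does not abort the others.
#'
#' @param table An `outcome_table` with time points T0, T1, T2.
#' @param alpha Significance level, default 0.05.
#' @return List of class `study_report` with `omnibus` (one row per
#'   outcome: route, statistic, df, p, effect size, n, dropped cases,
#'   significance flag) and `pairwise` (post-hoc rows for all outcomes),
#'   plus `alpha` and `errors` (named character of per-outcome failure
#'   messages, empty when clean).
#' @export
run_study_analysis <- function(table, alpha = 0.05) {
  if (!nrow(table))
    stop("run_study_analysis: empty outcome table", call. = FALSE)
  outcomes <- unique(table$outcome_name)
  omni <- list(); pw <- list(); errs <- character()
  for (oc in outcomes) {
    res <- tryCatch({
      wide <- outcome_wide(table, oc)
      gate <- suppressWarnings(normality_gate(wide, alpha))
      omn <- if (gate$route == "parametric") rm_anova(wide)
             else friedman_rm(wide)
      ph <- posthoc(wide, gate$route)
      ph$outcome <- oc
      list(omnibus = data.frame(
             outcome = oc, route = gate$route, test = omn$test_name,
             statistic = omn$statistic, df1 = omn$df[1L],
             df2 = if (length(omn$df) > 1L) omn$df[2L] else NA_real_,
             p_value = omn$p_value,
             effect_size_name = omn$effect_size_name,
             effect_size_value = omn$effect_size_value,
             n = omn$n, n_dropped = attr(wide, "n_dropped"),
             significant = omn$p_value < alpha,
             stringsAsFactors = FALSE),
           pairwise = ph)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[oc] <- conditionMessage(res)
    } else {
      omni[[oc]] <- res$omnibus
      pw[[oc]] <- res$pairwise
    }
  }
  structure(list(omnibus = do.call(rbind, c(omni, list(make.row.names = FALSE))),
                 pairwise = do.call(rbind, c(pw, list(make.row.names = FALSE))),
                 alpha = alpha, errors = errs),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> alpha = %g\n", x$alpha))
  print(x$omnibus, row.names = FALSE)
  if (length(x$errors))
    cat("failed outcomes:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
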