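# Language-task scoring (category naming fluency, 30-item confrontation
# naming), z-scoring against a control reference, and group-comparison
# statistics (t, one-way F, Pearson chi-square) recomputable from
# published summary tables.

#' Score category naming fluency
#'
#' Counts unique valid category exemplars produced within the time
#' window: responses are case-folded, trimmed, deduplicated, filtered by
#' the category criterion, and restricted to `window_s` seconds when
#' onset times are given.
#'
#' @param responses character vector of produced words.
#' @param category either a character vector of acceptable words or a
#'   predicate function `word -> logical`.
#' @param times_s optional numeric vector of response onsets (seconds
#'   from task start); responses after `window_s` are excluded.
#' @param window_s scoring window in seconds (default 60).
#' @return integer total score.
#' @export
score_category_fluency <- function(responses, category, times_s = NULL,
                                   window_s = 60) {
  if (length(responses) == 0L) return(0L)
  w <- tolower(trimws(as.character(responses)))
  if (!is.null(times_s)) {
    if (length(times_s) != length(w))
      abort("score_category_fluency: times_s length mismatch")
    w <- w[times_s <= window_s]
  }
  w <- unique(w[nzchar(w)])
  ok <- if (is.function(category)) {
    vapply(w, function(x) isTRUE(category(x)), logical(1))
  } else {
    w %in% tolower(trimws(as.character(category)))
  }
  sum(ok)
}

#' Score a 30-item confrontation-naming test
#'
#' Number of stimuli correctly named against a 30-item answer key,
#' case-insensitively; unanswered items (NA or empty) are incorrect.
#'
#' @param responses character vector of length 30 (one response per
#'   stimulus, in key order).
#' @param key character vector of 30 target names.
#' @return integer score, 0-30.
#' @export
score_bnt <- function(responses, key) {
  if (length(key) != 30L)
    abort("score_bnt: answer key must have exactly 30 items, got ", length(key))
  if (length(responses) != 30L)
    abort("score_bnt: expected 30 responses, got ", length(responses))
  r <- tolower(trimws(as.character(responses)))
  k <- tolower(trimws(as.character(key)))
  sum(!is.na(r) & nzchar(r) & r == k)
}

#' z-score against a reference cohort
#'
#' @param raw numeric raw score(s).
#' @param ref_mean,ref_sd reference (control cohort) mean and SD;
#'   `ref_sd` must be positive.
#' @return `(raw - ref_mean) / ref_sd`.
#' @export
zscore <- function(raw, ref_mean, ref_sd) {
  if (!is.finite(ref_sd) || ref_sd <= 0)
    abort("zscore: reference sd must be positive")
  (raw - ref_mean) / ref_sd
}

#' Group summary (n, mean, sd)
#'
#' @param label group label.
#' @param n group size (>= 2).
#' @param mean,sd summary statistics; `sd > 0`.
#' @return an object of class `group_summary`.
#' @export
group_summary <- function(label, n, mean, sd) {
  if (n < 2L) abort("group_summary: n must be >= 2")
  if (!is.finite(sd) || sd <= 0) abort("group_summary: sd must be > 0")
  structure(list(label = label, n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

#' Pooled two-sample t-test from group summaries
#'
#' Student (pooled-variance) t with `df = n_a + n_b - 2` and a
#' two-sided p-value, computed from the groups' n/mean/sd only — the
#' form needed to recompute published comparisons from summary tables.
#'
#' @param a,b [group_summary()] objects.
#' @return list with `t`, `df`, `p`.
#' @export
summary_ttest <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  df <- a$n + b$n - 2L
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' One-way ANOVA from group summaries
#'
#' Between-group mean square from group means about the size-weighted
#' grand mean; within-group mean square from pooled SDs.
#'
#' @param groups list of [group_summary()] objects (>= 2).
#' @return list with `F`, `df_between`, `df_within`, `p`.
#' @export
summary_anova <- function(groups) {
  if (length(groups) < 2L) abort("summary_anova: need >= 2 groups")
  for (g in groups) stopifnot(inherits(g, "group_summary"))
  n <- vapply(groups, `[[`, numeric(1), "n")
  m <- vapply(groups, `[[`, numeric(1), "mean")
  s <- vapply(groups, `[[`, numeric(1), "sd")
  N <- sum(n)
  grand <- sum(n * m) / N
  df_b <- length(groups) - 1L
  df_w <- N - length(groups)
  msb <- sum(n * (m - grand)^2) / df_b
  msw <- sum((n - 1) * s^2) / df_w
  f <- msb / msw
  list(F = f, df_between = df_b, df_within = df_w,
       p = stats::pf(f, df_b, df_w, lower.tail = FALSE))
}

#' Pearson chi-square test of a contingency table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square with
#' `df = (r - 1)(c - 1)`.
#'
#' @param counts integer matrix (at least 2 x 2) of counts; dimnames
#'   optional.
#' @return list with `chisq`, `df`, `p`, `n`.
#' @export
chisq_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    abort("chisq_counts: table must be at least 2 x 2")
  if (any(counts < 0)) abort("chisq_counts: counts must be non-negative")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0))
    abort("chisq_counts: zero marginal; test undefined")
  n <- sum(counts)
  expected <- outer(rs, cs) / n
  chisq <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  list(chisq = chisq, df = df, p = stats::pchisq(chisq, df, lower.tail = FALSE),
       n = n)
}

# bundled fixture of the cohort summary table --------------------------------

table1_summaries_path <- function() {
  system.file("extdata", "cohort_summaries.csv", package = "tractfa",
              mustWork = TRUE)
}

table1_sex_path <- function() {
  system.file("extdata", "cohort_sex_counts.csv", package = "tractfa",
              mustWork = TRUE)
}

#' Recompute the cohort group comparisons from bundled summaries
#'
#' Reruns every demographic/behavioral group comparison from the
#' bundled summary fixture (group n/mean/sd per measure plus sex
#' counts): one-way F across the three groups for age and education, a
#' sex chi-square, and patient-vs-patient pooled t-tests for MMSE,
#' disease duration, category fluency (Animals), and confrontation
#' naming (BNT).
#'
#' @param summaries_csv,sex_csv paths to the summary fixtures; defaults
#'   to the files bundled with the package.
#' @return data.frame with columns `measure`, `test`, `statistic`,
#'   `df1`, `df2`, `p`.
#' @export
table1_comparisons <- function(summaries_csv = table1_summaries_path(),
                               sex_csv = table1_sex_path()) {
  sm <- utils::read.csv(summaries_csv, stringsAsFactors = FALSE)
  sx <- utils::read.csv(sex_csv, stringsAsFactors = FALSE)
  gs <- function(measure, group) {
    row <- sm[sm$measure == measure & sm$group == group, ]
    if (nrow(row) != 1L) abort("table1_comparisons: missing summary ",
                               measure, "/", group)
    group_summary(group, row$n, row$mean, row$sd)
  }
  out <- list()
  for (meas in c("age", "education")) {
    a <- summary_anova(list(gs(meas, "lvPPA"), gs(meas, "svPPA"),
                            gs(meas, "control")))
    out[[length(out) + 1L]] <- data.frame(
      measure = meas, test = "anova_F", statistic = a$F,
      df1 = a$df_between, df2 = a$df_within, p = a$p)
  }
  counts <- as.matrix(sx[, c("male", "female")])
  rownames(counts) <- sx$group
  cx <- chisq_counts(counts)
  out[[length(out) + 1L]] <- data.frame(
    measure = "sex", test = "chisq", statistic = cx$chisq,
    df1 = cx$df, df2 = NA_real_, p = cx$p)
  for (meas in c("mmse", "duration", "animals_z", "bnt_z")) {
    tt <- summary_ttest(gs(meas, "lvPPA"), gs(meas, "svPPA"))
    out[[length(out) + 1L]] <- data.frame(
      measure = meas, test = "pooled_t", statistic = tt$t,
      df1 = tt$df, df2 = NA_real_, p = tt$p)
  }
  do.call(rbind, out)
}
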