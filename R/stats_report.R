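#' Build and validate a cohort result table
#'
#' One row per case: Goutallier grade, fatty infiltration percentage and
#' occupation ratio.
#'
#' @param case_id character vector, unique.
#' @param grade integer vector in 0..4.
#' @param fi_pct numeric vector in `[0, 100]`.
#' @param occupation_ratio positive numeric vector.
#' @return data frame of class `cohort_table`.
#' @export
cohort_table <- function(case_id, grade, fi_pct, occupation_ratio) {
  if (anyDuplicated(case_id)) {
    stop("case ids must be unique", call. = FALSE)
  }
  grade <- as.integer(grade)
  if (any(grade < 0L | grade > 4L)) {
    stop("grades must lie in 0..4", call. = FALSE)
  }
  if (any(fi_pct < 0 | fi_pct > 100)) {
    stop("fi_pct must lie in [0, 100]", call. = FALSE)
  }
  df <- data.frame(case_id = as.character(case_id), grade = grade,
                   fi_pct = fi_pct, occupation_ratio = occupation_ratio,
                   stringsAsFactors = FALSE)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' One-way ANOVA of fatty infiltration across grades with Bonferroni post hoc
#'
#' Classical one-way analysis of variance of `fi_pct` on `grade`, followed
#' by all pairwise two-sample t-tests with Bonferroni correction (raw p
#' multiplied by the number of comparisons, capped at 1). The per-grade
#' summary reports mean, SD and the observed minimum/maximum (the
#' lower/upper limits of the values; a normal-theory 95% CI is available
#' via `limits = "ci"`).
#'
#' @param table a [cohort_table()].
#' @param limits `"range"` (observed min/max, default) or `"ci"` (95%
#'   normal-theory confidence limits of the mean).
#' @param pool_sd use the pooled-variance two-sample t-test for the post
#'   hoc pairs (default `TRUE`); `FALSE` uses Welch.
#' @return list with `f_statistic`, `df`, `p_value`, `group_summary`
#'   (data frame: grade, n, mean, sd, lower, upper), `pairwise` (data
#'   frame: grade_a, grade_b, p_raw, p_bonferroni), and `degenerate`
#'   (`TRUE` with `NA` statistics when all values are identical).
#' @export
anova_bonferroni <- function(table, limits = c("range", "ci"),
                             pool_sd = TRUE) {
  limits <- match.arg(limits)
  stopifnot(inherits(table, "cohort_table"))
  groups <- split(table$fi_pct, table$grade)
  if (length(groups) < 2L) {
    stop("need at least 2 grade groups", call. = FALSE)
  }
  small <- names(groups)[lengths(groups) < 2L]
  if (length(small) > 0L) {
    stop(sprintf("grade group(s) with fewer than 2 members: %s",
                 paste(small, collapse = ", ")), call. = FALSE)
  }
  gs <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    if (limits == "range") {
      lo <- min(v)
      hi <- max(v)
    } else {
      half <- stats::qt(0.975, length(v) - 1L) * stats::sd(v) /
        sqrt(length(v))
      lo <- mean(v) - half
      hi <- mean(v) + half
    }
    data.frame(grade = as.integer(g), n = length(v), mean = mean(v),
               sd = stats::sd(v), lower = lo, upper = hi)
  }))
  if (stats::var(table$fi_pct) == 0) {
    return(list(f_statistic = NA_real_, df = c(NA_integer_, NA_integer_),
                p_value = NA_real_, group_summary = gs,
                pairwise = NULL, degenerate = TRUE))
  }
  fit <- stats::aov(fi_pct ~ factor(grade), data = table)
  an <- summary(fit)[[1L]]
  pairs <- utils::combn(names(groups), 2L)
  n_cmp <- ncol(pairs)
  pw <- do.call(rbind, apply(pairs, 2L, function(pr) {
    a <- groups[[pr[1L]]]
    b <- groups[[pr[2L]]]
    p_raw <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) NA_real_ else 0
    } else {
      stats::t.test(a, b, var.equal = pool_sd)$p.value
    }
    data.frame(grade_a = as.integer(pr[1L]), grade_b = as.integer(pr[2L]),
               p_raw = p_raw, p_bonferroni = pmin(p_raw * n_cmp, 1))
  }))
  list(
    f_statistic = an[["F value"]][1L],
    df = c(an[["Df"]][1L], an[["Df"]][2L]),
    p_value = an[["Pr(>F)"]][1L],
    group_summary = gs,
    pairwise = pw,
    degenerate = FALSE
  )
}

#' Pearson correlation between occupation ratio and fatty infiltration
#'
#' Product-moment correlation with the two-sided t-based p-value.
#'
#' @param table a [cohort_table()], or a numeric vector when `y` is given.
#' @param y optional second numeric vector.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_or_fi <- function(table, y = NULL) {
  if (inherits(table, "cohort_table")) {
    x <- table$occupation_ratio
    y <- table$fi_pct
  } else {
    x <- table
  }
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in one of the variables", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Weighted kappa between two raters of ordinal grades
#'
#' Cohen's weighted kappa on the 5x5 contingency table of Goutallier
#' grades, with linear (default) or quadratic disagreement weights.
#'
#' @param rater_a,rater_b integer vectors of grades in 0..4, equal length.
#' @param weights `"linear"` or `"quadratic"`.
#' @return list with `kappa`, `weights`, `n`.
#' @export
weighted_kappa <- function(rater_a, rater_b,
                           weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  if (length(rater_a) != length(rater_b)) {
    stop("rating vectors must have equal length", call. = FALSE)
  }
  if (any(c(rater_a, rater_b) < 0L | c(rater_a, rater_b) > 4L)) {
    stop("grades must lie in 0..4", call. = FALSE)
  }
  lev <- 0:4
  obs <- table(factor(rater_a, levels = lev), factor(rater_b, levels = lev))
  obs <- obs / sum(obs)
  exp_ <- outer(rowSums(obs), colSums(obs))
  d <- abs(outer(lev, lev, "-"))
  w <- if (weights == "linear") d / max(d) else (d / max(d))^2
  kappa <- 1 - sum(w * obs) / sum(w * exp_)
  list(kappa = kappa, weights = weights, n = length(rater_a))
}

#' Intraclass correlation coefficient (two-way random, absolute agreement)
#'
#' Single-measure ICC from the standard two-way mean-squares
#' decomposition, ICC(2,1): subjects are random rows, the two measurements
#' random columns, and absolute agreement is assessed (a systematic offset
#' between measurements lowers the coefficient).
#'
#' @param values_a,values_b numeric vectors of paired measurements,
#'   length >= 3.
#' @return list with `icc`, `ms` (mean squares: rows, columns, error),
#'   `n`.
#' @export
icc_agreement <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop("measurement vectors must have equal length", call. = FALSE)
  }
  n <- length(values_a)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  k <- 2L
  dat <- cbind(values_a, values_b)
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  grand <- mean(dat)
  msr <- k * sum((row_means - grand)^2) / (n - 1L)
  msc <- n * sum((col_means - grand)^2) / (k - 1L)
  sse <- sum((dat - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1L) * (k - 1L))
  icc <- (msr - mse) /
    (msr + (k - 1L) * mse + k * (msc - mse) / n)
  list(icc = icc, ms = c(rows = msr, columns = msc, error = mse), n = n)
}

#' Full statistical report for a cohort table
#'
#' Convenience wrapper running the grade-wise ANOVA with Bonferroni post
#' hoc tests and the occupation-ratio/fatty-infiltration Pearson
#' correlation.
#'
#' @param table a [cohort_table()].
#' @param ... passed to [anova_bonferroni()].
#' @return list with `anova` and `correlation`.
#' @export
stats_report <- function(table, ...) {
  list(
    anova = anova_bonferroni(table, ...),
    correlation = pearson_or_fi(table)
  )
}
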