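test_that("one-way ANOVA matches hand-computed sums of squares", {
  # 2 groups x 3 values, textbook decomposition
  fi <- c(1, 2, 3, 7, 8, 9)
  gr <- c(0, 0, 0, 2, 2, 2)
  tab <- cohort_table(sprintf("c%d", 1:6), gr, fi, rep(0.5, 6))
  res <- anova_bonferroni(tab)
  grand <- mean(fi)
  ss_between <- 3 * (mean(fi[1:3]) - grand)^2 + 3 * (mean(fi[4:6]) - grand)^2
  ss_within <- sum((fi[1:3] - mean(fi[1:3]))^2) +
    sum((fi[4:6] - mean(fi[4:6]))^2)
  f_manual <- (ss_between / 1) / (ss_within / 4)
  expect_equal(res$f_statistic, f_manual)
  expect_equal(res$df, c(1L, 4L))
  expect_equal(res$p_value, pf(f_manual, 1, 4, lower.tail = FALSE))
  # per-grade summary carries mean/SD and observed limits
  g0 <- res$group_summary[res$group_summary$grade == 0L, ]
  expect_equal(c(g0$mean, g0$sd, g0$lower, g0$upper), c(2, 1, 1, 3))
})

test_that("grade-structured cohorts separate with p < 0.0001", {
  set.seed(31)
  means <- c(0, 5, 20, 43, 56)
  fi <- pmin(pmax(unlist(lapply(means, function(m) rnorm(40, m, 5))), 0),
             100)
  gr <- rep(0:4, each = 40)
  tab <- cohort_table(sprintf("c%d", 1:200), gr, fi,
                      runif(200, 0.3, 0.9))
  res <- anova_bonferroni(tab)
  expect_lt(res$p_value, 1e-4)
  expect_true(all(res$pairwise$p_bonferroni < 0.05))
  expect_identical(nrow(res$pairwise), 10L)
})

test_that("Bonferroni post hoc equals raw pairwise t-tests times m, capped", {
  set.seed(8)
  fi <- c(rnorm(10, 5), rnorm(10, 6), rnorm(10, 30))
  gr <- rep(c(0, 1, 3), each = 10)
  tab <- cohort_table(sprintf("c%d", 1:30), gr, fi, rep(0.5, 30))
  res <- anova_bonferroni(tab)
  p01 <- t.test(fi[gr == 0], fi[gr == 1], var.equal = TRUE)$p.value
  row01 <- res$pairwise[res$pairwise$grade_a == 0 &
                          res$pairwise$grade_b == 1, ]
  expect_equal(row01$p_raw, p01)
  expect_equal(row01$p_bonferroni, min(p01 * 3, 1))
  # cross-check against the standard pairwise machinery
  std <- pairwise.t.test(fi, factor(gr), p.adjust.method = "bonferroni",
                         pool.sd = FALSE, var.equal = TRUE)
  expect_equal(row01$p_bonferroni, std$p.value["1", "0"])
})

test_that("degenerate inputs are flagged, not silently computed", {
  tab <- cohort_table(sprintf("c%d", 1:6), rep(c(0, 1), each = 3),
                      rep(5, 6), rep(0.5, 6))
  res <- anova_bonferroni(tab)
  expect_true(res$degenerate)
  expect_true(is.na(res$f_statistic))
  expect_error(
    anova_bonferroni(cohort_table(c("a", "b", "c"), c(0, 0, 1),
                                  c(1, 2, 3), rep(0.5, 3))),
    "fewer than 2"
  )
})

test_that("Pearson correlation matches manual computation", {
  # perfectly anticorrelated pairs
  tab <- cohort_table(sprintf("c%d", 1:5), rep(0, 5), (5:1) * 10,
                      seq(0.1, 0.5, 0.1))
  res <- pearson_or_fi(tab)
  expect_equal(res$r, -1)
  # 5-point hand fixture
  x <- c(1, 2, 4, 5, 8)
  y <- c(2, 1, 5, 9, 8)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res2 <- pearson_or_fi(x, y)
  expect_equal(res2$r, r_manual)
  tstat <- r_manual * sqrt(3 / (1 - r_manual^2))
  expect_equal(res2$p_value, 2 * pt(abs(tstat), 3, lower.tail = FALSE))
  expect_error(pearson_or_fi(rep(1, 5), 1:5), "zero variance")
})

test_that("weighted kappa matches the contingency-table formula", {
  expect_equal(weighted_kappa(c(0, 1, 2, 3, 4), c(0, 1, 2, 3, 4))$kappa, 1)

  # 3-case hand fixture, linear weights
  a <- c(0, 2, 4)
  b <- c(0, 3, 4)
  obs <- table(factor(a, levels = 0:4), factor(b, levels = 0:4)) / 3
  ex <- outer(rowSums(obs), colSums(obs))
  w <- abs(outer(0:4, 0:4, "-")) / 4
  expect_equal(weighted_kappa(a, b)$kappa, 1 - sum(w * obs) / sum(w * ex))
  # quadratic weights weigh distant disagreement more
  wq <- (abs(outer(0:4, 0:4, "-")) / 4)^2
  expect_equal(weighted_kappa(a, b, "quadratic")$kappa,
               1 - sum(wq * obs) / sum(wq * ex))

  # independent shuffled ratings: kappa near zero
  set.seed(77)
  r1 <- sample(0:4, 4000, replace = TRUE)
  r2 <- sample(0:4, 4000, replace = TRUE)
  expect_lt(abs(weighted_kappa(r1, r2)$kappa), 0.05)
  expect_error(weighted_kappa(0:2, 0:3), "equal length")
})

test_that("ICC(2,1) matches the mean-squares decomposition", {
  expect_equal(icc_agreement(c(1, 5, 9), c(1, 5, 9))$icc, 1)

  # 6-subject two-rater fixture: oracle from the two-way ANOVA table
  a <- c(9, 6, 8, 7, 10, 6)
  b <- c(2, 1, 4, 1, 5, 2)
  dat <- data.frame(y = c(a, b),
                    subj = factor(rep(1:6, 2)),
                    rater = factor(rep(1:2, each = 6)))
  ms <- anova(aov(y ~ subj + rater, data = dat))[["Mean Sq"]]
  icc_manual <- (ms[1] - ms[3]) /
    (ms[1] + ms[3] + 2 * (ms[2] - ms[3]) / 6)
  expect_equal(icc_agreement(a, b)$icc, icc_manual)

  # large independent noise destroys agreement
  set.seed(19)
  base <- rnorm(200, 50, 5)
  noisy <- base + rnorm(200, 0, 60)
  expect_lt(abs(icc_agreement(base, noisy)$icc), 0.2)
  expect_error(icc_agreement(1:2, 1:2), "at least 3")
})

test_that("ANOVA p-values are approximately uniform under the null", {
  set.seed(41)
  fi <- rnorm(60, 20, 8)
  ps <- replicate(200, {
    gr <- sample(rep(0:2, each = 20))
    anova_bonferroni(cohort_table(sprintf("c%d", 1:60), gr,
                                  pmin(pmax(fi, 0), 100),
                                  rep(0.5, 60)))$p_value
  })
  expect_gt(min(ps), 0)
  frac05 <- mean(ps < 0.05)
  expect_gt(frac05, 0.005)
  expect_lt(frac05, 0.12)
  expect_lt(abs(mean(ps) - 0.5), 0.1)
})
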