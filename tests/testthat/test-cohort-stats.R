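test_that("Welch's t from summaries matches raw-sample computation", {
  set.seed(1)
  x <- rnorm(30, 0, 1); y <- rnorm(20, 0.5, 2)
  from_raw <- welch_t(x, y)
  from_sum <- welch_t(group_summary_of(x, "a"), group_summary_of(y, "b"))
  expect_equal(from_raw$t, from_sum$t, tolerance = 1e-12)
  expect_equal(from_raw$p, from_sum$p, tolerance = 1e-12)
  # and both agree with stats::t.test as the independent oracle
  ht <- t.test(x, y)
  expect_equal(from_raw$t, unname(ht$statistic), tolerance = 1e-10)
  expect_equal(from_raw$p, ht$p.value, tolerance = 1e-10)

  same <- group_summary("g", 10, 5, 1)
  id <- welch_t(same, same)
  expect_equal(id$t, 0)
  expect_equal(id$p, 1)
  expect_error(welch_t(group_summary("a", 5, 1, 0), group_summary("b", 5, 1, 0)),
               "undefined")
})

test_that("published two-group summaries reproduce the printed p-values", {
  height <- welch_t(group_summary("exposed", 96, 163.95, 7.89),
                    group_summary("unexposed", 25, 169.96, 8.15))
  expect_equal(round(height$p, 3), 0.002)
  weight <- welch_t(group_summary("exposed", 96, 63.11, 10.94),
                    group_summary("unexposed", 25, 71.76, 12.06))
  expect_equal(round(weight$p, 3), 0.003)
})

test_that("Welch's ANOVA reduces to Welch's t at k = 2 and to F = 0 on equal groups", {
  set.seed(2)
  x <- rnorm(25); y <- rnorm(15, 1, 3)
  wa <- welch_anova(list(a = x, b = y))
  wt <- welch_t(x, y)
  expect_equal(wa$p, wt$p, tolerance = 1e-10)
  # oracle: stats::oneway.test with var.equal = FALSE
  ow <- oneway.test(v ~ g, data.frame(v = c(x, y),
                                      g = rep(c("a", "b"), c(25, 15))))
  expect_equal(wa$F, unname(ow$statistic), tolerance = 1e-10)
  expect_equal(wa$p, ow$p.value, tolerance = 1e-10)

  z <- rnorm(12)
  eq <- welch_anova(list(z, z, z))
  expect_equal(eq$F, 0)
  expect_equal(eq$p, 1)
  expect_error(welch_anova(list(rnorm(5))), "2 groups")
})

test_that("Games-Howell reduces to Welch at k = 2 and never reports smaller p", {
  set.seed(3)
  x <- rnorm(20); y <- rnorm(25, 0.8, 2)
  gh <- games_howell(list(a = x, b = y))
  wt <- welch_t(x, y)
  expect_equal(nrow(gh), 1)
  expect_equal(gh$p, wt$p, tolerance = 1e-8)   # ptukey(q*sqrt(2), 2, df) == t
  z <- rnorm(10)
  gh3 <- games_howell(list(a = z, b = z, c = rnorm(10, 3)))
  expect_equal(gh3$diff[gh3$group_a == "a" & gh3$group_b == "b"], 0)
  expect_equal(gh3$p[gh3$group_a == "a" & gh3$group_b == "b"], 1, tolerance = 1e-6)
  # with more groups the studentized-range adjustment can only raise p
  wt_ab <- welch_t(z, rnorm(10, 0.5))
  set.seed(4)
  g4 <- games_howell(list(a = rnorm(10), b = rnorm(10, 0.5), c = rnorm(10, 5),
                          d = rnorm(10, -5)))
  p_ab_gh <- g4$p[g4$group_a == "a" & g4$group_b == "b"]
  set.seed(4)
  p_ab_t <- welch_t(rnorm(10), rnorm(10, 0.5))$p
  expect_gte(p_ab_gh, p_ab_t)
})

test_that("chi-square matches the textbook statistic and handles Yates", {
  counts <- matrix(c(12, 5, 7, 16), 2, 2)
  plain <- chi_square(counts, yates = FALSE)
  # brute-force oracle
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  expect_equal(plain$statistic, sum((counts - E)^2 / E), tolerance = 1e-10)
  expect_equal(plain$expected, E, ignore_attr = TRUE)
  # Yates default ON for 2x2 shrinks the statistic
  yat <- chi_square(counts)
  expect_lt(yat$statistic, plain$statistic)
  # proportional margins: statistic 0, p 1
  prop <- chi_square(matrix(c(10, 20, 30, 60), 2, 2), yates = FALSE)
  expect_equal(prop$statistic, 0, tolerance = 1e-12)
  expect_equal(prop$p, 1)
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2, 2)), "margin")
  expect_error(chi_square(matrix(c(1.5, 2, 3, 4), 2, 2)), "integers")
})

test_that("exposure-by-cluster and gender tables reproduce the published tests", {
  # 6 clusters x exposure (no/yes)
  counts <- cbind(no = c(1, 3, 5, 0, 0, 16), yes = c(31, 20, 23, 1, 4, 17))
  res <- chi_square(counts)
  expect_lt(res$p, 0.001)
  # excluding the two minor clusters leaves the conclusion unchanged
  res4 <- chi_square(counts[c(1, 2, 3, 6), ])
  expect_lt(res4$p, 0.001)
  # gender x exposure 2x2 rebuilt from the printed percentages, Yates-corrected
  gender <- matrix(c(44, 4, 52, 21), 2, 2)
  expect_equal(round(chi_square(gender, yates = TRUE)$p, 3), 0.013)
})

test_that("cohort_report renders mean (SD) cells with a p per variable", {
  set.seed(5)
  d <- data.frame(g = rep(c("A", "B"), each = 15),
                  v1 = c(rnorm(15), rnorm(15, 3)),
                  v2 = rnorm(30))
  rep <- cohort_report(d, c("v1", "v2"), "g")
  expect_equal(nrow(rep), 2)
  expect_match(rep$A[1], "\\(")
  expect_lt(as.numeric(rep$p[1]), 0.001)
})
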