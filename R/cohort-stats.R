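# Heteroscedastic group statistics: Welch's t (from raw samples or published
# summary statistics), Welch's ANOVA, Games-Howell post hoc pairwise tests,
# and Pearson chi-square on contingency tables. These accept mean/SD/n
# summaries so that published cohort tables can be re-analyzed directly.

#' Group summary
#'
#' A (label, n, mean, sd) summary of one group, the unit of the summary-based
#' tests. `group_summary_of()` computes it from a raw sample.
#'
#' @param label group label.
#' @param n sample size (>= 2).
#' @param mean,sd sample mean and standard deviation.
#' @return object of class `group_summary`.
#' @export
group_summary <- function(label, n, mean, sd) {
  stop_if(n < 2, "group '%s': n must be >= 2", label)
  stop_if(!is.finite(mean) || !is.finite(sd) || sd < 0,
          "group '%s': invalid mean/sd", label)
  structure(list(label = as.character(label), n = as.integer(n),
                 mean = as.numeric(mean), sd = as.numeric(sd)),
            class = "group_summary")
}

#' @rdname group_summary
#' @param x raw numeric sample (NAs dropped).
#' @export
group_summary_of <- function(x, label = "group") {
  x <- x[is.finite(x)]
  group_summary(label, length(x), mean(x), stats::sd(x))
}

as_summaries <- function(groups) {
  lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    if (inherits(g, "group_summary")) g
    else group_summary_of(g, names(groups)[i] %||% paste0("g", i))
  })
}

#' Welch's two-sample t-test from summary statistics
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom,
#' computable from (mean, sd, n) summaries alone, so published group tables
#' can be re-tested without raw data.
#'
#' @param a,b `group_summary` objects or raw numeric samples.
#' @return list with `t`, `df`, `p` (two-sided), and the mean difference.
#' @export
#' @examples
#' welch_t(group_summary("exposed", 96, 163.95, 7.89),
#'         group_summary("unexposed", 25, 169.96, 8.15))$p
welch_t <- function(a, b) {
  s <- as_summaries(list(a, b)); a <- s[[1]]; b <- s[[2]]
  va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
  stop_if(va + vb == 0 && a$mean == b$mean,
          "both groups are constant and equal: t undefined")
  t <- (a$mean - b$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), diff = a$mean - b$mean)
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Welch's F* test for equality of k group means under unequal variances,
#' from `group_summary` objects or raw samples. With k = 2 the p-value
#' coincides with [welch_t].
#'
#' @param groups list of `group_summary` objects or raw numeric vectors
#'   (optionally named).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
welch_anova <- function(groups) {
  gs <- as_summaries(groups)
  k <- length(gs)
  stop_if(k < 2, "need at least 2 groups")
  n <- vapply(gs, `[[`, 0, "n"); m <- vapply(gs, `[[`, 0, "mean")
  v <- vapply(gs, `[[`, 0, "sd")^2
  stop_if(any(v == 0), "a group has zero variance: Welch weights undefined")
  w <- n / v; W <- sum(w)
  mw <- sum(w * m) / W
  A <- sum(w * (m - mw)^2) / (k - 1)
  lambda <- sum((1 - w / W)^2 / (n - 1))
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * lambda
  Fstar <- A / B
  df1 <- k - 1
  df2 <- (k^2 - 1) / (3 * lambda)
  list(F = Fstar, df1 = df1, df2 = df2,
       p = stats::pf(Fstar, df1, df2, lower.tail = FALSE))
}

#' Games-Howell post hoc pairwise comparisons
#'
#' All pairwise mean comparisons after Welch's ANOVA: per pair, the standard
#' error is \eqn{\sqrt{s_i^2/n_i + s_j^2/n_j}}, degrees of freedom are
#' Welch-Satterthwaite per pair, and the p-value comes from the studentized
#' range distribution with k groups (so the family of comparisons is
#' controlled). With k = 2 this reduces to Welch's t.
#'
#' @inheritParams welch_anova
#' @return data frame with one row per pair: groups, mean difference, se, t,
#'   df, and adjusted p.
#' @export
games_howell <- function(groups) {
  gs <- as_summaries(groups)
  k <- length(gs)
  stop_if(k < 2, "need at least 2 groups")
  labs <- vapply(gs, `[[`, "", "label")
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    a <- gs[[ij[1]]]; b <- gs[[ij[2]]]
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    diff <- a$mean - b$mean
    if (se == 0) {
      c(diff = diff, se = 0, t = 0, df = a$n + b$n - 2, p = 1)
    } else {
      t <- diff / se
      df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
      p <- stats::ptukey(abs(t) * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
      c(diff = diff, se = se, t = t, df = df, p = p)
    }
  })
  data.frame(group_a = labs[pairs[1, ]], group_b = labs[pairs[2, ]],
             t(res), stringsAsFactors = FALSE, row.names = NULL)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's chi-square statistic with expected counts. Yates continuity
#' correction is applied by default for 2x2 tables and never for larger ones.
#' Cells with expected counts below 5 are flagged.
#'
#' @param counts integer matrix (at least 2x2, non-negative, both margins
#'   positive).
#' @param yates apply continuity correction (only meaningful for 2x2);
#'   default: TRUE exactly when the table is 2x2.
#' @return list with `statistic`, `df`, `p`, `expected`, `low_expected_cells`.
#' @export
chi_square <- function(counts, yates = all(dim(counts) == 2L)) {
  counts <- as.matrix(counts)
  stop_if(any(counts < 0) || any(counts != round(counts)),
          "counts must be non-negative integers")
  stop_if(nrow(counts) < 2 || ncol(counts) < 2, "table must be at least 2x2")
  stop_if(any(rowSums(counts) == 0) || any(colSums(counts) == 0),
          "table has a zero margin")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = yates))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), expected = ht$expected,
       low_expected_cells = sum(ht$expected < 5))
}

#' Cohort comparison report
#'
#' Renders a mean (SD) + p summary table for a set of variables across
#' groups: Welch's t for 2 groups, Welch's ANOVA for more.
#'
#' @param data data frame of subjects.
#' @param variables character vector of numeric column names.
#' @param group name of the grouping column.
#' @return data frame, one row per variable: per-group `mean (sd)` strings
#'   and the p-value.
#' @export
cohort_report <- function(data, variables, group) {
  g <- factor(data[[group]])
  out <- lapply(variables, function(v) {
    sp <- lapply(split(data[[v]], g), function(x) x[is.finite(x)])
    cells <- vapply(sp, function(x) {
      if (length(x) < 2) sprintf("%.2f (-)", mean(x))
      else sprintf("%.2f (%.2f)", mean(x), stats::sd(x))
    }, "")
    # the test uses only groups that admit a Welch variance weight
    ok <- vapply(sp, function(x) length(x) >= 2 && stats::sd(x) > 0, TRUE)
    p <- tryCatch({
      sums <- lapply(names(sp)[ok], function(nm) group_summary_of(sp[[nm]], nm))
      if (length(sums) == 2) welch_t(sums[[1]], sums[[2]])$p
      else welch_anova(sums)$p
    }, error = function(e) NA_real_)
    stats::setNames(as.list(c(cells, sprintf("%.3g", p))),
                    c(names(sp), "p"))
  })
  cbind(variable = variables,
        do.call(rbind, lapply(out, as.data.frame, stringsAsFactors = FALSE)))
}
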