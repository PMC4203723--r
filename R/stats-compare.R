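#' @include AllClasses.R
NULL

.groupStats <- function(values, labels) {
  data.frame(
    label = labels,
    n = vapply(values, length, integer(1)),
    mean = vapply(values, mean, numeric(1)),
    sd = vapply(values, sd, numeric(1))
  )
}

#' Two-group comparison by Student's t-test
#'
#' Two-sided t-test between two sets of per-cell metric values, reporting
#' means +/- SD per group, the t statistic, degrees of freedom, p-value and
#' the 95\% CI of the mean difference.  The default is the unpaired
#' equal-variance (Student's) test; `var_equal = FALSE` gives Welch's test
#' and `paired = TRUE` a paired test.  Two identical constant samples give
#' t = 0, p = 1 by convention; constant samples with different means give
#' p = 0.
#'
#' @param a,b numeric metric values of the two groups (n >= 2 each; equal n
#'   when paired).
#' @param paired paired test? (default FALSE).
#' @param var_equal pool the variances (Student's, default) or not (Welch).
#' @param conf_level confidence level (default 0.95).
#' @param labels group labels, length 2.
#' @param metric metric name recorded in the result.
#' @return a [GroupComparison-class].
#' @examples
#' gc <- twoGroupTTest(c(1, 2, 3), c(4, 5, 6))
#' pairwiseResults(gc)$t  # -3.674 (pooled-variance Student's t)
#' @export
twoGroupTTest <- function(a, b, paired = FALSE, var_equal = TRUE,
                          conf_level = 0.95, labels = c("A", "B"),
                          metric = "metric") {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (paired && length(a) != length(b)) {
    stop("paired test requires equal group sizes")
  }
  degenerate <- if (paired) sd(a - b) == 0 else sd(a) == 0 && sd(b) == 0
  if (degenerate) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    res <- list(statistic = if (equal) 0 else Inf * sign(mean(a) - mean(b)),
                parameter = NA_real_,
                p.value = if (equal) 1 else 0,
                conf.int = rep(mean(a) - mean(b), 2))
  } else {
    ht <- t.test(a, b, paired = paired, var.equal = var_equal,
                 conf.level = conf_level)
    res <- list(statistic = unname(ht$statistic),
                parameter = unname(ht$parameter),
                p.value = ht$p.value, conf.int = as.numeric(ht$conf.int))
  }
  method <- if (paired) "paired_t" else if (var_equal) "student_t"
            else "welch_t"
  pw <- data.frame(
    group1 = labels[1], group2 = labels[2],
    diff = mean(a) - mean(b),
    ci_lo = res$conf.int[1], ci_hi = res$conf.int[2],
    t = res$statistic, df = res$parameter, p_value = res$p.value,
    p_adjusted = res$p.value,
    significant = res$p.value < (1 - conf_level)
  )
  new("GroupComparison", metric = metric,
      groups = .groupStats(list(a, b), labels),
      pairwise = pw, method = method, conf_level = conf_level)
}

#' Bonferroni multiple comparison of group means
#'
#' All pairwise mean differences between three or more groups with
#' confidence intervals at the family 95\% level using Bonferroni-adjusted
#' per-pair levels alpha / k (k = number of pairs) and the pooled variance
#' across all groups (the behavior of the classical multiple-comparison-of-
#' means procedure): a pair is significant exactly when its adjusted CI
#' excludes zero.  With two groups the comparison delegates to
#' [twoGroupTTest()].
#'
#' @param groups named list of numeric vectors (>= 2 values each).
#' @param conf_level family confidence level (default 0.95).
#' @param metric metric name recorded in the result.
#' @return a [GroupComparison-class] with one pairwise row per group pair;
#'   `p_adjusted` is the Bonferroni-adjusted p-value min(1, k * p).
#' @export
bonferroniMulticompare <- function(groups, conf_level = 0.95,
                                   metric = "metric") {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2)) stop("every group needs n >= 2")
  if (length(groups) == 2L) {
    return(twoGroupTTest(groups[[1]], groups[[2]], conf_level = conf_level,
                         labels = names(groups), metric = metric))
  }
  g <- length(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  vars <- vapply(groups, function(x) stats::var(x), numeric(1))
  mse <- sum((ns - 1) * vars) / (N - g)
  df <- N - g
  k <- choose(g, 2)
  alpha <- 1 - conf_level
  tcrit <- qt(1 - alpha / (2 * k), df)

  idx <- utils::combn(g, 2)
  rows <- lapply(seq_len(ncol(idx)), function(c_) {
    i <- idx[1, c_]; j <- idx[2, c_]
    diff <- means[i] - means[j]
    se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    if (se == 0) {
      tval <- if (diff == 0) 0 else Inf * sign(diff)
      p <- if (diff == 0) 1 else 0
      ci <- c(diff, diff)
    } else {
      tval <- diff / se
      p <- 2 * pt(-abs(tval), df)
      ci <- diff + c(-1, 1) * tcrit * se
    }
    data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
               diff = diff, ci_lo = ci[1], ci_hi = ci[2], t = tval,
               df = df, p_value = p, p_adjusted = min(1, k * p),
               significant = ci[1] > 0 || ci[2] < 0)
  })
  new("GroupComparison", metric = metric,
      groups = .groupStats(groups, names(groups)),
      pairwise = do.call(rbind, rows),
      method = "bonferroni_multicompare", conf_level = conf_level)
}

#' Significance stars from p-values
#'
#' The star coding conventional in bar-graph figures: *** p < 0.001,
#' ** p < 0.01, * p < 0.05, "" otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of stars.
#' @export
significanceStars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) "" else if (x < 0.001) "***" else if (x < 0.01) "**"
    else if (x < 0.05) "*" else ""
  }, character(1))
}

#' Bar-graph table of a metric across groups
#'
#' Builds the group table behind a bar graph (one row per group: n, mean,
#' SD) and the pairwise significance entries with star coding, using a
#' Student's t-test for two groups and the Bonferroni multiple comparison
#' for three or more.  Stars are assigned from the Bonferroni-adjusted
#' p-values so they match the adjusted-CI significance calls.
#'
#' @param summaries per-cell summaries: a data.frame (e.g. from
#'   [summariesToDataFrame()] or a summary CSV) or a list of
#'   [OscillationSummary-class] objects; every cell must carry a group
#'   label.
#' @param metric metric column to tabulate, e.g. "frequency_per_min" or
#'   "mean_peak_amplitude".
#' @param group_col name of the grouping column (default "group_label").
#' @return list with `table` (group, n, mean, sd) and `pairwise`
#'   (group1, group2, diff, ci_lo, ci_hi, p_value, p_adjusted, significant,
#'   stars); `pairwise` has zero rows for a single group.
#' @export
buildFigureTable <- function(summaries, metric = "frequency_per_min",
                             group_col = "group_label") {
  df <- if (is.data.frame(summaries)) summaries
        else summariesToDataFrame(summaries)
  if (!metric %in% names(df) || !is.numeric(df[[metric]])) {
    stop(sprintf("unknown metric '%s'", metric))
  }
  if (!group_col %in% names(df)) {
    stop(sprintf("missing grouping column '%s'", group_col))
  }
  if (anyNA(df[[group_col]])) stop("every cell must be labeled with a group")
  groups <- split(df[[metric]], df[[group_col]])
  groups <- groups[unique(df[[group_col]])]  # keep input group order
  tab <- .groupStats(groups, names(groups))
  names(tab)[1] <- "group"
  if (length(groups) < 2L) {
    pw <- tab[0, c("group", "group")]
    names(pw) <- c("group1", "group2")
    return(list(table = tab, pairwise = pw))
  }
  gc <- if (length(groups) == 2L) {
    twoGroupTTest(groups[[1]], groups[[2]], labels = names(groups),
                  metric = metric)
  } else {
    bonferroniMulticompare(groups, metric = metric)
  }
  pw <- gc@pairwise
  pw$stars <- significanceStars(pw$p_adjusted)
  list(table = tab,
       pairwise = pw[, c("group1", "group2", "diff", "ci_lo", "ci_hi",
                         "p_value", "p_adjusted", "significant", "stars")])
}
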