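#' Outcome-by-level contingency summary
#'
#' Tabulates a binary outcome over the levels of a categorical variable in
#' the analysis table: level total, outcome-positive count, and the row
#' percentage (positives as a percent of the level total), i.e. the layout
#' of a descriptive readmission-pattern table.
#'
#' @param data Analysis tibble.
#' @param row_var Name of the categorical variable.
#' @param outcome Name of the logical/0-1 outcome column.
#' @return Tibble with `level`, `n`, `n_event`, `pct` (`NA` for empty
#'   levels).
#' @export
crosstab <- function(data, row_var, outcome) {
  for (v in c(row_var, outcome)) {
    if (!v %in% names(data)) {
      stop("unknown variable '", v, "'", call. = FALSE)
    }
  }
  x <- data[[row_var]]
  y <- as.logical(data[[outcome]])
  levels <- if (is.factor(x)) levels(x) else sort(unique(as.character(x)))
  out <- lapply(levels, function(lv) {
    sel <- !is.na(x) & as.character(x) == lv
    n <- sum(sel)
    n_event <- sum(y[sel], na.rm = TRUE)
    tibble::tibble(level = lv, n = n, n_event = n_event,
                   pct = if (n > 0) 100 * n_event / n else NA_real_)
  })
  dplyr::bind_rows(out)
}

#' Crude odds ratio with Woolf confidence interval
#'
#' For the 2x2 table (`a` exposed-event, `b` exposed-nonevent, `c`
#' unexposed-event, `d` unexposed-nonevent): OR = ad/bc, with the Woolf
#' standard error on the log scale, `se = sqrt(1/a + 1/b + 1/c + 1/d)`, and
#' the 95% interval `exp(log OR +/- 1.96 se)`. Zero cells make the estimate
#' degenerate; with `continuity = TRUE` the Haldane-Anscombe correction
#' (add 0.5 to every cell) is applied and flagged in the result.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param conf_level Confidence level (default 0.95).
#' @param continuity Apply the 0.5 continuity correction to all cells.
#' @return An `odds_ratio` object: `or`, `log_or`, `se_log_or`, `ci_low`,
#'   `ci_high`, `conf_level`, `continuity`.
#' @examples
#' odds_ratio_woolf(331, 1022, 85, 308)  # OR 1.17, 95% CI 0.90-1.54
#' @export
odds_ratio_woolf <- function(a, b, c, d, conf_level = 0.95,
                             continuity = FALSE) {
  cells <- c(a = unname(a), b = unname(b), c = unname(c), d = unname(d))
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (any(cells == 0)) {
    if (!continuity) {
      stop("degenerate 2x2 table: zero cell(s) ",
           paste(names(cells)[cells == 0], collapse = ", "),
           "; rerun with continuity = TRUE for the Haldane-Anscombe ",
           "correction", call. = FALSE)
    }
    cells <- cells + 0.5
  }
  log_or <- log(cells["a"]) + log(cells["d"]) - log(cells["b"]) - log(cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    or = unname(exp(log_or)),
    log_or = unname(log_or),
    se_log_or = unname(se),
    ci_low = unname(exp(log_or - z * se)),
    ci_high = unname(exp(log_or + z * se)),
    conf_level = conf_level,
    continuity = any(c(a, b, c, d) == 0)),
    class = "odds_ratio")
}

#' @export
print.odds_ratio <- function(x, ...) {
  cat(sprintf("OR %.2f (%d%% CI %.2f-%.2f)%s\n", x$or,
              round(100 * x$conf_level), x$ci_low, x$ci_high,
              if (x$continuity) " [continuity-corrected]" else ""))
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' The uncorrected Pearson statistic `sum((O - E)^2 / E)` over an r x c
#' count table, with expected counts from the margins, `df = (r-1)(c-1)`,
#' and the upper-tail chi-square p-value. No continuity correction is
#' applied for any table size.
#'
#' @param counts Numeric matrix (or table) of non-negative counts.
#' @return A `chi2_result`: `statistic`, `df`, `p_value`, `expected`.
#' @export
pearson_chi2 <- function(counts) {
  m <- as.matrix(counts)
  if (any(is.na(m)) || any(m < 0)) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("need an r x c table with r, c >= 2", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table: a zero row or column margin leaves the ",
         "expected counts undefined", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 expected = ht$expected),
            class = "chi2_result")
}

#' @export
print.chi2_result <- function(x, ...) {
  cat(sprintf("X-squared = %.4g, df = %d, p-value = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Linkage-bias diagnostic
#'
#' Compares the distribution of an evaluative score between linked (uniquely
#' matched) and unlinked survey respondents with a Pearson chi-square test
#' on the 2 x k matched-status by score-category table. A significant
#' difference warns that linkage success is informative about the score,
#' i.e. that the linked subset may be biased.
#'
#' The 5-level quality rating is tested on its native levels (`binning =
#' NULL`); for the 0-10 experience score a binning is configurable, e.g.
#' `cut()` breakpoints.
#'
#' @param matched_scores,unmatched_scores Vectors of scores for the two
#'   groups.
#' @param binning `NULL` (use each distinct score as its own category), a
#'   numeric vector of `cut()` breaks, or a function mapping scores to
#'   categories.
#' @return A `chi2_result`, with the underlying table attached as attribute
#'   `"table"`.
#' @export
linkage_bias_test <- function(matched_scores, unmatched_scores,
                              binning = NULL) {
  bin <- function(x) {
    if (is.null(binning)) as.character(x)
    else if (is.function(binning)) as.character(binning(x))
    else as.character(cut(x, breaks = binning, include.lowest = TRUE))
  }
  mb <- bin(matched_scores)
  ub <- bin(unmatched_scores)
  cats <- sort(unique(c(mb, ub)))
  tab <- rbind(matched = table(factor(mb, levels = cats)),
               unmatched = table(factor(ub, levels = cats)))
  res <- pearson_chi2(tab)
  attr(res, "table") <- tab
  res
}
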