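#' Prevalence with confidence interval
#'
#' Point prevalence `affected / total` with a 95% (by default)
#' normal-approximation (Wald) confidence interval clipped to `[0, 1]`;
#' a Wilson score interval is available via `method`.
#'
#' @param affected,total Non-negative counts, `affected <= total`,
#'   `total > 0`.
#' @param method `"wald"` (default) or `"wilson"`.
#' @param level Confidence level.
#' @return One-row tibble: `affected`, `total`, `proportion`, `ci_low`,
#'   `ci_high`, `method`.
#' @examples
#' prevalence(2634, 33548)
#' @export
prevalence <- function(affected, total, method = c("wald", "wilson"),
                       level = 0.95) {
  method <- match.arg(method)
  if (total <= 0) validation_error("`total` must be positive.")
  if (affected < 0 || affected > total) {
    validation_error("`affected` must lie in [0, total].")
  }
  p <- affected / total
  if (method == "wald") {
    z <- qnorm(1 - (1 - level) / 2)
    half <- z * sqrt(p * (1 - p) / total)
    lo <- max(0, p - half)
    hi <- min(1, p + half)
  } else {
    ci <- prop.test(affected, total, conf.level = level, correct = FALSE)$conf.int
    lo <- ci[1]; hi <- ci[2]
  }
  tibble::tibble(affected = affected, total = total, proportion = p,
                 ci_low = lo, ci_high = hi, method = method)
}

#' Sex-difference chi-square test on a 2x2 table
#'
#' Pearson chi-square without continuity correction (df = 1), as used to
#' compare trait prevalence between males and females.
#'
#' @param table 2x2 matrix of counts, rows = groups (e.g. sex), columns =
#'   affected / unaffected.
#' @return One-row tibble: `chi2`, `df`, `p`.
#' @examples
#' sex_difference_chi2(rbind(male = c(1798, 15148), female = c(836, 15766)))
#' @export
sex_difference_chi2 <- function(table) {
  table <- as.matrix(table)
  check_2x2(table, positive_cells = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    validation_error("Both margins of the 2x2 table must be positive.")
  }
  ct <- chisq.test(table, correct = FALSE)
  tibble::tibble(chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value)
}

#' Odds ratio from a 2x2 table
#'
#' Cross-product odds ratio with a Woolf (log-scale) confidence interval,
#' \eqn{\exp(\log \mathrm{OR} \pm z \sqrt{1/a + 1/b + 1/c + 1/d})}. When any
#' cell is zero, 0.5 is added to every cell (Haldane-Anscombe correction) and
#' the result is flagged via the `corrected` column.
#'
#' @inheritParams sex_difference_chi2
#' @param level Confidence level.
#' @return One-row tibble: `odds_ratio`, `or_ci_low`, `or_ci_high`,
#'   `corrected`.
#' @examples
#' odds_ratio(rbind(c(1798, 15148), c(836, 15766)))
#' @export
odds_ratio <- function(table, level = 0.95) {
  table <- as.matrix(table)
  check_2x2(table, positive_cells = FALSE)
  corrected <- any(table == 0)
  x <- unname(table + if (corrected) 0.5 else 0)
  or <- (x[1, 1] * x[2, 2]) / (x[1, 2] * x[2, 1])
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(sum(1 / x))
  tibble::tibble(odds_ratio = or,
                 or_ci_low = exp(log(or) - z * se),
                 or_ci_high = exp(log(or) + z * se),
                 corrected = corrected)
}

check_2x2 <- function(table, positive_cells = FALSE) {
  if (!is.matrix(table) || any(dim(table) != c(2, 2))) {
    validation_error("`table` must be a 2x2 matrix of counts.")
  }
  if (any(table < 0) || any(!is.finite(table))) {
    validation_error("Counts must be finite and non-negative.")
  }
  if (positive_cells && any(table == 0)) {
    validation_error("All cells must be positive.")
  }
  invisible(table)
}

#' Two-sample pooled-variance t-test from summary statistics
#'
#' Student's t-test computed from group means, standard deviations and sizes
#' with a pooled variance estimate; df = n1 + n2 - 2, two-sided p-value.
#' Used to compare cognitive test scores between screened-positive and
#' screened-negative groups when only summary statistics are available.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return One-row tibble: `t`, `df`, `p`, `mean_difference` (group 1 minus
#'   group 2; the sign of `t` matches it).
#' @examples
#' pooled_t_test(81.5, 19.6, 66, 98.3, 21.4, 377)
#' @export
pooled_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) validation_error("Both group sizes must be at least 2.")
  if (sd1 <= 0 || sd2 <= 0) validation_error("Standard deviations must be positive.")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  diff <- mean1 - mean2
  t <- diff / (sp * sqrt(1 / n1 + 1 / n2))
  tibble::tibble(t = t, df = df, p = 2 * pt(-abs(t), df),
                 mean_difference = diff)
}

#' Prevalence summaries from an analysis set
#'
#' Overall and by-sex prevalence of the coded phenotype among analysable
#' individuals, plus the male-versus-female 2x2 association (uncorrected
#' Pearson chi-square and Woolf odds ratio).
#'
#' @param aset An [pair_analysis_set()] result.
#' @param method CI method passed to [prevalence()].
#' @return A list with `prevalence` (tibble with rows overall/male/female),
#'   `chi2` and `odds_ratio` (one-row tibbles).
#' @export
summarise_prevalence <- function(aset, method = "wald") {
  if (!inherits(aset, "analysis_set")) {
    validation_error("`aset` must come from pair_analysis_set().")
  }
  ind <- aset$individuals
  row_for <- function(label, sub) {
    dplyr::mutate(prevalence(sum(sub$affected), nrow(sub), method = method),
                  group = label, .before = 1)
  }
  prev <- dplyr::bind_rows(
    row_for("overall", ind),
    row_for("male", dplyr::filter(ind, .data$sex == "male")),
    row_for("female", dplyr::filter(ind, .data$sex == "female"))
  )
  tab <- rbind(
    male = c(sum(ind$affected & ind$sex == "male"),
             sum(!ind$affected & ind$sex == "male")),
    female = c(sum(ind$affected & ind$sex == "female"),
               sum(!ind$affected & ind$sex == "female"))
  )
  list(prevalence = prev,
       chi2 = sex_difference_chi2(tab),
       odds_ratio = odds_ratio(tab))
}
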