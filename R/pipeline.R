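#' Run the full twin-analysis pipeline
#'
#' Orchestrates simulate (or load) -> phenotype coding -> descriptive
#' epidemiology -> concordance tables -> saturated and variance-component
#' fits with likelihood-ratio comparisons, returning one bundle holding
#' every statistic. With an output directory the bundle is also written to
#' disk (TSV tables, JSON statistics, PNG figure), each file derived from
#' the same in-memory values.
#'
#' @param config A [sim_config()] (to simulate) — or `input`, a cohort CSV
#'   path; exactly one must be given.
#' @param input Path to a cohort CSV (see [read_cohort()]).
#' @param model Phenotype coding model, 1 or 2.
#' @param ci `"profile"` (profile-likelihood CIs on ACE components) or
#'   `"none"`.
#' @param threshold_pattern Passed to [fit_variance_model()].
#' @param out Optional output directory.
#' @return A list of class `sald_report`: `cohort`, `coded`, `analysis_set`,
#'   `descriptives`, `causes` (when cause labels are present), `tables`,
#'   `correlations`, `fits` (saturated/ACE/AE/CE/E), `ladder` (model-fit
#'   table with LRTs), `components` (best ACE components with CIs), and
#'   `figure_data`.
#' @export
run_pipeline <- function(config = NULL, input = NULL, model = 1,
                         ci = c("profile", "none"),
                         threshold_pattern = "sex", out = NULL) {
  ci <- match.arg(ci)
  if (is.null(config) == is.null(input)) {
    validation_error("Supply exactly one of `config` or `input`.")
  }
  cohort <- tryCatch(
    if (!is.null(config)) simulate_cohort(config) else read_cohort(input),
    error = function(e) abort("Pipeline stage 'cohort' failed.", parent = e))
  coded <- tryCatch(code_sald(cohort, model = model),
                    error = function(e) abort("Pipeline stage 'coding' failed.", parent = e))
  aset <- pair_analysis_set(coded)
  desc <- summarise_prevalence(aset)
  causes <- if (any(!is.na(cohort$cause1)) || any(!is.na(cohort$cause2))) {
    tabulate_causes(cohort)
  }
  tables <- group_tables(aset$pairs)
  correlations <- tetrachoric_by_class(tables)
  sat <- fit_saturated(tables)
  fits <- list(saturated = sat)
  for (m in c("ACE", "AE", "CE", "E")) {
    fits[[m]] <- fit_variance_model(
      tables, m, threshold_pattern = threshold_pattern,
      ci = if (m == "ACE") ci else "none")
  }
  ladder <- model_ladder(fits)
  components <- fits$ACE$components
  figure_data <- dplyr::mutate(
    dplyr::select(components, "component", "estimate", "ci_low", "ci_high"),
    model = paste0("Model ", model), .before = 1)
  report <- structure(list(
    model = model,
    cohort = cohort, coded = coded, analysis_set = aset,
    descriptives = desc, causes = causes,
    tables = tables, correlations = correlations,
    fits = fits, ladder = ladder, components = components,
    figure_data = figure_data
  ), class = "sald_report")
  if (!is.null(out)) write_report(report, out)
  report
}

# Table-3-style ladder: ACE vs saturated, then AE/CE/E vs ACE
model_ladder <- function(fits) {
  cmp <- list(c("ACE", "saturated"), c("AE", "ACE"), c("CE", "ACE"),
              c("E", "ACE"))
  rows <- purrr::map_dfr(cmp, function(x)
    likelihood_ratio_test(fits[[x[1]]], fits[[x[2]]]))
  base <- purrr::map_dfr(fits[c("saturated", "ACE", "AE", "CE", "E")], glance)
  dplyr::left_join(base, dplyr::rename(rows, model = "restricted",
                                       comparison = "general"),
                   by = "model") |>
    dplyr::select("model", "comparison", "minus2LL", "df", "n_parameters",
                  "delta_chi2", "delta_df", "p", "converged")
}

#' @export
print.sald_report <- function(x, ...) {
  cat(sprintf("<sald_report> model %d, %d pairs analysed\n",
              x$model, sum(x$tables$n_pairs)))
  cat("\nPrevalence:\n"); print(x$descriptives$prevalence)
  cat("\nTetrachoric correlations:\n"); print(x$correlations)
  cat("\nModel ladder:\n"); print(x$ladder)
  cat("\nACE components:\n"); print(x$components)
  invisible(x)
}

write_report <- function(report, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$descriptives$prevalence,
                   file.path(out, "prevalence.tsv"))
  readr::write_tsv(report$tables, file.path(out, "group_tables.tsv"))
  readr::write_tsv(report$ladder, file.path(out, "model_ladder.tsv"))
  readr::write_tsv(report$figure_data, file.path(out, "variance_components.tsv"))
  if (!is.null(report$causes)) {
    readr::write_tsv(report$causes, file.path(out, "cause_tally.tsv"))
  }
  stats_json <- list(
    model = report$model,
    flow = report$analysis_set$flow,
    prevalence = report$descriptives$prevalence,
    chi2 = report$descriptives$chi2,
    odds_ratio = report$descriptives$odds_ratio,
    correlations = report$correlations,
    ladder = report$ladder,
    components = report$components
  )
  jsonlite::write_json(stats_json, file.path(out, "statistics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  p <- plot_variance_components(report$figure_data)
  ggplot2::ggsave(file.path(out, "variance_components.png"), p,
                  width = 4, height = 5, dpi = 150)
  invisible(out)
}

#' Stacked-bar figure of variance components
#'
#' One stacked bar per model, segments A (bottom), C, E summing to 1, with
#' the estimated proportions annotated.
#'
#' @param data Tibble with columns `model`, `component` (`a2`, `c2`, `e2`)
#'   and `estimate` (plus optional `ci_low`/`ci_high`, shown for the A
#'   segment boundary).
#' @return A ggplot object.
#' @examples
#' plot_variance_components(tibble::tibble(
#'   model = "Model 1", component = c("a2", "c2", "e2"),
#'   estimate = c(0.75, 0.22, 0.03)))
#' @export
plot_variance_components <- function(data) {
  sums <- tapply(data$estimate, data$model, sum)
  if (any(abs(sums - 1) > 1e-6)) {
    validation_error("Component estimates must sum to 1 within each model.")
  }
  data <- dplyr::mutate(
    data,
    component = factor(.data$component, levels = c("e2", "c2", "a2"),
                       labels = c("E", "C", "A")))
  ggplot2::ggplot(data, ggplot2::aes(x = .data$model, y = .data$estimate,
                                     fill = .data$component)) +
    ggplot2::geom_col(width = 0.6, colour = "grey20") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$estimate)),
                       position = ggplot2::position_stack(vjust = 0.5),
                       size = 3.2) +
    ggplot2::scale_fill_manual(values = c(A = "#4477AA", C = "#EE6677",
                                          E = "#CCBB44"),
                               breaks = c("A", "C", "E")) +
    ggplot2::labs(x = NULL, y = "Proportion of liability variance",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ace_fit <- function(object, ...) {
  plot_variance_components(dplyr::mutate(
    dplyr::select(object$components, "component", "estimate"),
    model = object$model, .before = 1))
}

#' @export
autoplot.sald_report <- function(object, ...) {
  plot_variance_components(object$figure_data)
}
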