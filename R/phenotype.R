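#' Code the binary screening phenotype with exclusion rules
#'
#' Converts the ordinal questionnaire item into a binary affected/unaffected
#' status per twin and applies the exclusion logic. A twin is affected when
#' the ordinal response is 1 ("yes, to a certain degree") or 2 ("yes") and
#' unaffected when 0. Under both models, twins flagged (or whose follow-up
#' cause indicates) hearing impairment, acquired language disorder, or a
#' chromosomal abnormality are excluded to avoid differential
#' misclassification; exclusion takes precedence over the phenotype. Under
#' model 2 (sensitivity analysis), twins with autism — register-reported or
#' parent-reported as the cause, merged into a single indicator — or
#' intellectual disability are additionally excluded. A missing ordinal
#' response with no exclusion flag yields status `"missing"`, distinct from
#' unaffected.
#'
#' Exclusion-reason precedence when several apply: hearing, acquired,
#' chromosomal, autism, intellectual_disability.
#'
#' @param cohort A cohort tibble (see [simulate_cohort()] for the schema).
#' @param model Analysis model, `1` (main) or `2` (autism/ID excluded).
#' @return The input tibble with per-twin columns `sald1`, `sald2` (factor:
#'   unaffected, affected, excluded, missing) and `excl1`, `excl2`
#'   (exclusion reason, `NA` when not excluded).
#' @examples
#' cohort <- simulate_cohort(sim_config(
#'   pairs_per_group = c(MZM = 50, DZOS = 50), seed = 1,
#'   comorbidity_rates = c(hearing = 0.02)))
#' code_sald(cohort, model = 1)
#' @export
code_sald <- function(cohort, model = 1) {
  if (!model %in% c(1, 2)) {
    validation_error("`model` must be 1 or 2.")
  }
  code_one <- function(atac, cause, autism, id, hearing, acquired, chrom) {
    cause <- ifelse(is.na(cause), "", cause)
    hearing_x <- hearing | cause == "hearing"
    acquired_x <- acquired | cause == "acquired_medical"
    autism_x <- autism | cause == "LD_due_to_ID_or_autism"
    reason <- rep(NA_character_, length(atac))
    if (model == 2) {
      reason[id] <- "intellectual_disability"
      reason[autism_x] <- "autism"
    }
    reason[chrom] <- "chromosomal"
    reason[acquired_x] <- "acquired"
    reason[hearing_x] <- "hearing"
    status <- dplyr::case_when(
      !is.na(reason) ~ "excluded",
      is.na(atac) ~ "missing",
      atac %in% c(1L, 2L) ~ "affected",
      atac == 0L ~ "unaffected",
      TRUE ~ NA_character_
    )
    if (any(is.na(status))) {
      validation_error("Ordinal responses must be 0, 1, 2 or missing.")
    }
    list(status = factor(status, levels = sald_levels()), reason = reason)
  }
  t1 <- code_one(cohort$atac1, cohort$cause1, cohort$autism1, cohort$id1,
                 cohort$hearing1, cohort$acquired1, cohort$chrom1)
  t2 <- code_one(cohort$atac2, cohort$cause2, cohort$autism2, cohort$id2,
                 cohort$hearing2, cohort$acquired2, cohort$chrom2)
  dplyr::mutate(cohort,
                sald1 = t1$status, excl1 = t1$reason,
                sald2 = t2$status, excl2 = t2$reason)
}

sald_levels <- function() c("unaffected", "affected", "excluded", "missing")

#' Build the analysis sets from a coded cohort
#'
#' Splits a coded cohort into the two denominators the analyses use:
#' prevalence counts every non-excluded individual with an observed
#' phenotype, while twin correlations and variance-component models use only
#' complete pairs in which both twins are non-excluded with observed
#' phenotypes. Counts removed at each step are tallied in a flow table.
#'
#' @param coded A tibble from [code_sald()].
#' @return A list of class `analysis_set` with elements `individuals` (one
#'   row per analysable twin: `pair_id`, `twin`, `zygosity_group`, `sex`,
#'   `affected`), `pairs` (complete analysable pairs in the coded schema),
#'   and `flow` (tibble of step/count removals).
#' @export
pair_analysis_set <- function(coded) {
  if (!all(c("sald1", "sald2") %in% names(coded))) {
    validation_error("`coded` must come from code_sald().")
  }
  long <- tidyr::pivot_longer(
    dplyr::select(coded, "pair_id", "zygosity_group", "sex1", "sex2",
                  "sald1", "sald2"),
    cols = c("sex1", "sex2", "sald1", "sald2"),
    names_to = c(".value", "twin"), names_pattern = "(sex|sald)([12])"
  )
  n_total <- nrow(long)
  n_excl <- sum(long$sald == "excluded")
  n_miss <- sum(long$sald == "missing")
  individuals <- dplyr::mutate(
    dplyr::filter(long, .data$sald %in% c("affected", "unaffected")),
    affected = .data$sald == "affected"
  )
  pairs <- dplyr::filter(coded,
                         sald1 %in% c("affected", "unaffected") &
                           sald2 %in% c("affected", "unaffected"))
  if (nrow(individuals) == 0) {
    abort("Analysis set is empty: every individual was excluded or missing.",
          class = "twinliab_empty_analysis_set")
  }
  flow <- tibble::tibble(
    step = c("individuals_total", "excluded", "missing_phenotype",
             "individuals_analysable", "pairs_total", "pairs_complete"),
    n = c(n_total, n_excl, n_miss, nrow(individuals), nrow(coded), nrow(pairs))
  )
  structure(list(individuals = individuals, pairs = pairs, flow = flow),
            class = "analysis_set")
}

#' @export
print.analysis_set <- function(x, ...) {
  cat("<analysis_set>\n")
  print(x$flow)
  invisible(x)
}

#' Tabulate parent-reported follow-up causes
#'
#' Counts follow-up cause categories among twins whose parents answered the
#' open-ended cause question, overall and by sex, with percentages on the
#' responder denominator (per sex for the sex columns). Twins recorded as
#' `"indicated_no_response"` count toward the indicated total but not the
#' responder denominator.
#'
#' @param cohort A cohort (or coded cohort) tibble with `cause1`/`cause2`.
#' @return A tibble of class `cause_tally` with one row per category and
#'   columns `n`, `pct`, `n_male`, `pct_male`, `n_female`, `pct_female`;
#'   attributes `n_indicated`, `n_responded` and `responded_pct` carry the
#'   follow-up response summary. With no cause data all counts are 0 and
#'   percentages are `NA`.
#' @export
tabulate_causes <- function(cohort) {
  long <- tidyr::pivot_longer(
    dplyr::select(cohort, "pair_id", "sex1", "sex2", "cause1", "cause2"),
    cols = c("sex1", "sex2", "cause1", "cause2"),
    names_to = c(".value", "twin"), names_pattern = "(sex|cause)([12])"
  )
  long <- dplyr::filter(long, !is.na(.data$cause))
  known <- c(cause_categories(), "indicated_no_response")
  bad <- setdiff(unique(long$cause), known)
  if (length(bad) > 0) {
    validation_error(sprintf("Unknown cause categories: %s.",
                             paste(bad, collapse = ", ")))
  }
  responders <- dplyr::filter(long, .data$cause != "indicated_no_response")
  n_ind <- nrow(long)
  n_resp <- nrow(responders)
  n_resp_m <- sum(responders$sex == "male")
  n_resp_f <- sum(responders$sex == "female")
  tally <- purrr::map_dfr(cause_categories(), function(cat) {
    sub <- responders$cause == cat
    tibble::tibble(
      category = cat,
      n = sum(sub),
      pct = if (n_resp > 0) 100 * sum(sub) / n_resp else NA_real_,
      n_male = sum(sub & responders$sex == "male"),
      pct_male = if (n_resp_m > 0) 100 * sum(sub & responders$sex == "male") / n_resp_m else NA_real_,
      n_female = sum(sub & responders$sex == "female"),
      pct_female = if (n_resp_f > 0) 100 * sum(sub & responders$sex == "female") / n_resp_f else NA_real_
    )
  })
  structure(tally,
            class = c("cause_tally", class(tally)),
            n_indicated = n_ind,
            n_responded = n_resp,
            responded_pct = if (n_ind > 0) 100 * n_resp / n_ind else NA_real_)
}
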