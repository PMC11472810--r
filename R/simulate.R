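#' Simulation configuration for a twin cohort
#'
#' Bundles and validates everything the cohort simulator needs: pair counts
#' for the five zygosity-by-sex groups, the generating liability variance
#' components, sex-specific prevalences, and optional follow-up-cause and
#' comorbidity settings. Defaults reproduce the structure of a large Swedish
#' population-based twin screening sample: group sizes 2465 (MZ male),
#' 2676 (MZ female), 3122 (DZ male), 2739 (DZ female) and 5772 (DZ
#' opposite-sex) pairs, with prevalence 10.61% in males and 5.03% in females.
#'
#' @param pairs_per_group Named integer vector of pair counts; names must be
#'   `MZM`, `MZF`, `DZM`, `DZF`, `DZOS`.
#' @param a2,c2,e2 Generating proportions of liability variance (additive
#'   genetic, shared environment, non-shared environment). Must be in
#'   `[0, 1]` and sum to 1 within 1e-9.
#' @param prevalence_male,prevalence_female Trait prevalence by sex, in
#'   (0, 1); each determines a probit threshold on the liability scale.
#' @param p_severe Probability that an affected twin's ordinal questionnaire
#'   response is 2 ("yes") rather than 1 ("yes, to a certain degree"). The
#'   analysis collapses the two, so this split does not affect coding.
#' @param cause_distribution Optional named probability vector over follow-up
#'   cause categories (see [cause_categories()]); `NULL` disables cause
#'   simulation. [catss_cause_distribution()] gives a realistic default.
#' @param cause_indicated_rate Probability that an affected twin's parent
#'   indicates a known cause on the follow-up question.
#' @param cause_response_rate Probability that an indicated cause receives an
#'   open-ended categorised answer (otherwise recorded as indicated with no
#'   response).
#' @param comorbidity_rates Optional named vector of per-twin flag
#'   probabilities with names among `autism`, `intellectual_disability`,
#'   `hearing`, `acquired`, `chromosomal`.
#' @param comorbidity_rr Relative risk of autism / intellectual-disability
#'   flags given an affected phenotype (1 = independent of liability).
#' @param missing_rate Probability that the ordinal response is missing.
#' @param seed Integer root seed; each group draws from its own documented
#'   substream so adding groups does not perturb existing draws.
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(pairs_per_group = c(MZM = 2465, MZF = 2676, DZM = 3122,
                                           DZF = 2739, DZOS = 5772),
                       a2 = 0.75, c2 = 0.22, e2 = 0.03,
                       prevalence_male = 0.1061, prevalence_female = 0.0503,
                       p_severe = 0.5,
                       cause_distribution = NULL,
                       cause_indicated_rate = 512 / 2424,
                       cause_response_rate = 479 / 512,
                       comorbidity_rates = NULL,
                       comorbidity_rr = 1,
                       missing_rate = 0,
                       seed = 1L) {
  groups <- zyg_group_levels()
  if (is.null(names(pairs_per_group)) ||
      !all(names(pairs_per_group) %in% groups)) {
    validation_error("`pairs_per_group` must be named with labels among MZM, MZF, DZM, DZF, DZOS.")
  }
  counts <- setNames(rep(0L, length(groups)), groups)
  counts[names(pairs_per_group)] <- as.integer(pairs_per_group)
  if (any(is.na(counts)) || any(counts < 0)) {
    validation_error("Pair counts must be non-negative integers.")
  }
  for (nm in c("a2", "c2", "e2")) stopifnot_prob(get(nm), nm)
  if (abs(a2 + c2 + e2 - 1) > 1e-9) {
    validation_error("Variance components must satisfy a2 + c2 + e2 = 1 (within 1e-9).")
  }
  for (nm in c("prevalence_male", "prevalence_female", "p_severe",
               "cause_indicated_rate", "cause_response_rate", "missing_rate")) {
    stopifnot_prob(get(nm), nm)
  }
  if (prevalence_male <= 0 || prevalence_male >= 1 ||
      prevalence_female <= 0 || prevalence_female >= 1) {
    validation_error("Prevalences must lie strictly inside (0, 1).")
  }
  if (!is.null(cause_distribution)) {
    bad <- setdiff(names(cause_distribution), cause_categories())
    if (length(bad) > 0) {
      validation_error(sprintf("Unknown cause categories: %s.",
                               paste(bad, collapse = ", ")))
    }
    stopifnot_prob(cause_distribution, "cause_distribution")
    if (abs(sum(cause_distribution) - 1) > 1e-9) {
      validation_error("`cause_distribution` must sum to 1.")
    }
  }
  if (!is.null(comorbidity_rates)) {
    bad <- setdiff(names(comorbidity_rates),
                   c("autism", "intellectual_disability", "hearing",
                     "acquired", "chromosomal"))
    if (length(bad) > 0) {
      validation_error(sprintf("Unknown comorbidity names: %s.",
                               paste(bad, collapse = ", ")))
    }
    stopifnot_prob(comorbidity_rates, "comorbidity_rates")
  }
  if (!is.numeric(comorbidity_rr) || comorbidity_rr < 0) {
    validation_error("`comorbidity_rr` must be a non-negative number.")
  }
  structure(list(
    pairs_per_group = counts,
    a2 = a2, c2 = c2, e2 = e2,
    prevalence_male = prevalence_male,
    prevalence_female = prevalence_female,
    p_severe = p_severe,
    cause_distribution = cause_distribution,
    cause_indicated_rate = cause_indicated_rate,
    cause_response_rate = cause_response_rate,
    comorbidity_rates = comorbidity_rates,
    comorbidity_rr = comorbidity_rr,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Follow-up cause category vocabulary
#'
#' Controlled vocabulary for the parent-reported cause behind a positive
#' screening response: developmental language disorder, language disorder
#' attributed to intellectual disability or autism, hearing impairment,
#' acquired/medical causes, speech sound disorder, unspecified (which absorbs
#' insufficient answers such as remarks about a kindergarten teacher or ear
#' wax), and combined DLD/SSD. `"indicated_no_response"` marks parents who
#' indicated a known cause but left the open-ended question blank.
#'
#' @return Character vector of category labels.
#' @export
cause_categories <- function() {
  c("DLD", "LD_due_to_ID_or_autism", "hearing", "acquired_medical",
    "SSD", "not_specified", "DLD_and_or_SSD")
}

#' Default follow-up cause distribution
#'
#' Category probabilities matching the observed distribution of categorised
#' parental comments in a population screening of 479 responders: DLD 95,
#' language disorder due to ID/autism 87, hearing 83, acquired/medical 80,
#' speech sound disorder 66, not specified 51, DLD and/or SSD 17.
#'
#' @return Named probability vector over [cause_categories()].
#' @export
catss_cause_distribution <- function() {
  n <- c(DLD = 95, LD_due_to_ID_or_autism = 87, hearing = 83,
         acquired_medical = 80, SSD = 66, not_specified = 51,
         DLD_and_or_SSD = 17)
  n / sum(n)
}

#' Simulate a twin cohort under the liability-threshold model
#'
#' For each zygosity-by-sex group, draws bivariate standard-normal liabilities
#' with correlation \eqn{a^2 + c^2} (MZ) or \eqn{0.5 a^2 + c^2} (DZ, including
#' opposite-sex pairs); a twin is affected when its liability exceeds the
#' sex-specific probit threshold \eqn{\Phi^{-1}(1 - \mathrm{prevalence})}.
#' Affected twins receive an ordinal response of 1 or 2, unaffected twins 0.
#' Optional follow-up cause labels and comorbidity flags are drawn per the
#' configured rates (flags independent of liability unless
#' `comorbidity_rr > 1` enriches autism/ID among affected twins).
#'
#' Randomness uses one substream per group derived from the root seed, with a
#' fixed draw order within each group (liabilities, severity, missingness,
#' flags, causes), so output is byte-identical for a given configuration.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with one row per pair and columns `pair_id`,
#'   `zygosity_group`, `sex1`, `sex2`, `atac1`, `atac2`, `cause1`, `cause2`,
#'   `autism1`, `autism2`, `id1`, `id2`, `hearing1`, `hearing2`, `acquired1`,
#'   `acquired2`, `chrom1`, `chrom2`. Opposite-sex pairs are ordered
#'   male-first.
#' @examples
#' cfg <- sim_config(pairs_per_group = c(MZM = 100, DZM = 100), seed = 7)
#' simulate_cohort(cfg)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    validation_error("`config` must be created by sim_config().")
  }
  info <- zyg_group_info()
  tau <- c(male = qnorm(1 - config$prevalence_male),
           female = qnorm(1 - config$prevalence_female))
  out <- purrr::pmap(info, function(group, zygosity, sex1, sex2) {
    n <- config$pairs_per_group[[group]]
    if (n == 0) return(NULL)
    idx <- match(group, info$group)
    set.seed(group_stream_seed(config$seed, idx))
    r <- group_correlation(zygosity, config$a2, config$c2)
    l1 <- rnorm(n)
    l2 <- r * l1 + sqrt(max(0, 1 - r^2)) * rnorm(n)
    aff1 <- l1 > tau[[sex1]]
    aff2 <- l2 > tau[[sex2]]
    atac1 <- ifelse(aff1, 1L + (runif(n) < config$p_severe), 0L)
    atac2 <- ifelse(aff2, 1L + (runif(n) < config$p_severe), 0L)
    if (config$missing_rate > 0) {
      atac1[runif(n) < config$missing_rate] <- NA_integer_
      atac2[runif(n) < config$missing_rate] <- NA_integer_
    }
    flags <- draw_flags(config, aff1, aff2, sex1, sex2, n)
    causes <- draw_causes(config, aff1, aff2, n)
    tibble::tibble(
      pair_id = sprintf("%s_%05d", group, seq_len(n)),
      zygosity_group = group,
      sex1 = sex1, sex2 = sex2,
      atac1 = atac1, atac2 = atac2,
      cause1 = causes$c1, cause2 = causes$c2,
      autism1 = flags$autism1, autism2 = flags$autism2,
      id1 = flags$id1, id2 = flags$id2,
      hearing1 = flags$hearing1, hearing2 = flags$hearing2,
      acquired1 = flags$acquired1, acquired2 = flags$acquired2,
      chrom1 = flags$chrom1, chrom2 = flags$chrom2
    )
  })
  dplyr::bind_rows(out)
}

# deterministic substream seed per group (kept below 2^31)
group_stream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 1000003 * index) %% 2147483647)
}

draw_flags <- function(config, aff1, aff2, sex1, sex2, n) {
  rates <- config$comorbidity_rates
  prev <- c(male = config$prevalence_male, female = config$prevalence_female)
  one <- function(flag, aff, sex) {
    base <- if (flag %in% names(rates)) rates[[flag]] else 0
    if (base == 0) return(rep(FALSE, n))
    if (flag %in% c("autism", "intellectual_disability") &&
        config$comorbidity_rr != 1) {
      pa <- min(1, base * config$comorbidity_rr)
      pu <- max(0, (base - prev[[sex]] * pa) / (1 - prev[[sex]]))
      p <- ifelse(aff, pa, pu)
    } else {
      p <- rep(base, n)
    }
    runif(n) < p
  }
  # fixed draw order: (autism, id, hearing, acquired, chromosomal) x (twin1, twin2)
  list(
    autism1 = one("autism", aff1, sex1), autism2 = one("autism", aff2, sex2),
    id1 = one("intellectual_disability", aff1, sex1),
    id2 = one("intellectual_disability", aff2, sex2),
    hearing1 = one("hearing", aff1, sex1), hearing2 = one("hearing", aff2, sex2),
    acquired1 = one("acquired", aff1, sex1), acquired2 = one("acquired", aff2, sex2),
    chrom1 = one("chromosomal", aff1, sex1), chrom2 = one("chromosomal", aff2, sex2)
  )
}

draw_causes <- function(config, aff1, aff2, n) {
  dist <- config$cause_distribution
  if (is.null(dist)) {
    return(list(c1 = rep(NA_character_, n), c2 = rep(NA_character_, n)))
  }
  one <- function(aff) {
    ind <- runif(n) < config$cause_indicated_rate
    resp <- runif(n) < config$cause_response_rate
    cat <- names(dist)[1 + findInterval(runif(n), cumsum(dist) / sum(dist))]
    cat <- pmin_chr(cat, names(dist))
    out <- rep(NA_character_, n)
    out[aff & ind] <- "indicated_no_response"
    out[aff & ind & resp] <- cat[aff & ind & resp]
    out
  }
  list(c1 = one(aff1), c2 = one(aff2))
}

# guard against findInterval landing past the last category through rounding
pmin_chr <- function(cat, levels) {
  cat[is.na(cat)] <- levels[length(levels)]
  cat
}

#' Read or write a cohort CSV
#'
#' The on-disk schema is one row per pair with the columns documented in
#' [simulate_cohort()]; logical flags are stored as 0/1.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `read_cohort()` returns a cohort tibble; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- dplyr::mutate(cohort, dplyr::across(dplyr::where(is.logical), as.integer))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  flags <- c("autism1", "autism2", "id1", "id2", "hearing1", "hearing2",
             "acquired1", "acquired2", "chrom1", "chrom2")
  x <- readr::read_csv(path, show_col_types = FALSE, na = "",
                       col_types = readr::cols(
                         pair_id = readr::col_character(),
                         zygosity_group = readr::col_character(),
                         sex1 = readr::col_character(),
                         sex2 = readr::col_character(),
                         atac1 = readr::col_integer(),
                         atac2 = readr::col_integer(),
                         cause1 = readr::col_character(),
                         cause2 = readr::col_character(),
                         .default = readr::col_integer()
                       ))
  dplyr::mutate(x, dplyr::across(dplyr::any_of(flags), as.logical))
}

#' Read or write a simulation configuration as JSON
#'
#' @param config A [sim_config()] object.
#' @param path File path.
#' @return `read_sim_config()` returns a validated `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  x <- lapply(unclass(config), function(v) {
    # keep names of named vectors (write_json drops them on atomics)
    if (!is.null(names(v)) && length(v) > 1) as.list(v) else v
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("pairs_per_group", "cause_distribution", "comorbidity_rates")) {
    if (is.list(x[[nm]])) x[[nm]] <- unlist(x[[nm]])
  }
  do.call(sim_config, x[!vapply(x, is.null, logical(1))])
}
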