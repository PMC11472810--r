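base_pair <- function(...) {
  row <- tibble::tibble(
    pair_id = "p1", zygosity_group = "MZM", sex1 = "male", sex2 = "male",
    atac1 = 0L, atac2 = 0L, cause1 = NA_character_, cause2 = NA_character_,
    autism1 = FALSE, autism2 = FALSE, id1 = FALSE, id2 = FALSE,
    hearing1 = FALSE, hearing2 = FALSE, acquired1 = FALSE, acquired2 = FALSE,
    chrom1 = FALSE, chrom2 = FALSE
  )
  modifyList(row, list(...))
}

test_that("phenotype coding follows the inclusion and exclusion rules", {
  cases <- dplyr::bind_rows(
    base_pair(pair_id = "affected_yes", atac1 = 2L),
    base_pair(pair_id = "affected_degree", atac1 = 1L),
    base_pair(pair_id = "unaffected", atac1 = 0L),
    base_pair(pair_id = "hearing_overrides", atac1 = 2L, hearing1 = TRUE),
    base_pair(pair_id = "acquired_cause", atac1 = 1L,
              cause1 = "acquired_medical"),
    base_pair(pair_id = "chromosomal", atac1 = 0L, chrom1 = TRUE),
    base_pair(pair_id = "missing", atac1 = NA_integer_),
    base_pair(pair_id = "missing_excluded", atac1 = NA_integer_,
              hearing1 = TRUE)
  )
  m1 <- code_sald(cases, model = 1)
  expect_equal(as.character(m1$sald1),
               c("affected", "affected", "unaffected", "excluded", "excluded",
                 "excluded", "missing", "excluded"))
  expect_equal(m1$excl1,
               c(NA, NA, NA, "hearing", "acquired", "chromosomal", NA,
                 "hearing"))
  expect_true(all(m1$sald2 == "unaffected"))
})

test_that("autism and intellectual disability are excluded only under model 2", {
  pair <- base_pair(atac1 = 1L, autism1 = TRUE)
  expect_equal(as.character(code_sald(pair, 1)$sald1), "affected")
  m2 <- code_sald(pair, 2)
  expect_equal(as.character(m2$sald1), "excluded")
  expect_equal(m2$excl1, "autism")
  # parent-reported autism cause merges with the register flag
  cause_only <- base_pair(atac1 = 2L, cause1 = "LD_due_to_ID_or_autism")
  expect_equal(as.character(code_sald(cause_only, 1)$sald1), "affected")
  expect_equal(code_sald(cause_only, 2)$excl1, "autism")
  id_pair <- base_pair(atac2 = 2L, id2 = TRUE)
  expect_equal(as.character(code_sald(id_pair, 2)$sald2), "excluded")
  expect_error(code_sald(pair, 3), class = "twinliab_validation_error")
  expect_error(code_sald(base_pair(atac1 = 5L), 1),
               class = "twinliab_validation_error")
})

test_that("coding is idempotent and independent of record order", {
  cfg <- sim_config(pairs_per_group = c(MZM = 300, DZOS = 300), seed = 31,
                    comorbidity_rates = c(autism = 0.05, hearing = 0.03))
  x <- simulate_cohort(cfg)
  coded <- code_sald(x, 2)
  expect_identical(code_sald(coded, 2)[names(coded)], coded)
  shuffled <- code_sald(x[sample(nrow(x)), ], 2)
  expect_identical(dplyr::arrange(shuffled, pair_id),
                   dplyr::arrange(coded, pair_id))
})

test_that("model 2 analysis set is nested in model 1", {
  cfg <- sim_config(pairs_per_group = c(MZM = 1000, DZF = 1000, DZOS = 1000),
                    seed = 32,
                    comorbidity_rates = c(autism = 0.02,
                                          intellectual_disability = 0.01,
                                          hearing = 0.02))
  x <- simulate_cohort(cfg)
  a1 <- pair_analysis_set(code_sald(x, 1))
  a2 <- pair_analysis_set(code_sald(x, 2))
  key <- function(a) paste(a$individuals$pair_id, a$individuals$twin)
  expect_true(all(key(a2) %in% key(a1)))
  expect_lte(sum(a2$individuals$affected), sum(a1$individuals$affected))
  expect_lte(nrow(a2$pairs), nrow(a1$pairs))
})

test_that("analysis sets use individual prevalence and complete-pair denominators", {
  pairs <- dplyr::bind_rows(
    base_pair(pair_id = "one_excluded", atac1 = 2L, hearing1 = TRUE,
              atac2 = 1L),
    base_pair(pair_id = "complete", atac1 = 1L, atac2 = 0L),
    base_pair(pair_id = "one_missing", atac1 = NA_integer_, atac2 = 2L)
  )
  aset <- pair_analysis_set(code_sald(pairs, 1))
  # excluded and missing twins drop from prevalence; their co-twins stay
  expect_equal(nrow(aset$individuals), 4)
  expect_equal(nrow(aset$pairs), 1)
  expect_equal(aset$flow$n[aset$flow$step == "excluded"], 1)
  expect_equal(aset$flow$n[aset$flow$step == "missing_phenotype"], 1)
  # without exclusions, pair count equals record count
  clean <- dplyr::bind_rows(base_pair(pair_id = "a"), base_pair(pair_id = "b"))
  expect_equal(nrow(pair_analysis_set(code_sald(clean, 1))$pairs), 2)
  all_excluded <- base_pair(hearing1 = TRUE, hearing2 = TRUE)
  expect_error(pair_analysis_set(code_sald(all_excluded, 1)),
               class = "twinliab_empty_analysis_set")
})

test_that("exclusion tallies match the configured flag rates", {
  rate <- 0.05
  cfg <- sim_config(pairs_per_group = c(MZM = 2000, DZF = 2000), seed = 33,
                    comorbidity_rates = c(hearing = rate))
  aset <- pair_analysis_set(code_sald(simulate_cohort(cfg), 1))
  n <- 8000
  removed <- aset$flow$n[aset$flow$step == "excluded"]
  expect_equal(removed, n * rate,
               tolerance = 3 * sqrt(n * rate * (1 - rate)) / (n * rate))
})

test_that("cause tallies reproduce the documented category breakdown", {
  tally <- tabulate_causes(table2_fixture())
  expect_equal(attr(tally, "n_indicated"), 512)
  expect_equal(attr(tally, "n_responded"), 479)
  expect_equal(attr(tally, "responded_pct"), 93.5, tolerance = 0.001)
  dld <- tally[tally$category == "DLD", ]
  expect_equal(dld$n, 95)
  expect_equal(dld$pct, 19.8, tolerance = 0.002)
  expect_equal(tally$pct_male[tally$category == "SSD"], 16.3,
               tolerance = 0.002)
  # per-category sex counts add up to the overall counts; counts to responders
  expect_equal(tally$n_male + tally$n_female, tally$n)
  expect_equal(sum(tally$n), 479)
})

test_that("cause tallies validate vocabulary and handle empty input", {
  bad <- cause_rows("ear wax verbatim", "male")
  expect_error(tabulate_causes(bad), class = "twinliab_validation_error")
  empty <- tabulate_causes(cause_rows(character(0), character(0)))
  expect_true(all(empty$n == 0))
  expect_true(all(is.na(empty$pct)))
})
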