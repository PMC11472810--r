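test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(a2 = 0.5, c2 = 0.5, e2 = 0.5),
               class = "twinliab_validation_error")
  expect_error(sim_config(pairs_per_group = c(MZM = -5)),
               class = "twinliab_validation_error")
  expect_error(sim_config(pairs_per_group = c(XX = 10)),
               class = "twinliab_validation_error")
  expect_error(sim_config(prevalence_male = 0),
               class = "twinliab_validation_error")
  expect_error(sim_config(cause_distribution = c(bogus_label = 1)),
               class = "twinliab_validation_error")
  expect_silent(sim_config(cause_distribution = catss_cause_distribution()))
})

test_that("simulation is reproducible and per-group streams are stable", {
  cfg <- sim_config(pairs_per_group = c(MZM = 200, DZOS = 300), seed = 11,
                    comorbidity_rates = c(hearing = 0.05),
                    cause_distribution = catss_cause_distribution())
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  # adding a group must not perturb draws of existing groups
  cfg2 <- sim_config(pairs_per_group = c(MZM = 200, DZM = 150, DZOS = 300),
                     seed = 11, comorbidity_rates = c(hearing = 0.05),
                     cause_distribution = catss_cause_distribution())
  a <- dplyr::filter(simulate_cohort(cfg), zygosity_group %in% c("MZM", "DZOS"))
  b <- dplyr::filter(simulate_cohort(cfg2), zygosity_group %in% c("MZM", "DZOS"))
  expect_identical(a, b)
})

test_that("sex composition and response coding constraints hold on every record", {
  cfg <- sim_config(pairs_per_group = c(MZM = 150, MZF = 150, DZM = 150,
                                        DZF = 150, DZOS = 150), seed = 5)
  x <- simulate_cohort(cfg)
  same <- x$zygosity_group != "DZOS"
  expect_true(all(x$sex1[same] == x$sex2[same]))
  expect_true(all(x$sex1[!same] == "male" & x$sex2[!same] == "female"))
  expect_true(all(x$atac1 %in% 0:2 & x$atac2 %in% 0:2))
})

test_that("independence case yields near-zero twin correlations", {
  cfg <- sim_config(pairs_per_group = c(MZM = 20000, DZF = 20000),
                    a2 = 0, c2 = 0, e2 = 1, seed = 8)
  tabs <- cohort_tables(cfg)
  tc <- tetrachoric_by_class(tabs)
  expect_true(all(abs(tc$rho) < 0.06))
})

test_that("pure additive genetics gives MZ correlation near 1 and DZ near 0.5", {
  cfg <- sim_config(pairs_per_group = c(MZM = 20000, DZM = 20000),
                    a2 = 1, c2 = 0, e2 = 0, seed = 9)
  tabs <- cohort_tables(cfg)
  tc <- tetrachoric_by_class(tabs)
  expect_gte(tc$rho[tc$class == "MZ"], 0.99)
  expect_equal(tc$rho[tc$class == "DZ"], 0.5, tolerance = 0.05)
})

test_that("pooled prevalence matches the sex-specific thresholds", {
  cfg <- sim_config(seed = 12) # registry-scale defaults
  x <- simulate_cohort(cfg)
  prev <- mean(c(x$atac1, x$atac2) > 0)
  n <- 2 * nrow(x)
  expected <- (0.1061 * 16946 + 0.0503 * 16602) / 33548 # 0.07848
  # twins are correlated within pairs, so allow twice the binomial SE margin
  expect_equal(prev, expected, tolerance = 6 * sqrt(expected * (1 - expected) / n) / expected)
})

test_that("empirical concordance converges to the orthant probabilities", {
  a2 <- 0.6; c2 <- 0.2
  cfg <- sim_config(pairs_per_group = c(MZM = 200000, DZF = 200000),
                    a2 = a2, c2 = c2, e2 = 0.2, seed = 13)
  tabs <- cohort_tables(cfg)
  for (i in seq_len(nrow(tabs))) {
    r <- if (tabs$zygosity[i] == "MZ") a2 + c2 else 0.5 * a2 + c2
    tau <- qnorm(1 - if (tabs$sex1[i] == "male") 0.1061 else 0.0503)
    p11 <- bvn_upper_orthant(tau, tau, r)
    p1 <- pnorm(-tau)
    probs <- c(p00 = 1 - 2 * p1 + p11, p01 = p1 - p11, p10 = p1 - p11,
               p11 = p11)
    obs <- as.numeric(tabs[i, c("n00", "n01", "n10", "n11")]) / tabs$n_pairs[i]
    se <- sqrt(probs * (1 - probs) / tabs$n_pairs[i])
    expect_true(all(abs(obs - probs) <= 3 * se))
  }
})

test_that("cohort and configuration files round-trip", {
  cfg <- sim_config(pairs_per_group = c(MZF = 80, DZOS = 120), seed = 21,
                    comorbidity_rates = c(autism = 0.01, hearing = 0.02),
                    cause_distribution = catss_cause_distribution())
  x <- simulate_cohort(cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(x, f)
  expect_equal(as.data.frame(read_cohort(f)), as.data.frame(x))
  g <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, g)
  cfg2 <- read_sim_config(g)
  expect_identical(simulate_cohort(cfg2), x)
})
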