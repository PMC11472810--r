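test_that("probability-exact tables recover the generating ACE components", {
  tabs <- make_exact_tables(a2 = 0.6, c2 = 0.2, tau_m = 1.2, tau_f = 1.2,
                            N = 1000)
  fit <- fit_variance_model(tabs, "ACE")
  est <- setNames(fit$components$estimate, fit$components$component)
  expect_equal(unname(est["a2"]), 0.6, tolerance = 1e-2)
  expect_equal(unname(est["c2"]), 0.2, tolerance = 1e-2)
  expect_equal(unname(est["e2"]), 0.2, tolerance = 1e-2)
  expect_equal(fit$thresholds$tau, c(1.2, 1.2), tolerance = 1e-3)
  expect_true(fit$converged)
  expect_equal(sum(fit$components$estimate), 1, tolerance = 1e-9)
})

test_that("optimised ACE solution agrees with a dense simplex grid search", {
  tabs <- make_exact_tables(a2 = 0.6, c2 = 0.2, tau_m = 1.2, tau_f = 1.2,
                            N = 1000)
  fit <- fit_variance_model(tabs, "ACE")
  # independent oracle: grid over (a2, c2) at step 0.005, thresholds at the
  # (exact) margin probits, cell probabilities from mvtnorm
  step <- 0.005
  grid <- expand.grid(a2 = seq(0, 1, by = step), c2 = seq(0, 1, by = step))
  grid <- grid[grid$a2 + grid$c2 <= 1, ]
  orth <- function(tau, r) {
    if (abs(r) < 1e-12) return(pnorm(-tau)^2)
    if (r >= 1 - 1e-12) return(pnorm(-tau))
    mvtnorm::pmvnorm(lower = c(tau, tau), upper = c(Inf, Inf),
                     corr = matrix(c(1, r, r, 1), 2),
                     algorithm = mvtnorm::Miwa(steps = 129))
  }
  tau <- 1.2
  m2ll_at <- function(a2, c2) {
    tot <- 0
    for (i in seq_len(nrow(tabs))) {
      r <- if (tabs$zygosity[i] == "MZ") a2 + c2 else 0.5 * a2 + c2
      p11 <- orth(tau, r)
      p1 <- pnorm(-tau)
      p <- pmax(c(1 - 2 * p1 + p11, p1 - p11, p1 - p11, p11), 1e-12)
      n <- as.numeric(tabs[i, c("n00", "n01", "n10", "n11")])
      tot <- tot - 2 * sum(n * log(p))
    }
    tot
  }
  vals <- mapply(m2ll_at, grid$a2, grid$c2)
  best <- grid[which.min(vals), ]
  est <- setNames(fit$components$estimate, fit$components$component)
  expect_equal(unname(est["a2"]), best$a2, tolerance = 0.01)
  expect_equal(unname(est["c2"]), best$c2, tolerance = 0.01)
})

test_that("saturated model reproduces observed proportions and the analytic -2LL", {
  cfg <- sim_config(pairs_per_group = c(MZM = 800, MZF = 800, DZM = 800,
                                        DZF = 800, DZOS = 800), seed = 51)
  tabs <- cohort_tables(cfg)
  sat <- fit_saturated(tabs)
  obs <- as.matrix(tabs[, c("n00", "n01", "n10", "n11")]) / tabs$n_pairs
  expect_lt(max(abs(as.matrix(sat$fitted_probs[, 2:5]) - obs)), 1e-9)
  analytic <- -2 * sum(apply(tabs[, c("n00", "n01", "n10", "n11")], 1,
                             function(n) {
                               n <- as.numeric(n); N <- sum(n); n <- n[n > 0]
                               sum(n * log(n / N))
                             }))
  expect_equal(sat$minus2LL, analytic, tolerance = 1e-10)
  expect_equal(sat$n_parameters, 11) # 2 per same-sex group + 3 for DZOS
})

test_that("threshold equality across zygosity costs nothing when true", {
  tabs <- make_exact_tables(a2 = 0.5, c2 = 0.25, tau_m = 1.1, tau_f = 1.5,
                            N = 2000)
  free <- fit_saturated(tabs)
  constrained <- fit_saturated(tabs, constraints = "sex_thresholds")
  expect_lt(constrained$minus2LL - free$minus2LL, 0.01)
  expect_equal(constrained$n_parameters, 7) # 2 thresholds + 5 correlations
  byclass <- fit_saturated(tabs, constraints = "sex_thresholds",
                           correlation_pattern = "zygosity_class")
  expect_equal(byclass$n_parameters, 5)
  expect_lt(byclass$minus2LL - free$minus2LL, 0.01)
})

test_that("-2LL is monotone along the nested model ladder", {
  cfg <- sim_config(pairs_per_group = c(MZM = 600, MZF = 600, DZM = 600,
                                        DZF = 600, DZOS = 600), seed = 52)
  tabs <- cohort_tables(cfg)
  fits <- list(saturated = fit_saturated(tabs))
  for (m in c("ACE", "AE", "CE", "E")) {
    fits[[m]] <- fit_variance_model(tabs, m)
  }
  m2 <- vapply(fits, `[[`, numeric(1), "minus2LL")
  expect_lte(m2[["saturated"]], m2[["ACE"]] + 1e-6)
  expect_lte(m2[["ACE"]], m2[["AE"]] + 1e-6)
  expect_lte(m2[["ACE"]], m2[["CE"]] + 1e-6)
  expect_lte(m2[["AE"]], m2[["E"]] + 1e-6)
  expect_lte(m2[["CE"]], m2[["E"]] + 1e-6)
  # E model: no familial resemblance
  e_comp <- setNames(fits$E$components$estimate, fits$E$components$component)
  expect_equal(unname(e_comp["a2"]), 0)
  expect_equal(unname(e_comp["c2"]), 0)
  expect_equal(unname(implied_correlations(fits$E)$rMZ), 0)
})

test_that("likelihood-ratio tests respect nesting and degenerate comparisons", {
  tabs <- make_exact_tables(a2 = 0.5, c2 = 0.2, N = 500)
  ace <- fit_variance_model(tabs, "ACE")
  ae <- fit_variance_model(tabs, "AE")
  ce <- fit_variance_model(tabs, "CE")
  self <- likelihood_ratio_test(ace, ace)
  expect_equal(self$delta_chi2, 0)
  expect_equal(self$p, 1)
  lrt <- likelihood_ratio_test(ae, ace)
  expect_gte(lrt$delta_chi2, 0)
  expect_equal(lrt$delta_df, 1)
  expect_error(likelihood_ratio_test(ae, ce),
               class = "twinliab_validation_error")
  expect_error(likelihood_ratio_test(ace, ae),
               class = "twinliab_validation_error")
})

test_that("implied correlations follow the additive-genetic sharing rule", {
  ic <- implied_correlations(0.75, 0.22)
  expect_equal(ic$rMZ, 0.97)
  expect_equal(ic$rDZ, 0.595)
  expect_equal(implied_correlations(0, 0), tibble::tibble(rMZ = 0, rDZ = 0))
  tabs <- make_exact_tables(a2 = 0.4, c2 = 0.3, N = 800)
  fit <- fit_variance_model(tabs, "ACE")
  ic2 <- implied_correlations(fit)
  expect_equal(ic2$rMZ, 0.7, tolerance = 0.01)
  expect_lte(ic2$rDZ, ic2$rMZ)
  expect_error(implied_correlations(0.5), class = "twinliab_validation_error")
})

test_that("profile intervals match the Wald quadratic approximation at interior optima", {
  tabs <- make_exact_tables(a2 = 0.5, c2 = 0.3, tau_m = 1.0, tau_f = 1.0,
                            N = 4000)
  fit <- fit_variance_model(tabs, "ACE")
  ci <- profile_ci(fit, "a2")
  curv <- profile_m2ll(fit, "a2",
                       ci$estimate + c(-0.02, 0, 0.02))$minus2LL
  hess <- (curv[1] - 2 * curv[2] + curv[3]) / 0.02^2
  wald_half <- qnorm(0.975) * sqrt(2 / hess)
  expect_equal(ci$ci_high - ci$ci_low, 2 * wald_half, tolerance = 0.05)
  expect_false(ci$boundary_low || ci$boundary_high)
})

test_that("components estimated at zero get a zero lower bound with a flag", {
  tabs <- make_exact_tables(a2 = 0.6, c2 = 0, N = 2000)
  fit <- fit_variance_model(tabs, "ACE")
  c2 <- fit$components$estimate[fit$components$component == "c2"]
  expect_lt(c2, 1e-3)
  expect_true("c2" %in% fit$boundary)
  ci <- profile_ci(fit, "c2")
  expect_equal(ci$ci_low, 0)
  expect_true(ci$boundary_low)
})

test_that("shared-environment effects are detected with high power at scale", {
  # AE vs ACE on multinomial draws from exact cell probabilities
  a2 <- 0.45; c2 <- 0.25
  template <- make_exact_tables(a2 = a2, c2 = c2, tau_m = 1.25, tau_f = 1.64,
                                N = 1)
  n_per_group <- 4000
  set.seed(53)
  hits <- vapply(seq_len(200), function(i) {
    tabs <- template
    for (j in seq_len(nrow(tabs))) {
      p <- as.numeric(tabs[j, c("n00", "n01", "n10", "n11")])
      draw <- as.numeric(rmultinom(1, n_per_group, p))
      tabs[j, c("n00", "n01", "n10", "n11")] <- as.list(draw)
      tabs$n_pairs[j] <- n_per_group
    }
    ace <- fit_variance_model(tabs, "ACE", n_starts = 2)
    ae <- fit_variance_model(tabs, "AE", n_starts = 2)
    likelihood_ratio_test(ae, ace)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("registry-scale recovery is unbiased with calibrated interval coverage", {
  exp <- recovery_experiment()
  expect_true(all(abs(exp$bias) <= 0.02))
  expect_gte(exp$a2_cover, 0.90)
  expect_lte(exp$a2_cover, 0.99)
  expect_true(all(exp$converged))
})
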