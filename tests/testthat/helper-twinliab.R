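# shared fixtures and memoised heavy experiments

# probability-exact concordance tables: counts = N * cell probabilities at the
# generating parameters, so the ML optimum sits exactly at those parameters
make_exact_tables <- function(a2, c2, tau_m = 1.2, tau_f = 1.2, N = 1000) {
  info <- tibble::tibble(
    group    = c("MZM", "MZF", "DZM", "DZF", "DZOS"),
    zygosity = c("MZ", "MZ", "DZ", "DZ", "DZ"),
    sex1     = c("male", "female", "male", "female", "male"),
    sex2     = c("male", "female", "male", "female", "female")
  )
  tau <- c(male = tau_m, female = tau_f)
  rows <- lapply(seq_len(nrow(info)), function(i) {
    r <- if (info$zygosity[i] == "MZ") a2 + c2 else 0.5 * a2 + c2
    t1 <- tau[[info$sex1[i]]]; t2 <- tau[[info$sex2[i]]]
    p11 <- bvn_upper_orthant(t1, t2, r)
    p1 <- pnorm(-t1); p2 <- pnorm(-t2)
    tibble::tibble(group = info$group[i], zygosity = info$zygosity[i],
                   sex1 = info$sex1[i], sex2 = info$sex2[i],
                   n00 = N * (1 - p1 - p2 + p11), n01 = N * (p2 - p11),
                   n10 = N * (p1 - p11), n11 = N * p11, n_pairs = N)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("group_table", class(out))
  out
}

# cohort -> group tables shortcut
cohort_tables <- function(cfg, model = 1) {
  group_tables(pair_analysis_set(code_sald(simulate_cohort(cfg), model))$pairs)
}

# 100-replicate parameter-recovery experiment at registry-scale group sizes,
# generating components (0.75, 0.22, 0.03); memoised because two test files
# consume it (bias and profile-CI coverage)
recovery_experiment <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    true <- c(a2 = 0.75, c2 = 0.22, e2 = 0.03)
    reps <- lapply(seq_len(100), function(i) {
      cfg <- sim_config(seed = 202600 + i)
      tabs <- cohort_tables(cfg)
      fit <- fit_variance_model(tabs, "ACE", n_starts = 2, ci = "none")
      ci <- profile_ci(fit, "a2")
      est <- setNames(fit$components$estimate, fit$components$component)
      list(est = est, a2_lo = ci$ci_low, a2_hi = ci$ci_high,
           converged = fit$converged)
    })
    est <- do.call(rbind, lapply(reps, `[[`, "est"))
    cache <<- list(
      true = true,
      estimates = est,
      bias = colMeans(est) - true,
      a2_cover = mean(vapply(reps, function(r)
        r$a2_lo <= true[["a2"]] && true[["a2"]] <= r$a2_hi, logical(1))),
      converged = vapply(reps, `[[`, logical(1), "converged")
    )
    cache
  }
})

# cohort rows holding one twin's follow-up cause each, for cause tallies
cause_rows <- function(cause, sex) {
  n <- length(cause)
  tibble::tibble(
    pair_id = sprintf("fix_%04d", seq_len(n)),
    zygosity_group = "DZOS",
    sex1 = sex, sex2 = as.character(ifelse(sex == "male", "female", "male")),
    atac1 = 1L, atac2 = 0L,
    cause1 = cause, cause2 = NA_character_,
    autism1 = FALSE, autism2 = FALSE, id1 = FALSE, id2 = FALSE,
    hearing1 = FALSE, hearing2 = FALSE, acquired1 = FALSE, acquired2 = FALSE,
    chrom1 = FALSE, chrom2 = FALSE
  )
}

# Table-2-style fixture: 512 twins indicating a cause, 479 with categorised
# open-ended answers (331 male, 148 female), 33 without
table2_fixture <- function() {
  male <- c(DLD = 69, LD_due_to_ID_or_autism = 54, hearing = 58,
            acquired_medical = 49, SSD = 54, not_specified = 35,
            DLD_and_or_SSD = 12)
  female <- c(DLD = 26, LD_due_to_ID_or_autism = 33, hearing = 25,
              acquired_medical = 31, SSD = 12, not_specified = 16,
              DLD_and_or_SSD = 5)
  dplyr::bind_rows(
    cause_rows(rep(names(male), male), "male"),
    cause_rows(rep(names(female), female), "female"),
    cause_rows(rep("indicated_no_response", 33), "male")
  )
}
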