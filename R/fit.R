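# Liability-threshold variance-component models over zygosity-group tables.
#
# All models maximise the joint multinomial likelihood of the per-group
# concordance tables, with cell probabilities from the bivariate-normal
# orthant kernel. Group correlations are structured as rMZ = a^2 + c^2 and
# rDZ = rDZOS = 0.5 a^2 + c^2; thresholds are shared across zygosity
# (one per sex by default). Path coefficients (a, c) are optimised on the
# constrained simplex a^2 + c^2 <= 1 with e^2 = 1 - a^2 - c^2.

# -2 log likelihood of all tables at given per-sex thresholds and components
vm_m2ll <- function(tables, tau, a, c_) {
  if (a < 0 || c_ < 0 || a > 1 || c_ > 1 || a^2 + c_^2 > 1) {
    return(1e10 + 1e4 * (max(0, a^2 + c_^2 - 1) + max(0, -a) + max(0, -c_)))
  }
  a2 <- a^2; c2 <- c_^2
  total <- 0
  for (i in seq_len(nrow(tables))) {
    r <- group_correlation(tables$zygosity[i], a2, c2)
    p <- liability_cell_probs(tau[[tables$sex1[i]]], tau[[tables$sex2[i]]], r)
    n <- c(tables$n00[i], tables$n01[i], tables$n10[i], tables$n11[i])
    total <- total - 2 * sum(n * log(p))
  }
  total
}

# map a flat parameter vector onto (tau named by sex, a, c) for a model
vm_decode <- function(par, sexes, model, pattern) {
  par <- unname(par)
  ntau <- if (pattern == "single") 1L else length(sexes)
  tau_vals <- par[seq_len(ntau)]
  tau <- if (pattern == "single") {
    setNames(rep(tau_vals, length(sexes)), sexes)
  } else {
    setNames(tau_vals, sexes)
  }
  rest <- par[-seq_len(ntau)]
  switch(model,
         ACE = list(tau = tau, a = rest[1], c = rest[2]),
         AE  = list(tau = tau, a = rest[1], c = 0),
         CE  = list(tau = tau, a = 0, c = rest[1]),
         E   = list(tau = tau, a = 0, c = 0))
}

vm_n_component_pars <- function(model) {
  switch(model, ACE = 2L, AE = 1L, CE = 1L, E = 0L)
}

# pooled per-sex affected margins across tables -> probit threshold starts
vm_threshold_starts <- function(tables, sexes) {
  vapply(sexes, function(s) {
    aff <- sum(ifelse(tables$sex1 == s, tables$n10 + tables$n11, 0) +
                 ifelse(tables$sex2 == s, tables$n01 + tables$n11, 0))
    tot <- sum((tables$sex1 == s) * tables$n_pairs +
                 (tables$sex2 == s) * tables$n_pairs)
    qnorm(1 - clamp01(aff / tot))
  }, numeric(1))
}

# documented component starting points spanning the feasible range
vm_component_starts <- function(model, n_starts = 5) {
  f <- seq(0.1, 0.9, length.out = n_starts)
  switch(model,
         ACE = lapply(f, function(x) c(sqrt(0.75 * x), sqrt(0.25 * x))),
         AE  = lapply(f, function(x) sqrt(x)),
         CE  = lapply(f, function(x) sqrt(x)),
         E   = list(numeric(0)))
}

#' Fit a liability-threshold variance-component model
#'
#' Maximum-likelihood ACE, AE, CE or E decomposition of liability variance
#' from zygosity-group concordance tables. Group liability correlations are
#' \eqn{a^2 + c^2} for MZ groups and \eqn{0.5 a^2 + c^2} for DZ groups
#' (same- and opposite-sex alike); thresholds are shared across zygosity,
#' one per sex by default. Components are parameterised as path coefficients
#' \eqn{(a, c)} on the constrained simplex so that \eqn{a^2, c^2,
#' e^2 = 1 - a^2 - c^2} all stay in \eqn{[0, 1]}. Optimisation is
#' Nelder-Mead from several documented starting points; the best converged
#' solution is kept and a component estimated at zero is flagged as a
#' boundary solution.
#'
#' @param tables A [group_tables()] tibble with at least one MZ and one DZ
#'   group for models containing A or C.
#' @param model `"ACE"`, `"AE"`, `"CE"` or `"E"`.
#' @param threshold_pattern `"sex"` (one threshold per sex, default) or
#'   `"single"` (one threshold overall).
#' @param n_starts Number of component starting points.
#' @param ci `"profile"` to attach profile-likelihood confidence intervals to
#'   the free components, `"none"` to skip (faster).
#' @param level Confidence level for `ci = "profile"`.
#' @return An object of class `ace_fit` (also `twin_fit`): a list with
#'   `components` (tibble of a2/c2/e2 estimates and CIs), `thresholds`,
#'   `minus2LL`, `n_parameters`, `df`, `converged`, `boundary`, per-start
#'   diagnostics, and the tables the fit used.
#' @examples
#' cfg <- sim_config(pairs_per_group = c(MZM = 400, DZM = 400), a2 = 0.6,
#'                   c2 = 0.2, e2 = 0.2, seed = 3)
#' tabs <- group_tables(pair_analysis_set(code_sald(simulate_cohort(cfg)))$pairs)
#' fit_variance_model(tabs, "ACE", ci = "none")
#' @export
fit_variance_model <- function(tables, model = c("ACE", "AE", "CE", "E"),
                               threshold_pattern = c("sex", "single"),
                               n_starts = 5,
                               ci = c("none", "profile"), level = 0.95) {
  model <- match.arg(model)
  threshold_pattern <- match.arg(threshold_pattern)
  ci <- match.arg(ci)
  check_tables(tables)
  if (model != "E" && !all(c("MZ", "DZ") %in% tables$zygosity)) {
    validation_error("Models with A or C require at least one MZ and one DZ group.")
  }
  sexes <- sort(unique(c(tables$sex1, tables$sex2)))
  tau0 <- vm_threshold_starts(tables, sexes)
  ntau <- if (threshold_pattern == "single") 1L else length(sexes)
  tau_start <- if (threshold_pattern == "single") mean(tau0) else tau0

  obj <- function(par) {
    d <- vm_decode(par, sexes, model, threshold_pattern)
    vm_m2ll(tables, d$tau, d$a, d$c)
  }
  starts <- vm_component_starts(model, n_starts)
  runs <- purrr::map(starts, function(cs) {
    par0 <- c(tau_start, cs)
    if (length(par0) == 1) {
      o <- optimize(function(x) obj(x), interval = tau_start + c(-2, 2),
                    tol = 1e-9)
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      optim(par0, obj, method = "Nelder-Mead",
            control = list(reltol = 1e-10, maxit = 5000))
    }
  })
  values <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(values)]]
  d <- vm_decode(best$par, sexes, model, threshold_pattern)
  a2 <- d$a^2; c2 <- d$c^2; e2 <- max(0, 1 - a2 - c2)

  n_cells <- sum(ifelse(tables$sex1 == tables$sex2, 2L, 3L))
  n_par <- ntau + vm_n_component_pars(model)
  free <- switch(model, ACE = c("a2", "c2"), AE = "a2", CE = "c2", E = character(0))
  boundary <- free[c(a2, c2)[match(free, c("a2", "c2"))] < 1e-4]

  comp <- tibble::tibble(
    component = c("a2", "c2", "e2"),
    estimate = c(a2, c2, e2),
    ci_low = NA_real_, ci_high = NA_real_,
    free = c("a2", "c2", "e2") %in% c(free, if (model != "E") "e2")
  )
  fit <- structure(list(
    model = model,
    components = comp,
    thresholds = tibble::tibble(sex = sexes,
                                tau = unname(d$tau[sexes]),
                                prevalence = pnorm(-unname(d$tau[sexes]))),
    minus2LL = best$value,
    n_parameters = n_par,
    df = n_cells - n_par,
    n_cells = n_cells,
    n_pairs = sum(tables$n_pairs),
    converged = (best$convergence %||% 0L) == 0L,
    boundary = boundary,
    threshold_pattern = threshold_pattern,
    sexes = sexes,
    tables = tables,
    starts = tibble::tibble(start = seq_along(runs),
                            minus2LL = values,
                            convergence = vapply(runs, function(r)
                              as.integer(r$convergence %||% 0L), integer(1)))
  ), class = c("ace_fit", "twin_fit"))
  if (!fit$converged) {
    warn(sprintf("%s fit did not converge from any starting point; inspect $starts.",
                 model))
  }
  if (ci == "profile") {
    for (cmp in comp$component[comp$free]) {
      int <- profile_ci(fit, cmp, level = level)
      fit$components$ci_low[fit$components$component == cmp] <- int$ci_low
      fit$components$ci_high[fit$components$component == cmp] <- int$ci_high
    }
  }
  fit
}

check_tables <- function(tables) {
  need <- c("group", "zygosity", "sex1", "sex2", "n00", "n01", "n10", "n11",
            "n_pairs")
  if (!is.data.frame(tables) || !all(need %in% names(tables))) {
    validation_error("`tables` must come from group_tables().")
  }
  if (nrow(tables) < 1 || any(tables$n_pairs <= 0)) {
    validation_error("Each table must contain at least one pair.")
  }
  invisible(tables)
}

#' Fit the saturated threshold model
#'
#' The saturated model gives every group its own thresholds and latent
#' correlation, reproducing the observed cell proportions exactly; its
#' \eqn{-2\log L} equals the multinomial saturated value
#' \eqn{-2\sum n_{ij} \log(n_{ij}/N)} and serves as the reference for
#' likelihood-ratio comparison. With `constraints = "sex_thresholds"`,
#' thresholds are shared per sex across zygosity (correlations remain free
#' per group or per zygosity class), which tests the threshold-equality
#' assumption.
#'
#' @inheritParams fit_variance_model
#' @param constraints `"none"` (default, exact fit) or `"sex_thresholds"`.
#' @param correlation_pattern When constrained: `"group"` (one correlation
#'   per zygosity-by-sex group) or `"zygosity_class"` (shared within MZ,
#'   same-sex DZ, and DZOS).
#' @return An object of class `saturated_fit` (also `twin_fit`) with
#'   per-group estimates, fitted cell probabilities, `minus2LL`,
#'   `n_parameters` and `df`.
#' @export
fit_saturated <- function(tables, constraints = c("none", "sex_thresholds"),
                          correlation_pattern = c("group", "zygosity_class")) {
  constraints <- match.arg(constraints)
  correlation_pattern <- match.arg(correlation_pattern)
  check_tables(tables)
  if (constraints == "none") {
    fit <- saturated_unconstrained(tables)
  } else {
    fit <- saturated_sex_thresholds(tables, correlation_pattern)
  }
  fit
}

saturated_unconstrained <- function(tables) {
  est <- purrr::map_dfr(seq_len(nrow(tables)), function(i) {
    n <- as.numeric(tables[i, c("n00", "n01", "n10", "n11")])
    N <- sum(n)
    p1 <- (n[3] + n[4]) / N
    p2 <- (n[2] + n[4]) / N
    tau1 <- qnorm(1 - clamp01(p1))
    tau2 <- qnorm(1 - clamp01(p2))
    sol <- solve_r_for_p11(tau1, tau2, n[4] / N)
    tibble::tibble(group = tables$group[i], tau1 = tau1, tau2 = tau2,
                   r = sol$r, boundary = sol$boundary)
  })
  fitted <- purrr::map_dfr(seq_len(nrow(est)), function(i) {
    p <- liability_cell_probs(est$tau1[i], est$tau2[i], est$r[i])
    tibble::tibble(group = est$group[i], p00 = p[1], p01 = p[2],
                   p10 = p[3], p11 = p[4])
  })
  m2 <- sum(purrr::map_dbl(seq_len(nrow(tables)), function(i)
    saturated_m2ll(as.numeric(tables[i, c("n00", "n01", "n10", "n11")]))))
  n_par <- sum(ifelse(tables$sex1 == tables$sex2, 2L, 3L))
  n_cells <- n_par
  new_saturated_fit(est, fitted, m2, n_par, n_cells, tables,
                    constraints = "none", converged = TRUE)
}

# monotone-in-r root for the concordant-cell probability
solve_r_for_p11 <- function(tau1, tau2, target) {
  eps <- 1e-9
  g <- function(r) bvn_orthant_1(tau1, tau2, r) - target
  if (g(1 - eps) < 0) return(list(r = 1, boundary = TRUE))
  if (g(-1 + eps) > 0) return(list(r = -1, boundary = TRUE))
  root <- uniroot(g, c(-1 + eps, 1 - eps), tol = 1e-12)
  list(r = root$root, boundary = FALSE)
}

saturated_sex_thresholds <- function(tables, correlation_pattern) {
  sexes <- sort(unique(c(tables$sex1, tables$sex2)))
  tau0 <- vm_threshold_starts(tables, sexes)
  cls <- if (correlation_pattern == "group") {
    tables$group
  } else {
    ifelse(tables$zygosity == "MZ", "MZ",
           ifelse(tables$group == "DZOS", "DZOS", "DZss"))
  }
  # given thresholds, each correlation (per class) maximises its own terms
  inner <- function(tau) {
    tau <- setNames(tau, sexes)
    rows <- split(seq_len(nrow(tables)), cls)
    fits <- purrr::map(rows, function(idx) {
      o <- optimize(function(r) {
        sum(purrr::map_dbl(idx, function(i) {
          p <- liability_cell_probs(tau[[tables$sex1[i]]],
                                    tau[[tables$sex2[i]]], r)
          n <- as.numeric(tables[i, c("n00", "n01", "n10", "n11")])
          -2 * sum(n * log(p))
        }))
      }, interval = c(-0.99999, 0.99999), tol = 1e-9)
      list(r = o$minimum, value = o$objective)
    })
    list(value = sum(purrr::map_dbl(fits, "value")),
         r = purrr::map_dbl(fits, "r"))
  }
  opt <- optim(tau0, function(tau) inner(tau)$value, method = "Nelder-Mead",
               control = list(reltol = 1e-10, maxit = 2000))
  sol <- inner(opt$par)
  tau <- setNames(opt$par, sexes)
  est <- tibble::tibble(
    group = tables$group,
    tau1 = unname(tau[tables$sex1]),
    tau2 = unname(tau[tables$sex2]),
    r = unname(sol$r[cls]),
    boundary = abs(sol$r[cls]) > 0.9995
  )
  fitted <- purrr::map_dfr(seq_len(nrow(est)), function(i) {
    p <- liability_cell_probs(est$tau1[i], est$tau2[i], est$r[i])
    tibble::tibble(group = est$group[i], p00 = p[1], p01 = p[2],
                   p10 = p[3], p11 = p[4])
  })
  n_cells <- sum(ifelse(tables$sex1 == tables$sex2, 2L, 3L))
  n_par <- length(sexes) + length(unique(cls))
  new_saturated_fit(est, fitted, sol$value, n_par, n_cells, tables,
                    constraints = "sex_thresholds",
                    converged = opt$convergence == 0)
}

new_saturated_fit <- function(est, fitted, m2, n_par, n_cells, tables,
                              constraints, converged) {
  structure(list(
    model = "saturated",
    group_estimates = est,
    fitted_probs = fitted,
    minus2LL = m2,
    n_parameters = n_par,
    df = n_cells - n_par,
    n_cells = n_cells,
    n_pairs = sum(tables$n_pairs),
    converged = converged,
    constraints = constraints,
    tables = tables
  ), class = c("saturated_fit", "twin_fit"))
}

#' Likelihood-ratio test between nested threshold models
#'
#' Compares a restricted model against a more general one by the difference
#' in \eqn{-2\log L}, referred to a chi-square distribution with degrees of
#' freedom equal to the difference in free parameters. The nesting ladder is
#' E within AE/CE within ACE within saturated. For comparisons that fix a
#' variance component at its boundary (e.g. AE vs ACE) the naive chi-square
#' reference is used, as is conventional in twin modelling, although the
#' asymptotic null there is a 50:50 mixture of chi-squares, making the test
#' conservative.
#'
#' @param restricted,general Fitted `twin_fit` objects.
#' @return One-row tibble: `restricted`, `general`, `delta_chi2`,
#'   `delta_df`, `p`.
#' @examples
#' # qchisq(0.95, 1) = 3.84 gives p = 0.05 at delta_df = 1
#' @export
likelihood_ratio_test <- function(restricted, general) {
  rank <- c(E = 0, AE = 1, CE = 1, ACE = 2, saturated = 3)
  for (f in list(restricted, general)) {
    if (!inherits(f, "twin_fit") || !f$model %in% names(rank)) {
      validation_error("Both arguments must be fitted twin models.")
    }
  }
  same <- restricted$model == general$model
  nested <- rank[[restricted$model]] < rank[[general$model]] &&
    !(restricted$model == "AE" && general$model == "CE") &&
    !(restricted$model == "CE" && general$model == "AE")
  if (!same && !nested) {
    validation_error(sprintf("Model %s is not nested in %s.",
                             restricted$model, general$model))
  }
  if (restricted$n_parameters > general$n_parameters) {
    validation_error("The restricted model must not have more parameters.")
  }
  delta <- restricted$minus2LL - general$minus2LL
  if (delta < -1e-6) {
    warn(sprintf("Negative likelihood-ratio statistic (%.3g); check convergence.",
                 delta))
  }
  delta <- max(0, delta)
  ddf <- general$n_parameters - restricted$n_parameters
  p <- if (ddf == 0) {
    if (delta <= 1e-12) 1 else 0
  } else {
    pchisq(delta, ddf, lower.tail = FALSE)
  }
  tibble::tibble(restricted = restricted$model, general = general$model,
                 delta_chi2 = delta, delta_df = ddf, p = p)
}

#' Twin correlations implied by variance components
#'
#' \eqn{r_{MZ} = a^2 + c^2} and \eqn{r_{DZ} = 0.5\,a^2 + c^2}: MZ pairs share
#' all additive-genetic and all shared-environmental variance, DZ pairs half
#' the additive-genetic part.
#'
#' @param x Either `a2` (with `c2` supplied) or an `ace_fit`.
#' @param c2 Shared-environment proportion when `x` is numeric.
#' @return One-row tibble with `rMZ` and `rDZ`.
#' @examples
#' implied_correlations(0.75, 0.22)
#' @export
implied_correlations <- function(x, c2 = NULL) {
  if (inherits(x, "ace_fit")) {
    a2 <- x$components$estimate[x$components$component == "a2"]
    c2 <- x$components$estimate[x$components$component == "c2"]
  } else {
    a2 <- x
    if (is.null(c2)) validation_error("Supply `c2` alongside a numeric `a2`.")
  }
  stopifnot_prob(a2, "a2"); stopifnot_prob(c2, "c2")
  tibble::tibble(rMZ = a2 + c2, rDZ = 0.5 * a2 + c2)
}

#' Profile-likelihood confidence interval for a variance component
#'
#' The interval is the set of component values whose profiled
#' \eqn{-2\log L} (all other parameters re-optimised) lies within the
#' chi-square(1) critical value of the minimum, located by root bisection
#' and truncated to \eqn{[0, 1]} with boundary flags.
#'
#' @param fit An `ace_fit`.
#' @param component `"a2"`, `"c2"` or `"e2"`.
#' @param level Confidence level.
#' @return One-row tibble: `component`, `estimate`, `ci_low`, `ci_high`,
#'   `level`, `boundary_low`, `boundary_high`.
#' @export
profile_ci <- function(fit, component = c("a2", "c2", "e2"), level = 0.95) {
  component <- match.arg(component)
  if (!inherits(fit, "ace_fit")) {
    validation_error("`fit` must be a variance-component fit.")
  }
  if (!fit$converged) {
    warn("Profiling a non-converged fit; interval may be unreliable.")
  }
  comp <- fit$components
  est <- comp$estimate[comp$component == component]
  if (!comp$free[comp$component == component]) {
    validation_error(sprintf("Component %s is fixed in the %s model.",
                             component, fit$model))
  }
  prof <- profiled_m2ll_fun(fit, component)
  b <- profile_bounds(estimate = est, m2ll_min = min(fit$minus2LL, prof(est)),
                      prof = prof, lower_limit = 0, upper_limit = 1,
                      level = level)
  tibble::tibble(component = component, estimate = est,
                 ci_low = b$lo, ci_high = b$hi, level = level,
                 boundary_low = b$lo_boundary, boundary_high = b$hi_boundary)
}

#' Profiled -2 log likelihood along one variance component
#'
#' Evaluates the profiled \eqn{-2\log L} (nuisance parameters re-optimised)
#' at the supplied component values — the curve whose chi-square(1) cutoff
#' defines the [profile_ci()] interval. Useful for inspecting likelihood
#' curvature and boundary behaviour.
#'
#' @inheritParams profile_ci
#' @param values Component values in `[0, 1]` at which to profile.
#' @return Tibble with columns `value` and `minus2LL`.
#' @export
profile_m2ll <- function(fit, component = c("a2", "c2", "e2"), values) {
  component <- match.arg(component)
  if (!inherits(fit, "ace_fit")) {
    validation_error("`fit` must be a variance-component fit.")
  }
  prof <- profiled_m2ll_fun(fit, component)
  tibble::tibble(value = values,
                 minus2LL = vapply(values, prof, numeric(1)))
}

# profiled -2LL as a function of one fixed component, warm-started between calls
profiled_m2ll_fun <- function(fit, component) {
  tables <- fit$tables
  sexes <- fit$sexes
  pattern <- fit$threshold_pattern
  model <- fit$model
  ntau <- if (pattern == "single") 1L else length(sexes)
  tau_hat <- if (pattern == "single") mean(fit$thresholds$tau) else fit$thresholds$tau
  a_hat <- sqrt(fit$components$estimate[1])
  c_hat <- sqrt(fit$components$estimate[2])
  env <- new.env()
  env$last <- NULL

  make_obj <- function(x) {
    # returns list(par0, fn) for the nuisance optimisation at fixed component
    # x; bounded nuisance path coefficients are optimised on a logistic scale
    # so the simplex never hits a hard box edge
    if (component == "a2") {
      if (model == "ACE") {
        cmax <- sqrt(max(0, 1 - x))
        if (cmax < 1e-8) {
          list(par0 = tau_hat,
               fn = function(p) vm_m2ll_pattern(tables, p, sexes, pattern,
                                                sqrt(x), 0))
        } else {
          list(par0 = c(tau_hat, qlogis_safe(min(c_hat, cmax) / cmax)),
               fn = function(p) vm_m2ll_pattern(tables, p[seq_len(ntau)], sexes,
                                                pattern, sqrt(x),
                                                cmax * plogis(p[ntau + 1])))
        }
      } else { # AE
        list(par0 = tau_hat,
             fn = function(p) vm_m2ll_pattern(tables, p, sexes, pattern,
                                              sqrt(x), 0))
      }
    } else if (component == "c2") {
      if (model == "ACE") {
        amax <- sqrt(max(0, 1 - x))
        if (amax < 1e-8) {
          list(par0 = tau_hat,
               fn = function(p) vm_m2ll_pattern(tables, p, sexes, pattern,
                                                0, sqrt(x)))
        } else {
          list(par0 = c(tau_hat, qlogis_safe(min(a_hat, amax) / amax)),
               fn = function(p) vm_m2ll_pattern(tables, p[seq_len(ntau)], sexes,
                                                pattern,
                                                amax * plogis(p[ntau + 1]),
                                                sqrt(x)))
        }
      } else { # CE
        list(par0 = tau_hat,
             fn = function(p) vm_m2ll_pattern(tables, p, sexes, pattern,
                                              0, sqrt(x)))
      }
    } else { # e2: a^2 + c^2 = 1 - x, optimise the split for ACE
      s <- max(0, 1 - x)
      if (model == "ACE") {
        v0 <- if (a_hat^2 + c_hat^2 > 0) a_hat^2 / (a_hat^2 + c_hat^2) else 0.5
        list(par0 = c(tau_hat, qlogis_safe(v0)),
             fn = function(p) {
               v <- plogis(p[ntau + 1])
               vm_m2ll_pattern(tables, p[seq_len(ntau)], sexes, pattern,
                               sqrt(s * v), sqrt(s * (1 - v)))
             })
      } else if (model == "AE") {
        list(par0 = tau_hat,
             fn = function(p) vm_m2ll_pattern(tables, p, sexes, pattern,
                                              sqrt(s), 0))
      } else { # CE
        list(par0 = tau_hat,
             fn = function(p) vm_m2ll_pattern(tables, p, sexes, pattern,
                                              0, sqrt(s)))
      }
    }
  }

  function(x) {
    x <- min(1, max(0, x))
    ob <- make_obj(x)
    if (length(ob$par0) == 1) {
      o <- optimize(function(z) ob$fn(z), interval = ob$par0 + c(-1.5, 1.5),
                    tol = 1e-8)
      return(o$objective)
    }
    # nuisance surface can change shape along the profile, so a warm start
    # from the previous point is tried alongside the cold start and the
    # better solution kept
    starts <- list(ob$par0)
    if (!is.null(env$last) && length(env$last) == length(ob$par0)) {
      starts <- c(starts, list(env$last))
    }
    runs <- lapply(starts, function(p0)
      optim(p0, ob$fn, method = "Nelder-Mead",
            control = list(reltol = 1e-9, maxit = 3000)))
    best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
    env$last <- best$par
    best$value
  }
}

vm_m2ll_pattern <- function(tables, tau_vals, sexes, pattern, a, c_) {
  tau <- if (pattern == "single") {
    setNames(rep(tau_vals[1], length(sexes)), sexes)
  } else {
    setNames(tau_vals, sexes)
  }
  vm_m2ll(tables, tau, a, c_)
}

qlogis_safe <- function(p) stats::qlogis(min(1 - 1e-6, max(1e-6, p)))

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf("<%s liability-threshold fit>\n", x$model))
  cat(sprintf("-2LL = %.3f  parameters = %d  df = %d  converged = %s\n",
              x$minus2LL, x$n_parameters, x$df, x$converged))
  if (inherits(x, "ace_fit")) {
    print(x$components)
  } else {
    print(x$group_estimates)
  }
  invisible(x)
}

#' @export
tidy.twin_fit <- function(x, ...) {
  if (inherits(x, "ace_fit")) {
    dplyr::bind_rows(
      dplyr::transmute(x$components, term = .data$component,
                       estimate = .data$estimate,
                       ci_low = .data$ci_low, ci_high = .data$ci_high),
      dplyr::transmute(x$thresholds, term = paste0("tau_", .data$sex),
                       estimate = .data$tau, ci_low = NA_real_,
                       ci_high = NA_real_)
    )
  } else {
    tidyr::pivot_longer(x$group_estimates, c("tau1", "tau2", "r"),
                        names_to = "term", values_to = "estimate") |>
      dplyr::transmute(term = paste(.data$term, .data$group, sep = "_"),
                       estimate = .data$estimate)
  }
}

#' @export
glance.twin_fit <- function(x, ...) {
  tibble::tibble(model = x$model, minus2LL = x$minus2LL,
                 n_parameters = x$n_parameters, df = x$df,
                 n_pairs = x$n_pairs, converged = x$converged)
}
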