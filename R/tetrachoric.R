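#' Maximum-likelihood tetrachoric correlation
#'
#' Estimates the latent bivariate-normal correlation underlying a 2x2
#' concordance table by joint maximum likelihood over the two thresholds and
#' the correlation, with cell probabilities from [bvn_upper_orthant()] and a
#' multinomial likelihood. The 95% confidence interval is obtained by profile
#' likelihood (thresholds re-optimised at each fixed correlation).
#'
#' Degenerate tables with empty off-diagonals and occupied diagonals imply a
#' perfect latent correlation; the estimate is reported at the boundary
#' (+1, or -1 for the reverse pattern) with `boundary = TRUE` rather than
#' failing.
#'
#' @param table A one-row [group_tables()] tibble, or a vector/named vector
#'   of counts `(n00, n01, n10, n11)`.
#' @param level Confidence level for the profile interval.
#' @param ci Compute the profile interval (`TRUE` by default; skip for speed
#'   in simulation loops).
#' @return An object of class `tetrachoric_fit`: a list with `rho`, `ci_low`,
#'   `ci_high`, `tau1`, `tau2`, `minus2LL`, `n`, `converged`, `boundary`.
#' @examples
#' tetrachoric_ml(c(n00 = 400, n01 = 200, n10 = 200, n11 = 400))
#' @export
tetrachoric_ml <- function(table, level = 0.95, ci = TRUE) {
  n <- table_counts(table)
  if (any(n < 0) || sum(n) <= 0) {
    validation_error("Counts must be non-negative with a positive total.")
  }
  if (sum(n > 0) < 2) {
    validation_error("At least two cells must be non-empty.")
  }
  N <- sum(n)
  p1 <- (n[3] + n[4]) / N # twin 1 affected margin
  p2 <- (n[2] + n[4]) / N # twin 2 affected margin

  # perfect-association boundaries
  if (n[2] + n[3] == 0 && n[1] > 0 && n[4] > 0) {
    tau <- qnorm(1 - p1)
    return(new_tetrachoric_fit(rho = 1, tau1 = tau, tau2 = qnorm(1 - p2),
                               minus2LL = saturated_m2ll(n), n = N,
                               converged = TRUE, boundary = TRUE))
  }
  if (n[1] + n[4] == 0 && n[2] > 0 && n[3] > 0) {
    return(new_tetrachoric_fit(rho = -1, tau1 = qnorm(1 - p1),
                               tau2 = qnorm(1 - p2),
                               minus2LL = saturated_m2ll(n), n = N,
                               converged = TRUE, boundary = TRUE))
  }

  m2ll <- function(par) {
    if (abs(par[3]) >= 0.99999) return(1e10 + abs(par[3]))
    p <- liability_cell_probs(par[1], par[2], par[3])
    -2 * sum(n * log(p))
  }
  start <- c(qnorm(1 - clamp01(p1)), qnorm(1 - clamp01(p2)), 0)
  opt <- optim(start, m2ll, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  rho <- opt$par[3]
  fit <- new_tetrachoric_fit(rho = rho, tau1 = opt$par[1], tau2 = opt$par[2],
                             minus2LL = opt$value, n = N,
                             converged = opt$convergence == 0,
                             boundary = abs(rho) > 0.9995)
  if (ci) {
    prof <- function(r0) {
      o <- optim(c(fit$tau1, fit$tau2),
                 function(tt) m2ll(c(tt, r0)),
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-10, maxit = 2000))
      o$value
    }
    b <- profile_bounds(estimate = rho, m2ll_min = fit$minus2LL, prof = prof,
                        lower_limit = -0.99999, upper_limit = 0.99999,
                        level = level)
    fit$ci_low <- max(-1, b$lo)
    fit$ci_high <- min(1, b$hi)
    fit$ci_boundary <- c(lower = b$lo_boundary, upper = b$hi_boundary)
  }
  fit
}

new_tetrachoric_fit <- function(rho, tau1, tau2, minus2LL, n, converged,
                                boundary) {
  structure(list(rho = rho, ci_low = NA_real_, ci_high = NA_real_,
                 tau1 = tau1, tau2 = tau2, minus2LL = minus2LL, n = n,
                 converged = converged, boundary = boundary,
                 ci_boundary = c(lower = FALSE, upper = FALSE)),
            class = "tetrachoric_fit")
}

#' @export
print.tetrachoric_fit <- function(x, ...) {
  cat(sprintf("Tetrachoric correlation: %.4f", x$rho))
  if (!is.na(x$ci_low)) cat(sprintf(" [%.4f, %.4f]", x$ci_low, x$ci_high))
  cat(sprintf("\nThresholds: %.4f, %.4f;  n = %g pairs", x$tau1, x$tau2, x$n))
  if (x$boundary) cat("\n(estimate at the boundary of the parameter space)")
  cat("\n")
  invisible(x)
}

#' @export
tidy.tetrachoric_fit <- function(x, ...) {
  tibble::tibble(
    term = c("rho", "tau1", "tau2"),
    estimate = c(x$rho, x$tau1, x$tau2),
    ci_low = c(x$ci_low, NA, NA),
    ci_high = c(x$ci_high, NA, NA)
  )
}

#' Tetrachoric correlations for each (pooled) zygosity class
#'
#' Convenience wrapper: pools the group tables per [pool_tables()] and fits
#' [tetrachoric_ml()] to each pooled class.
#'
#' @inheritParams pool_tables
#' @param level Confidence level.
#' @return A tibble with one row per class: `class`, `rho`, `ci_low`,
#'   `ci_high`, `n_pairs`, `boundary`.
#' @export
tetrachoric_by_class <- function(tables, pool = "MZ_DZ", level = 0.95) {
  pooled <- pool_tables(tables, pool)
  purrr::map_dfr(seq_len(nrow(pooled)), function(i) {
    f <- tetrachoric_ml(pooled[i, c("n00", "n01", "n10", "n11")], level = level)
    tibble::tibble(class = pooled$class[i], rho = f$rho,
                   ci_low = f$ci_low, ci_high = f$ci_high,
                   n_pairs = pooled$n_pairs[i], boundary = f$boundary)
  })
}

clamp01 <- function(p, eps = 1e-9) pmin(1 - eps, pmax(eps, p))

# multinomial saturated -2 log likelihood of one table
saturated_m2ll <- function(n) {
  N <- sum(n)
  keep <- n > 0
  -2 * sum(n[keep] * log(n[keep] / N))
}

# shared bisection machinery for profile-likelihood bounds
profile_bounds <- function(estimate, m2ll_min, prof, lower_limit, upper_limit,
                           level = 0.95, tol = 1e-4) {
  crit <- qchisq(level, 1)
  # guard against a slightly suboptimal central fit
  target <- m2ll_min + crit
  g <- function(x) prof(x) - target
  find <- function(at_limit, bracket_lo, bracket_hi) {
    gl <- g(at_limit)
    if (is.na(gl) || gl < 0) return(list(x = at_limit, boundary = TRUE))
    root <- uniroot(g, lower = bracket_lo, upper = bracket_hi, tol = tol,
                    extendInt = "no")
    list(x = root$root, boundary = FALSE)
  }
  lo <- if (estimate - lower_limit < 1e-8) {
    list(x = lower_limit, boundary = TRUE)
  } else {
    find(lower_limit, lower_limit, estimate)
  }
  hi <- if (upper_limit - estimate < 1e-8) {
    list(x = upper_limit, boundary = TRUE)
  } else {
    find(upper_limit, estimate, upper_limit)
  }
  list(lo = lo$x, hi = hi$x, lo_boundary = lo$boundary, hi_boundary = hi$boundary)
}
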