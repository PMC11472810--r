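#' Concordance tables by zygosity group
#'
#' Tallies complete analysable pairs into 2x2 concordance counts
#' (`n00`, `n01`, `n10`, `n11` by twin-1/twin-2 affection) per
#' zygosity-by-sex group. Same-sex pairs have no meaningful within-pair
#' ordering, so their tables are double-entered: each pair contributes both
#' orderings at half weight, which symmetrises the off-diagonal
#' (`n01 = n10`) and makes within-pair threshold equality automatic.
#' Opposite-sex pairs are ordered male-first.
#'
#' @param pairs A coded pair tibble in which both twins are analysable
#'   (typically the `pairs` element of [pair_analysis_set()]).
#' @return A tibble of class `group_table` with columns `group`, `zygosity`,
#'   `sex1`, `sex2`, `n00`, `n01`, `n10`, `n11`, `n_pairs`.
#' @export
group_tables <- function(pairs) {
  if (nrow(pairs) == 0) {
    abort("No complete pairs to tabulate.", class = "twinliab_empty_analysis_set")
  }
  info <- zyg_group_info()
  x <- dplyr::mutate(pairs,
                     aff1 = .data$sald1 == "affected",
                     aff2 = .data$sald2 == "affected")
  # order DZOS pairs male-first regardless of input ordering
  swap <- x$zygosity_group == "DZOS" & x$sex1 == "female"
  tmp <- x$aff1[swap]; x$aff1[swap] <- x$aff2[swap]; x$aff2[swap] <- tmp
  out <- x |>
    dplyr::count(.data$zygosity_group, .data$aff1, .data$aff2) |>
    dplyr::mutate(cell = paste0("n", as.integer(.data$aff1), as.integer(.data$aff2))) |>
    dplyr::select("zygosity_group", "cell", "n") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "n", values_fill = 0)
  for (cell in c("n00", "n01", "n10", "n11")) {
    if (!cell %in% names(out)) out[[cell]] <- 0
  }
  out <- dplyr::left_join(out, info, by = c(zygosity_group = "group")) |>
    dplyr::rename(group = "zygosity_group")
  same <- out$sex1 == out$sex2
  off <- (out$n01 + out$n10) / 2
  out$n01[same] <- off[same]
  out$n10[same] <- off[same]
  out <- dplyr::mutate(out, n_pairs = .data$n00 + .data$n01 + .data$n10 + .data$n11)
  out <- dplyr::arrange(out, match(.data$group, zyg_group_levels()))
  res <- dplyr::select(out, "group", "zygosity", "sex1", "sex2",
                       "n00", "n01", "n10", "n11", "n_pairs")
  class(res) <- c("group_table", class(res))
  res
}

#' Pool concordance tables across groups
#'
#' Sums concordance counts within zygosity classes for pooled tetrachoric
#' correlations: either monozygotic versus all dizygotic pairs (the common
#' reporting convention, `"MZ_DZ"`), or keeping same-sex and opposite-sex
#' dizygotic pairs apart (`"MZ_DZss_DZOS"`).
#'
#' @param tables A [group_tables()] tibble.
#' @param pool `"MZ_DZ"` or `"MZ_DZss_DZOS"`.
#' @return A tibble with one row per pooled class and the summed counts.
#' @export
pool_tables <- function(tables, pool = c("MZ_DZ", "MZ_DZss_DZOS")) {
  pool <- match.arg(pool)
  cls <- dplyr::case_when(
    tables$zygosity == "MZ" ~ "MZ",
    pool == "MZ_DZ" ~ "DZ",
    tables$group == "DZOS" ~ "DZOS",
    TRUE ~ "DZss"
  )
  tables |>
    dplyr::mutate(class = cls) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(dplyr::across(c("n00", "n01", "n10", "n11", "n_pairs"), sum),
                     .groups = "drop")
}

# counts in canonical order from a one-row table-like object or named vector
table_counts <- function(x) {
  nm <- c("n00", "n01", "n10", "n11")
  if (is.data.frame(x)) {
    if (nrow(x) != 1) validation_error("Expected a single table (one row).")
    as.numeric(x[1, nm])
  } else if (!is.null(names(x)) && all(nm %in% names(x))) {
    as.numeric(x[nm])
  } else if (length(x) == 4) {
    as.numeric(x)
  } else {
    validation_error("Counts must be a one-row table or vector (n00, n01, n10, n11).")
  }
}
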