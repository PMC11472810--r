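# internal helpers shared across modules

# canonical zygosity-by-sex groups; DZOS records are ordered male-first
zyg_group_info <- function() {
  tibble::tibble(
    group    = c("MZM", "MZF", "DZM", "DZF", "DZOS"),
    zygosity = c("MZ", "MZ", "DZ", "DZ", "DZ"),
    sex1     = c("male", "female", "male", "female", "male"),
    sex2     = c("male", "female", "male", "female", "female")
  )
}

zyg_group_levels <- function() zyg_group_info()$group

validation_error <- function(msg, ...) {
  abort(msg, class = "twinliab_validation_error", ...)
}

stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    validation_error(sprintf("`%s` must be a proportion in [0, 1].", name))
  }
}

# liability correlation implied by (a2, c2) for a zygosity class
group_correlation <- function(zygosity, a2, c2) {
  ifelse(zygosity == "MZ", a2 + c2, 0.5 * a2 + c2)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
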