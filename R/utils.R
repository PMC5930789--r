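# internal helpers

#' @importFrom data.table data.table uniqueN .N
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# nearest-rank (type-1) empirical quantile; CI endpoints must be order
# statistics of the replicate vector
quantile_type1 <- function(x, probs) {
  x <- sort(x)
  n <- length(x)
  idx <- pmax(1L, ceiling(probs * n))
  x[idx]
}

# "68.6 (66.1-71.2)"-style cell, en dash, percentages to 1 decimal
fmt_pct_ci <- function(est, lo, hi, digits = 1) {
  f <- paste0("%.", digits, "f")
  sprintf(paste0(f, " (", f, "–", f, ")"), 100 * est, 100 * lo, 100 * hi)
}

check_enum <- function(x, levels, what, allow_na = FALSE) {
  bad <- !(x %in% levels)
  if (allow_na) bad <- bad & !is.na(x)
  if (any(bad)) {
    stop(sprintf("invalid %s value(s): %s (allowed: %s)", what,
                 paste(unique(x[bad]), collapse = ", "),
                 paste(levels, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must be probabilities in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}

check_rate <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("%s must be non-negative rates", what), call. = FALSE)
  }
  invisible(x)
}
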