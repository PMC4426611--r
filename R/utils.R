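# small internal helpers shared across modules

# round-half-up (10/42 -> 24%), unlike base round()'s round-half-even
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

assert_number <- function(x, name, lower = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower else x >= lower)
  if (!ok) {
    cmp <- if (strict) ">" else ">="
    abort(sprintf("`%s` must be a single finite number %s %s", name, cmp, lower))
  }
  invisible(x)
}

match_analyte <- function(analyte) {
  if (!is.character(analyte) || !all(analyte %in% VENT_ANALYTES)) {
    abort(sprintf("analyte must be one of: %s",
                  paste(VENT_ANALYTES, collapse = ", ")))
  }
  analyte
}

# numeric columns rounded to 6 significant digits for reproducible file diffs
signif_cols <- function(df, digits = 6) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  df
}

write_csv_seeded <- function(df, path, seed = NULL) {
  if (!is.null(seed)) {
    writeLines(sprintf("# seed=%d", as.integer(seed)), path)
    readr::write_csv(signif_cols(df), path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(signif_cols(df), path)
  }
  invisible(path)
}

read_csv_quiet <- function(path, ...) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}
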