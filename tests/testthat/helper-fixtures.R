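# fixtures built in code: scan tables, interval rows, one-row concentration
# records, all small enough to brute-force against

# 42-scan interval (two 21-scan bursts) of a single analyte at given values
burst_scans <- function(channel, values, start_s = 0, analyte = "sulfide",
                        censored = FALSE) {
  stopifnot(length(values) == 42L)
  tibble::tibble(
    time_s = start_s + c((0:20) * 2, 900 + (0:20) * 2),
    channel = channel,
    analyte = analyte,
    concentration_uM = values,
    censored = as.integer(rep_len(censored, 42L))
  )
}

# full 4-channel cycle of constant-concentration intervals
cycle_scans <- function(channels, conc_by_channel, n_hours,
                        analyte = "sulfide") {
  n_int <- n_hours * 2L
  dplyr::bind_rows(lapply(seq_len(n_int) - 1L, function(k) {
    ch <- channels[(k %% 4L) + 1L]
    burst_scans(ch, rep(conc_by_channel[[ch]], 42L), start_s = k * 1800,
                analyte = analyte)
  }))
}

# one-row interval-concentration record, for exercising net_rate directly
conc_row <- function(channel, analyte, set_index, mean_uM, is_bdl = FALSE,
                     start_s = 0) {
  tibble::tibble(channel = channel, analyte = analyte,
                 set_index = set_index, interval_index = NA_integer_,
                 start_s = start_s, mean_uM = mean_uM, is_bdl = is_bdl,
                 n_used = 32L, n_discarded = 10L, frac_censored = 0)
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), rel_tol)
}
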