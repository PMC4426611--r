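#' Per-analyte voltammetric detection limits
#'
#' Concentrations under the electrode's detection limit are censored: the scan
#' is flagged rather than reported as a trustworthy number. Defaults are the
#' working limits of the in-line voltammetric microelectrode for the three
#' sulfur species (micromolar).
#'
#' @param sulfide,thiosulfate,polysulfide Detection limit in uM; all > 0.
#' @return A named numeric vector of class `detection_limits`.
#' @examples
#' detection_limits()
#' detection_limits(thiosulfate = 25)
#' @export
detection_limits <- function(sulfide = 0.20, thiosulfate = 30,
                             polysulfide = 0.20) {
  lim <- c(sulfide = sulfide, thiosulfate = thiosulfate,
           polysulfide = polysulfide)
  if (!all(is.finite(lim)) || any(lim <= 0)) {
    abort("all detection limits must be finite and > 0")
  }
  structure(lim, class = c("detection_limits", "numeric"))
}

#' Channel schedule for one sampling set
#'
#' Effluent and input lines are sampled in a repeating cycle of 30-min
#' intervals. One complete pass over the four channels — the experimental
#' aquaria first, the reference channel (control-aquarium effluent or input
#' water) last — is a 2-h "set".
#'
#' @param channels Character vector of exactly four channel identifiers, in
#'   cycle order; the last entry is the reference channel.
#' @param interval_s Interval length in seconds (default 1800 = 30 min).
#' @return A list of class `set_schedule` with elements `channels`,
#'   `reference_channel`, `interval_s` and `set_duration_s`.
#' @examples
#' set_schedule(c("aq1", "aq2", "aq3", "control"))
#' @export
set_schedule <- function(channels, interval_s = 1800) {
  if (!is.character(channels) || length(channels) != 4L ||
      anyDuplicated(channels)) {
    abort("`channels` must be four distinct channel ids (reference last)")
  }
  assert_number(interval_s, "interval_s", 0, strict = TRUE)
  structure(
    list(channels = channels,
         reference_channel = channels[[length(channels)]],
         interval_s = interval_s,
         set_duration_s = interval_s * length(channels)),
    class = "set_schedule"
  )
}

#' Group raw scans into scheduled 30-min intervals
#'
#' Scans are assigned to intervals by timestamp window (tolerating cadence
#' jitter around the nominal one-scan-per-2-s rate), then checked against the
#' channel the schedule places in that window. Each interval is labelled with
#' its set index and its position within the set. Two 21-scan bursts (at
#' minute 0 and minute 15) give the nominal 42 scans per interval.
#'
#' @param scans Tibble with columns `time_s`, `channel`, `analyte`,
#'   `concentration_uM`, `censored` (0/1 or logical), one row per scan per
#'   analyte, sorted by time.
#' @param schedule A [set_schedule()].
#' @param min_scans Minimum scan count (distinct scan times) per interval
#'   below which the interval is flagged incomplete with a warning. The
#'   default 22 leaves at least 12 scans after the transitory-scan discard.
#' @return Tibble with one row per interval: `channel`, `set_index`,
#'   `position_in_set`, `interval_index`, `start_s`, `duration_s`, `n_scans`,
#'   `incomplete`, and a `scans` list-column of per-interval scan tibbles.
#' @export
assemble_intervals <- function(scans, schedule, min_scans = 22) {
  validate_scans(scans)
  if (!inherits(schedule, "set_schedule")) abort("`schedule` must be a set_schedule")
  if (nrow(scans) == 0L) {
    return(tibble::tibble(
      channel = character(), set_index = integer(),
      position_in_set = integer(), interval_index = integer(),
      start_s = double(), duration_s = double(), n_scans = integer(),
      incomplete = logical(), scans = list()
    ))
  }
  if (is.unsorted(scans$time_s)) abort("`scans` must be sorted by time_s")
  unknown <- setdiff(unique(scans$channel), schedule$channels)
  if (length(unknown) > 0L) {
    abort(sprintf("channels not in schedule: %s",
                  paste(unknown, collapse = ", ")))
  }

  k <- length(schedule$channels)
  idx <- as.integer(floor(scans$time_s / schedule$interval_s))
  expected <- schedule$channels[(idx %% k) + 1L]
  bad <- which(scans$channel != expected)
  if (length(bad) > 0L) {
    b <- bad[[1L]]
    abort(sprintf(
      paste0("scan at %g s is channel '%s' but schedule expects '%s' in ",
             "window [%g, %g) s"),
      scans$time_s[b], scans$channel[b], expected[b],
      idx[b] * schedule$interval_s, (idx[b] + 1) * schedule$interval_s))
  }

  scans$..interval <- idx
  nested <- dplyr::group_by(scans, .data$..interval) |>
    tidyr::nest(.key = "scans") |>
    dplyr::ungroup()
  out <- tibble::tibble(
    interval_index = nested$..interval,
    channel = vapply(nested$scans, function(s) s$channel[[1L]], character(1)),
    set_index = nested$..interval %/% k + 1L,
    position_in_set = nested$..interval %% k + 1L,
    start_s = nested$..interval * schedule$interval_s,
    duration_s = schedule$interval_s,
    n_scans = vapply(nested$scans,
                     function(s) length(unique(s$time_s)), integer(1)),
    scans = nested$scans
  )
  out$incomplete <- out$n_scans < min_scans
  if (any(out$incomplete)) {
    warn(sprintf("%d interval(s) have fewer than %d scans; flagged incomplete",
                 sum(out$incomplete), min_scans))
  }
  out[order(out$interval_index),
      c("channel", "set_index", "position_in_set", "interval_index",
        "start_s", "duration_s", "n_scans", "incomplete", "scans")]
}

censor_substitution <- function(substitution, limit) {
  if (is.numeric(substitution)) return(substitution)
  switch(match.arg(substitution, c("zero", "half-limit", "limit")),
         "zero" = 0, "half-limit" = limit / 2, "limit" = limit)
}

#' Interval concentration of one analyte
#'
#' Collapses the scans of one interval for one analyte into the single
#' "interval concentration": the first `discard_n` scans are removed as
#' transitory carry-over from the previous channel, and the remainder are
#' averaged. Scans below the detection limit enter the mean as a substitution
#' value (0 by default, configurable to half the limit or the limit). The
#' interval is itself flagged below detection (`is_bdl`) when the resulting
#' mean falls under the analyte's limit.
#'
#' @param interval One row of [assemble_intervals()] output, or a plain scan
#'   tibble with columns `time_s`, `analyte`, `concentration_uM`, `censored`.
#' @param analyte One of `r paste(VENT_ANALYTES, collapse = ", ")`.
#' @param limits A [detection_limits()] vector.
#' @param discard_n Number of leading transitory scans removed (default 10).
#' @param substitution `"zero"` (default), `"half-limit"`, `"limit"`, or a
#'   number: the value a censored scan contributes to the mean.
#' @return One-row tibble: `channel`, `analyte`, `set_index`,
#'   `interval_index`, `start_s`, `mean_uM`, `is_bdl`, `n_used`,
#'   `n_discarded`, `frac_censored`.
#' @export
interval_concentration <- function(interval, analyte, limits = detection_limits(),
                                   discard_n = 10, substitution = "zero") {
  match_analyte(analyte)
  if (is.data.frame(interval) && "scans" %in% names(interval) &&
      is.list(interval$scans)) {
    meta <- interval[1L, ]
    s <- meta$scans[[1L]]
  } else {
    meta <- NULL
    s <- interval
  }
  s <- s[s$analyte == analyte, , drop = FALSE]
  if (nrow(s) == 0L) abort(sprintf("analyte '%s' absent from interval", analyte))
  if (nrow(s) < discard_n + 1L) {
    abort(sprintf("interval has %d '%s' scans; need at least discard_n + 1 = %d",
                  nrow(s), analyte, discard_n + 1L))
  }
  s <- s[order(s$time_s), , drop = FALSE]
  used <- s[seq.int(discard_n + 1L, nrow(s)), , drop = FALSE]
  limit <- unname(limits[[analyte]])
  sub <- censor_substitution(substitution, limit)
  cens <- as.logical(used$censored)
  vals <- ifelse(cens, sub, used$concentration_uM)
  m <- mean(vals)
  tibble::tibble(
    channel = if (!is.null(meta)) meta$channel
              else if ("channel" %in% names(s)) s$channel[[1L]]
              else NA_character_,
    analyte = analyte,
    set_index = if (!is.null(meta)) meta$set_index else NA_integer_,
    interval_index = if (!is.null(meta)) meta$interval_index else NA_integer_,
    start_s = if (!is.null(meta)) meta$start_s else min(s$time_s),
    mean_uM = m,
    is_bdl = m < limit,
    n_used = nrow(used),
    n_discarded = as.integer(discard_n),
    frac_censored = mean(cens)
  )
}

#' Interval concentrations for every interval and analyte
#'
#' Maps [interval_concentration()] over the full interval table, one row per
#' interval per analyte present.
#'
#' @inheritParams interval_concentration
#' @param intervals Output of [assemble_intervals()].
#' @return Tidy tibble with the [interval_concentration()] columns.
#' @export
interval_concentrations <- function(intervals, limits = detection_limits(),
                                    discard_n = 10, substitution = "zero") {
  rows <- lapply(seq_len(nrow(intervals)), function(i) {
    row <- intervals[i, ]
    present <- intersect(VENT_ANALYTES, unique(row$scans[[1L]]$analyte))
    dplyr::bind_rows(lapply(present, function(a) {
      interval_concentration(row, a, limits, discard_n, substitution)
    }))
  })
  dplyr::bind_rows(rows)
}

#' Percentage of scans discarded as transitory
#'
#' @param total_scans Scans per interval (> 0).
#' @param discard_n Leading scans removed, 0..total_scans.
#' @return Integer percent, rounded half-up (10 of 42 -> 24).
#' @examples
#' discard_fraction(42, 10) # 24
#' @export
discard_fraction <- function(total_scans, discard_n) {
  assert_number(total_scans, "total_scans", 0, strict = TRUE)
  assert_number(discard_n, "discard_n", 0)
  if (discard_n > total_scans) abort("discard_n cannot exceed total_scans")
  as.integer(round_half_up(100 * discard_n / total_scans))
}

validate_scans <- function(scans) {
  need <- c("time_s", "channel", "analyte", "concentration_uM", "censored")
  missing <- setdiff(need, names(scans))
  if (length(missing) > 0L) {
    abort(sprintf("scan table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  bad_analyte <- which(!scans$analyte %in% VENT_ANALYTES)
  bad_time <- which(!is.finite(scans$time_s) | scans$time_s < 0)
  bad_conc <- which(!as.logical(scans$censored) &
                      (!is.finite(scans$concentration_uM) |
                         scans$concentration_uM < 0))
  problems <- c(
    if (length(bad_analyte)) sprintf("unknown analyte at row(s) %s",
                                     paste(head(bad_analyte, 5), collapse = ", ")),
    if (length(bad_time)) sprintf("invalid time_s at row(s) %s",
                                  paste(head(bad_time, 5), collapse = ", ")),
    if (length(bad_conc)) sprintf("negative/non-finite uncensored concentration at row(s) %s",
                                  paste(head(bad_conc, 5), collapse = ", "))
  )
  if (length(problems) > 0L) {
    abort(paste0("invalid scan table:\n  ", paste(problems, collapse = "\n  ")))
  }
  invisible(scans)
}
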