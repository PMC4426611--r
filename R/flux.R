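#' Describe one flow-through aquarium
#'
#' @param id Channel/aquarium identifier (matches the scan `channel`).
#' @param role `"experimental"`, `"control"` (empty aquarium run alongside),
#'   or `"input"` (input-water line, no volume of its own).
#' @param flow_L_per_h Fluid flow through the aquarium, litres per hour.
#' @param volume_L Aquarium volume, litres; one turnover = volume/flow hours.
#' @param total_gill_wet_g Total wet gill mass of the occupants, grams
#'   (0 for control/input).
#' @param genus Host genus occupying the aquarium (NA for control/input).
#' @return One-row tibble.
#' @export
aquarium_config <- function(id, role = c("experimental", "control", "input"),
                            flow_L_per_h, volume_L,
                            total_gill_wet_g = 0, genus = NA_character_) {
  role <- match.arg(role)
  assert_number(flow_L_per_h, "flow_L_per_h", 0, strict = TRUE)
  assert_number(volume_L, "volume_L", 0, strict = TRUE)
  assert_number(total_gill_wet_g, "total_gill_wet_g", 0)
  if (role != "experimental" && total_gill_wet_g != 0) {
    abort("control/input channels must have total_gill_wet_g = 0")
  }
  tibble::tibble(id = id, role = role, flow_L_per_h = flow_L_per_h,
                 volume_L = volume_L, total_gill_wet_g = total_gill_wet_g,
                 genus = genus)
}

#' Temporal gating policy for rate calculations
#'
#' Rates are computed only from data collected once the aquarium has
#' approached steady state: at least `min_elapsed_h` hours into the
#' experiment and after at least `min_turnovers` full exchanges of the
#' aquarium volume, whichever is later.
#'
#' @param min_elapsed_h Minimum elapsed time, hours (default 10).
#' @param min_turnovers Minimum volume turnovers (default 3).
#' @return A list of class `gating_policy`.
#' @export
gating_policy <- function(min_elapsed_h = 10, min_turnovers = 3) {
  assert_number(min_elapsed_h, "min_elapsed_h", 0)
  assert_number(min_turnovers, "min_turnovers", 0)
  structure(list(min_elapsed_h = min_elapsed_h, min_turnovers = min_turnovers),
            class = "gating_policy")
}

#' Gating cutoff in hours for one aquarium
#'
#' @param aquarium One-row [aquarium_config()] tibble.
#' @param policy A [gating_policy()].
#' @return Cutoff in hours: `max(min_elapsed_h, min_turnovers * volume/flow)`.
#' @examples
#' gating_cutoff_h(aquarium_config("a", "experimental", 1, 8, 10), gating_policy())
#' @export
gating_cutoff_h <- function(aquarium, policy = gating_policy()) {
  max(policy$min_elapsed_h,
      policy$min_turnovers * aquarium$volume_L / aquarium$flow_L_per_h)
}

#' Filter interval concentrations by the gating policy
#'
#' @param conc Interval-concentration tibble ([interval_concentrations()]).
#' @param aquarium One-row [aquarium_config()] tibble (supplies volume/flow).
#' @param policy A [gating_policy()].
#' @return List with `intervals` (the retained rows, `start_s >= cutoff`) and
#'   `cutoff_h` (the applied cutoff in hours). Warns when nothing survives.
#' @export
gate_sets <- function(conc, aquarium, policy = gating_policy()) {
  cutoff_h <- gating_cutoff_h(aquarium, policy)
  kept <- conc[conc$start_s >= cutoff_h * 3600, , drop = FALSE]
  if (nrow(kept) == 0L && nrow(conc) > 0L) {
    warn(sprintf("no intervals at or after the %.3g h gating cutoff", cutoff_h))
  }
  list(intervals = kept, cutoff_h = cutoff_h)
}

#' Net mass-specific rate from one experimental/reference interval pair
#'
#' The control-differenced mass balance: the reference interval concentration
#' is subtracted from the experimental one, multiplied by the flow and divided
#' by the total wet gill mass in the aquarium. Units resolve as
#' uM * L/h / g = umol per gram wet gill per hour. Negative rates are net
#' uptake (oxidation); positive rates are net excretion.
#'
#' Below-detection interval concentrations enter as `bdl_value` (0 by
#' default); the resulting rate is flagged `"bdl"` when one side is censored
#' and `"bdl_pair"` when both are (such pairs are excluded by
#' [summarize_rates()]).
#'
#' @param exp,ref One-row interval-concentration tibbles sharing analyte and
#'   set; `ref` is the control-effluent or input-water interval of the same set.
#' @param aquarium One-row [aquarium_config()] for the experimental channel;
#'   must have `total_gill_wet_g > 0`.
#' @param bdl_value Value a below-detection interval contributes (default 0).
#' @return One-row tibble: `genus`, `analyte`, `set_index`, `rate_umol_g_h`,
#'   `reference_channel`, `flag`.
#' @export
net_rate <- function(exp, ref, aquarium, bdl_value = 0) {
  if (!identical(exp$analyte, ref$analyte)) {
    abort("experimental and reference intervals measure different analytes")
  }
  if (!is.na(exp$set_index) && !is.na(ref$set_index) &&
      exp$set_index != ref$set_index) {
    abort("experimental and reference intervals belong to different sets")
  }
  if (aquarium$total_gill_wet_g <= 0) {
    abort("total_gill_wet_g must be > 0 to normalize a rate")
  }
  e <- if (isTRUE(exp$is_bdl)) bdl_value else exp$mean_uM
  r <- if (isTRUE(ref$is_bdl)) bdl_value else ref$mean_uM
  flag <- if (isTRUE(exp$is_bdl) && isTRUE(ref$is_bdl)) "bdl_pair"
          else if (isTRUE(exp$is_bdl) || isTRUE(ref$is_bdl)) "bdl"
          else "ok"
  tibble::tibble(
    genus = aquarium$genus,
    analyte = exp$analyte,
    set_index = exp$set_index,
    rate_umol_g_h = (e - r) * aquarium$flow_L_per_h / aquarium$total_gill_wet_g,
    reference_channel = ref$channel,
    flag = flag
  )
}

#' Per-set rates for every experimental channel and analyte
#'
#' Pairs each experimental interval with the single reference interval of its
#' own 2-h set and applies [net_rate()].
#'
#' @param conc Gated interval-concentration tibble covering experimental and
#'   reference channels.
#' @param aquaria Tibble of [aquarium_config()] rows, one per channel.
#' @param reference_channel Channel id used as reference (control effluent in
#'   rate experiments, input water in variation experiments).
#' @inheritParams net_rate
#' @return Tibble of per-set [net_rate()] rows.
#' @export
set_rates <- function(conc, aquaria, reference_channel, bdl_value = 0) {
  refs <- conc[conc$channel == reference_channel, , drop = FALSE]
  if (nrow(refs) == 0L) {
    abort(sprintf("reference channel '%s' absent from interval concentrations",
                  reference_channel))
  }
  exps <- conc[conc$channel != reference_channel, , drop = FALSE]
  rows <- lapply(seq_len(nrow(exps)), function(i) {
    e <- exps[i, ]
    r <- refs[refs$set_index == e$set_index & refs$analyte == e$analyte, ]
    if (nrow(r) == 0L) return(NULL) # set lacks its reference interval
    aq <- aquaria[aquaria$id == e$channel, ]
    if (nrow(aq) == 0L) abort(sprintf("no aquarium config for channel '%s'", e$channel))
    net_rate(e, r[1L, ], aq[1L, ], bdl_value = bdl_value)
  })
  dplyr::bind_rows(rows)
}

#' Summarize per-set rates by genus and analyte
#'
#' Arithmetic mean and sample standard deviation over set-level rates, the
#' shape in which flow-through rate tables are reported. Pairs flagged
#' `bdl_pair` (both sides censored) are excluded. A single retained set gives
#' sd 0 with `single_set = TRUE`.
#'
#' @param rates Tibble from [set_rates()] (or [net_rate()] rows).
#' @return Tibble: `genus`, `analyte`, `mean_rate`, `sd_rate`, `min_rate`,
#'   `max_rate`, `n_sets`, `single_set`, `direction` (`"uptake"` when the mean
#'   is negative, `"excretion"` when positive, `"none"` at 0).
#' @export
summarize_rates <- function(rates) {
  keep <- rates[rates$flag != "bdl_pair", , drop = FALSE]
  if (nrow(keep) == 0L) abort("no usable rates (all pairs below detection?)")
  out <- keep |>
    dplyr::group_by(.data$genus, .data$analyte) |>
    dplyr::summarise(
      mean_rate = mean(.data$rate_umol_g_h),
      sd_rate = if (dplyr::n() > 1L) sd(.data$rate_umol_g_h) else 0,
      min_rate = min(.data$rate_umol_g_h),
      max_rate = max(.data$rate_umol_g_h),
      n_sets = dplyr::n(),
      .groups = "drop"
    )
  out$single_set <- out$n_sets == 1L
  out$direction <- ifelse(out$mean_rate < 0, "uptake",
                          ifelse(out$mean_rate > 0, "excretion", "none"))
  out
}

#' Detect sustained excretion of a sulfur compound
#'
#' A compound absent (below detection) from the reference channel but present
#' above detection in an experimental effluent across at least
#' `min_consecutive` consecutive gated sets is reported as sustained
#' excretion — the signature distinguishing genuine release from a stray
#' interval.
#'
#' @param conc Gated interval-concentration tibble.
#' @param reference_channel Reference channel id.
#' @param min_consecutive Consecutive sets required (default 2).
#' @return Tibble: `channel`, `analyte`, `n_consecutive` (longest qualifying
#'   run), `sustained`.
#' @export
sustained_excretion <- function(conc, reference_channel, min_consecutive = 2) {
  refs <- conc[conc$channel == reference_channel, c("set_index", "analyte", "is_bdl")]
  names(refs)[names(refs) == "is_bdl"] <- "ref_bdl"
  exps <- conc[conc$channel != reference_channel, , drop = FALSE]
  joined <- dplyr::left_join(exps, refs, by = c("set_index", "analyte"))
  joined$hit <- !joined$is_bdl & !is.na(joined$ref_bdl) & joined$ref_bdl
  longest_run <- function(x) {
    if (!any(x)) return(0L)
    r <- rle(x)
    max(r$lengths[r$values])
  }
  joined |>
    dplyr::arrange(.data$set_index) |>
    dplyr::group_by(.data$channel, .data$analyte) |>
    dplyr::summarise(n_consecutive = longest_run(.data$hit), .groups = "drop") |>
    dplyr::mutate(sustained = .data$n_consecutive >= min_consecutive)
}
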