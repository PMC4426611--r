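#' Configure a pipeline run
#'
#' Bundles everything [run_pipeline()] needs beyond the three input tables:
#' the per-aquarium flow/volume configuration, the channel cycle, detection
#' limits, gating policy, censoring substitution and stoichiometric
#' constants.
#'
#' @param aquaria Tibble of [aquarium_config()] rows (gill totals may be 0;
#'   they are recomputed from the animal table).
#' @param channels Channel cycle, reference last; defaults to the aquaria ids
#'   ordered experimental-first.
#' @param substrate The analyte supplied as energy source (`NULL` for a
#'   sulfur-free run; disables attribution/excretion reporting).
#' @param limits A [detection_limits()] vector.
#' @param policy A [gating_policy()].
#' @param substitution Censored-scan substitution ([interval_concentration()]).
#' @param bdl_value Value a below-detection interval contributes to rates and
#'   concentration summaries (default 0).
#' @param stoich A [stoich_params()] list.
#' @param top_k Individuals credited by [attribution_fraction()] (default 2).
#' @param discard_n Transitory scans discarded per interval (default 10).
#' @param min_scans Minimum scans per interval ([assemble_intervals()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(aquaria, channels = NULL, substrate = NULL,
                            limits = detection_limits(),
                            policy = gating_policy(),
                            substitution = "zero", bdl_value = 0,
                            stoich = stoich_params(), top_k = 2,
                            discard_n = 10, min_scans = 22) {
  if (is.null(channels)) {
    channels <- c(aquaria$id[aquaria$role == "experimental"],
                  aquaria$id[aquaria$role != "experimental"])
  }
  if (!all(channels %in% aquaria$id)) {
    abort("every scheduled channel needs an aquarium config row")
  }
  reference <- channels[[length(channels)]]
  if (aquaria$role[aquaria$id == reference] == "experimental") {
    abort("the last (reference) channel must be a control or input line")
  }
  structure(
    list(aquaria = aquaria, channels = channels,
         reference_channel = reference, substrate = substrate,
         limits = limits, policy = policy, substitution = substitution,
         bdl_value = bdl_value, stoich = stoich, top_k = top_k,
         discard_n = discard_n, min_scans = min_scans),
    class = "pipeline_config"
  )
}

#' Pipeline configuration matching a simulated scenario
#'
#' @param sim A [simulate_experiment()] result (or its `scenario_config`).
#' @return A [pipeline_config()] whose aquaria, channel cycle, reference,
#'   substrate, limits and stoichiometry mirror the generator's.
#' @export
scenario_pipeline_config <- function(sim) {
  cfg <- if (inherits(sim, "vent_simulation")) sim$config else sim
  stopifnot(inherits(cfg, "scenario_config"))
  gp <- .genus_params()
  gp <- gp[gp$genus %in% names(cfg$n_animals_per_genus), ]
  exp_rows <- dplyr::bind_rows(lapply(seq_len(nrow(gp)), function(i) {
    aquarium_config(gp$aquarium[[i]], "experimental", cfg$flow_L_per_h,
                    cfg$volume_L, 0, genus = gp$genus[[i]])
  }))
  ref_role <- if (cfg$reference_channel == "control") "control" else "input"
  ref_row <- aquarium_config(cfg$reference_channel, ref_role,
                             cfg$flow_L_per_h, cfg$volume_L, 0)
  pipeline_config(
    aquaria = dplyr::bind_rows(exp_rows, ref_row),
    channels = c(exp_rows$id, cfg$reference_channel),
    substrate = if (cfg$substrate %in% VENT_ANALYTES) cfg$substrate else NULL,
    limits = cfg$limits, stoich = cfg$stoich
  )
}

#' Summarize gated interval concentrations per channel and analyte
#'
#' The "average (min, max)" concentration block: below-detection intervals
#' enter the average as `bdl_value`; `any_bdl`/`all_bdl` drive the BDL
#' rendering in reports.
#'
#' @param conc Gated interval-concentration tibble.
#' @param bdl_value Substitute for below-detection interval means.
#' @return Tibble: `channel`, `analyte`, `mean_uM`, `min_uM`, `max_uM`,
#'   `n_intervals`, `any_bdl`, `all_bdl`.
#' @export
summarize_concentrations <- function(conc, bdl_value = 0) {
  conc |>
    dplyr::mutate(val = ifelse(.data$is_bdl, bdl_value, .data$mean_uM)) |>
    dplyr::group_by(.data$channel, .data$analyte) |>
    dplyr::summarise(
      mean_uM = mean(.data$val),
      min_uM = min(.data$val),
      max_uM = max(.data$val),
      n_intervals = dplyr::n(),
      any_bdl = any(.data$is_bdl),
      all_bdl = all(.data$is_bdl),
      .groups = "drop"
    )
}

fmt_num <- function(x) formatC(signif(x, 3), format = "g")

fmt_conc_cell <- function(mean_uM, min_uM, max_uM, any_bdl, all_bdl) {
  ifelse(all_bdl, "BDL",
         sprintf("%s (%s, %s)", fmt_num(mean_uM),
                 ifelse(any_bdl, "BDL", fmt_num(min_uM)), fmt_num(max_uM)))
}

fmt_rate_cell <- function(mean_rate, sd_rate, all_bdl) {
  ifelse(all_bdl, "BDL",
         sprintf("%+.3g ± %.2g", mean_rate, sd_rate))
}

#' Run the full analysis pipeline on a scenario directory
#'
#' Reads `scans.csv`, `animals.csv` and `tissue.csv` from `data_dir` (the
#' layout written by [write_scenario()]), validates them, and runs the whole
#' chain: interval assembly, interval concentrations with censoring,
#' temporal gating, control-differenced mass-specific rates, rate and
#' concentration summaries, per-animal carbon-fixation rates, sulfur
#' attribution to the most productive individuals, and excretion fractions.
#' Missing gill masses are filled from the per-genus allometric line.
#'
#' All randomness-free: identical inputs give byte-identical outputs (floats
#' are serialized at 6 significant digits).
#'
#' @param data_dir Directory containing the three input CSVs.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every result table plus a
#'   run manifest (`manifest.json`) and a plain-text report are written.
#' @return List of class `vent_run`: `intervals`, `concentrations`
#'   (gated), `rates`, `rate_summary`, `conc_summary`, `c_inc`,
#'   `attribution`, `excretion`, `sustained`, `animals`, `manifest`.
#' @export
run_pipeline <- function(data_dir, config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  paths <- file.path(data_dir, c("scans.csv", "animals.csv", "tissue.csv"))
  names(paths) <- basename(paths)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    abort(sprintf("missing input file(s): %s",
                  paste(missing, collapse = ", ")))
  }
  scans <- read_csv_quiet(paths[["scans.csv"]])
  animals <- read_csv_quiet(paths[["animals.csv"]])
  tissue <- read_csv_quiet(paths[["tissue.csv"]])
  validate_scans(scans)
  validate_animals(animals)

  warnings_seen <- character()
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  # gill masses: measured where present, allometric prediction otherwise
  animals <- collect(fill_gill_mass(animals))
  totals <- animals |>
    dplyr::group_by(.data$aquarium) |>
    dplyr::summarise(total_gill_wet_g = sum(.data$gill_wet_g),
                     n = dplyr::n(), .groups = "drop")
  aquaria <- config$aquaria
  aquaria$total_gill_wet_g <- NULL
  aquaria <- dplyr::left_join(aquaria, totals, by = c(id = "aquarium"))
  aquaria$total_gill_wet_g <- ifelse(is.na(aquaria$total_gill_wet_g), 0,
                                     aquaria$total_gill_wet_g)
  aquaria$n <- ifelse(is.na(aquaria$n), 0L, aquaria$n)

  schedule <- set_schedule(config$channels)
  intervals <- collect(assemble_intervals(scans, schedule, config$min_scans))
  conc <- interval_concentrations(intervals, config$limits,
                                  config$discard_n, config$substitution)

  # gate each experimental channel by its own aquarium's cutoff; the
  # reference channel rides along for set pairing and is summarized at the
  # largest experimental cutoff
  exp_ids <- aquaria$id[aquaria$role == "experimental"]
  cutoffs <- setNames(vapply(exp_ids, function(id) {
    gating_cutoff_h(aquaria[aquaria$id == id, ], config$policy)
  }, numeric(1)), exp_ids)
  gated_exp <- dplyr::bind_rows(lapply(exp_ids, function(id) {
    collect(gate_sets(conc[conc$channel == id, ],
                      aquaria[aquaria$id == id, ], config$policy))$intervals
  }))
  refs <- conc[conc$channel == config$reference_channel, ]
  gated <- dplyr::bind_rows(
    gated_exp, refs[refs$start_s >= max(cutoffs) * 3600, ])

  rates <- set_rates(dplyr::bind_rows(gated_exp, refs), aquaria,
                     config$reference_channel, config$bdl_value)
  rate_summary <- if (any(rates$flag != "bdl_pair")) {
    summarize_rates(rates)
  } else {
    # e.g. a sulfur-free run: every pair below detection, nothing to average
    tibble::tibble(genus = character(), analyte = character(),
                   mean_rate = double(), sd_rate = double(),
                   min_rate = double(), max_rate = double(),
                   n_sets = integer(), single_set = logical(),
                   direction = character())
  }
  conc_summary <- summarize_concentrations(gated, config$bdl_value)
  sustained <- sustained_excretion(gated, config$reference_channel)

  c_inc <- collect(c_inc_pipeline(tissue))
  c_inc <- dplyr::left_join(
    c_inc,
    animals[, c("animal_id", "genus", "aquarium", "position", "gill_wet_g")],
    by = "animal_id")

  attribution <- excretion <- NULL
  if (!is.null(config$substrate)) {
    uptake <- rate_summary[rate_summary$analyte == config$substrate &
                             rate_summary$mean_rate < 0, ]
    attribution <- dplyr::bind_rows(lapply(seq_len(nrow(uptake)), function(i) {
      u <- uptake[i, ]
      ind <- c_inc[c_inc$genus == u$genus, ]
      aq <- aquaria[!is.na(aquaria$genus) & aquaria$genus == u$genus, ]
      if (nrow(ind) == 0L || nrow(aq) == 0L) return(NULL)
      k <- min(config$top_k, nrow(ind))
      cbind(tibble::tibble(aquarium = aq$id, genus = u$genus),
            attribution_fraction(ind$wet_rate, ind$gill_wet_g,
                                 config$substrate, u$mean_rate,
                                 aq$total_gill_wet_g, top_k = k,
                                 params = config$stoich))
    }))
    excretion <- dplyr::bind_rows(lapply(unique(rate_summary$genus), function(g) {
      rs <- rate_summary[rate_summary$genus == g, ]
      upt <- rs[rs$analyte == config$substrate & rs$mean_rate < 0, ]
      exc <- rs[rs$mean_rate > 0, ]
      if (nrow(upt) == 0L || nrow(exc) == 0L) return(NULL)
      dplyr::bind_rows(lapply(seq_len(nrow(exc)), function(j) {
        cbind(tibble::tibble(genus = g),
              excretion_fraction(exc$mean_rate[[j]], upt$mean_rate[[1L]],
                                 exc$analyte[[j]], config$substrate,
                                 params = config$stoich,
                                 excretion_sd = exc$sd_rate[[j]],
                                 uptake_sd = upt$sd_rate[[1L]]))
      }))
    }))
  }

  seed <- scan_header_seed(paths[["scans.csv"]])
  manifest <- list(
    package_version = as.character(utils::packageVersion("ventflux")),
    seed = seed,
    input_md5 = as.list(tools::md5sum(unname(paths))),
    gating_cutoff_h = as.list(cutoffs),
    reference_channel = config$reference_channel,
    substrate = config$substrate,
    warnings = warnings_seen
  )

  run <- structure(
    list(intervals = intervals[, setdiff(names(intervals), "scans")],
         concentrations = gated, rates = rates, rate_summary = rate_summary,
         conc_summary = conc_summary, c_inc = c_inc,
         attribution = attribution, excretion = excretion,
         sustained = sustained, animals = animals, aquaria = aquaria,
         manifest = manifest),
    class = "vent_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

scan_header_seed <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^# seed=", first)) as.integer(sub("^# seed=", "", first))
  else NA_integer_
}

#' Write every pipeline result table, the manifest and a text report
#'
#' @param run A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  stopifnot(inherits(run, "vent_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("intervals", "concentrations", "rates", "rate_summary",
            "conc_summary", "c_inc", "attribution", "excretion",
            "sustained", "animals")
  for (nm in tabs) {
    df <- run[[nm]]
    if (!is.null(df) && nrow(df) > 0L) {
      write_csv_seeded(df, file.path(out_dir, paste0(nm, ".csv")),
                       run$manifest$seed)
    }
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report_text(run), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Plain-text summary report
#'
#' Renders the concentration block (average (min, max) per channel and
#' analyte, `BDL` where below detection) and the signed rate block
#' (mean +/- sd, negative = uptake, positive = excretion), followed by
#' attribution and excretion-fraction lines when available.
#'
#' @param run A [run_pipeline()] result.
#' @return Character vector of report lines.
#' @export
report_text <- function(run) {
  lines <- c("ventflux run report", "===================", "")
  aq <- run$aquaria
  cs <- run$conc_summary
  lines <- c(lines, "Effluent concentrations (uM), average (min, max):")
  for (ch in unique(cs$channel)) {
    row <- aq[aq$id == ch, ]
    label <- if (nrow(row) && !is.na(row$genus)) {
      sprintf("%s [%s, n=%d, gill %.4g g]", ch, row$genus, row$n,
              row$total_gill_wet_g)
    } else ch
    cells <- vapply(VENT_ANALYTES, function(a) {
      d <- cs[cs$channel == ch & cs$analyte == a, ]
      if (nrow(d) == 0L) "n.a."
      else fmt_conc_cell(d$mean_uM, d$min_uM, d$max_uM, d$any_bdl, d$all_bdl)
    }, character(1))
    lines <- c(lines, sprintf("  %-40s %s", label,
                              paste(sprintf("%s: %s", VENT_ANALYTES, cells),
                                    collapse = "  ")))
  }
  rs <- run$rate_summary
  lines <- c(lines, "",
             "Net rates (umol per g wet gill per h; - uptake, + excretion):")
  for (i in seq_len(nrow(rs))) {
    r <- rs[i, ]
    lines <- c(lines, sprintf("  %-15s %-12s %s (n_sets=%d)", r$genus,
                              r$analyte,
                              fmt_rate_cell(r$mean_rate, r$sd_rate, FALSE),
                              r$n_sets))
  }
  if (!is.null(run$attribution) && nrow(run$attribution) > 0L) {
    lines <- c(lines, "", "Oxidation attributable to most productive individuals:")
    for (i in seq_len(nrow(run$attribution))) {
      a <- run$attribution[i, ]
      lines <- c(lines, sprintf("  %-15s top %d individuals: %.3g%%%s",
                                a$genus, a$top_k, a$percent,
                                if (a$capped) " (capped)" else ""))
    }
  }
  if (!is.null(run$excretion) && nrow(run$excretion) > 0L) {
    lines <- c(lines, "", "Excretion as % of uptake (sulfur-atom basis):")
    for (i in seq_len(nrow(run$excretion))) {
      e <- run$excretion[i, ]
      lines <- c(lines, sprintf("  %-15s %s from %s: %.3g%% (%.3g-%.3g%%)",
                                e$genus, e$excreted, e$consumed, e$percent,
                                e$percent_lo, e$percent_hi))
    }
  }
  lines
}

validate_animals <- function(animals) {
  need <- c("animal_id", "genus", "aquarium", "position", "body_wet_g",
            "gill_wet_g")
  missing <- setdiff(need, names(animals))
  if (length(missing) > 0L) {
    abort(sprintf("animal table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  bad_mass <- which(!is.finite(animals$body_wet_g) | animals$body_wet_g <= 0)
  if (length(bad_mass) > 0L) {
    abort(sprintf("non-positive body mass at row(s) %s",
                  paste(head(bad_mass, 5), collapse = ", ")))
  }
  invisible(animals)
}
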