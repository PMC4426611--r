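#' Carbon-sulfur stoichiometric parameters
#'
#' Conversion factors between carbon-fixation and sulfur-oxidation
#' currencies. `s_per_c_*` is the number of moles of substrate oxidized per
#' mole of carbon fixed under the assumed 10% efficiency of energy
#' conservation; the efficiency is stored for documentation, the defaults
#' already embed it. `s_atoms` counts sulfur atoms per molecule of each
#' analyte (thiosulfate carries two; the polysulfide chain length is
#' configurable 1-8, with per-molecule accounting at 1 by default).
#'
#' @param s_per_c_sulfide mol sulfide oxidized per mol C fixed (default 6.21).
#' @param s_per_c_thiosulfate mol thiosulfate per mol C fixed (default 6.64).
#' @param efficiency Assumed fraction of conserved energy (informational).
#' @param polysulfide_chain Sulfur atoms per polysulfide molecule, 1-8.
#' @return A list of class `stoich_params` with `s_per_c` and `s_atoms`
#'   named vectors.
#' @export
stoich_params <- function(s_per_c_sulfide = 6.21, s_per_c_thiosulfate = 6.64,
                          efficiency = 0.10, polysulfide_chain = 1) {
  assert_number(s_per_c_sulfide, "s_per_c_sulfide", 0, strict = TRUE)
  assert_number(s_per_c_thiosulfate, "s_per_c_thiosulfate", 0, strict = TRUE)
  if (!polysulfide_chain %in% 1:8) {
    abort("polysulfide_chain must be an integer 1-8")
  }
  structure(
    list(
      s_per_c = c(sulfide = s_per_c_sulfide,
                  thiosulfate = s_per_c_thiosulfate),
      s_atoms = c(sulfide = 1, thiosulfate = 2,
                  polysulfide = polysulfide_chain),
      efficiency = efficiency
    ),
    class = "stoich_params"
  )
}

#' Reference free energies of substrate oxidation
#'
#' Standard Gibbs free energies of the complete aerobic oxidation of sulfide
#' and thiosulfate, kJ per mol substrate. Stored reference constants for
#' reporting; nothing in the package derives them.
#'
#' @format Named numeric vector (negative, i.e. exergonic).
#' @export
THERMO_DG_KJ_PER_MOL <- c(sulfide = -732.6, thiosulfate = -738.7)

#' Predicted sulfur-oxidation rate from a carbon-fixation rate
#'
#' @param c_inc_wet Carbon-fixation rate, umol C per g wet gill per h (>= 0).
#'   Vectorized.
#' @param substrate `"sulfide"` or `"thiosulfate"`.
#' @param params A [stoich_params()] list.
#' @return Predicted substrate oxidation rate, umol substrate per g wet gill
#'   per h: `c_inc_wet * s_per_c[substrate]`.
#' @examples
#' predicted_sulfur_rate(1, "sulfide") # 6.21
#' @export
predicted_sulfur_rate <- function(c_inc_wet, substrate,
                                  params = stoich_params()) {
  if (!substrate %in% names(params$s_per_c)) {
    abort(sprintf("unknown substrate '%s'; use %s", substrate,
                  paste(names(params$s_per_c), collapse = " or ")))
  }
  if (any(c_inc_wet < 0)) abort("c_inc_wet must be >= 0")
  c_inc_wet * unname(params$s_per_c[[substrate]])
}

#' Share of aquarium-level oxidation attributable to the top individuals
#'
#' Converts the `top_k` highest individual carbon-fixation rates into
#' predicted substrate-oxidation fluxes (rate x own gill mass x molar ratio)
#' and expresses their sum as a percentage of the measured aquarium-level
#' oxidation flux (|mass-specific uptake| x total gill mass).
#'
#' @param c_inc_wet Individual carbon-fixation rates, umol C g-1 h-1.
#' @param gill_wet_g Matching individual gill wet masses, grams.
#' @param substrate `"sulfide"` or `"thiosulfate"`.
#' @param aquarium_rate Measured mass-specific aquarium rate, umol g-1 h-1;
#'   must be negative (net uptake).
#' @param total_gill_wet_g Total wet gill mass in the aquarium, grams.
#' @param top_k How many of the most productive individuals to credit.
#' @param params A [stoich_params()] list.
#' @return One-row tibble: `substrate`, `top_k`, `percent`, `capped`
#'   (TRUE when the prediction exceeds the measured total).
#' @export
attribution_fraction <- function(c_inc_wet, gill_wet_g, substrate,
                                 aquarium_rate, total_gill_wet_g,
                                 top_k = 2, params = stoich_params()) {
  if (length(c_inc_wet) != length(gill_wet_g)) {
    abort("c_inc_wet and gill_wet_g must be the same length")
  }
  if (top_k > length(c_inc_wet)) abort("top_k exceeds the number of individuals")
  assert_number(total_gill_wet_g, "total_gill_wet_g", 0, strict = TRUE)
  if (!is.finite(aquarium_rate) || aquarium_rate >= 0) {
    abort("aquarium_rate must be negative (net uptake); nothing to attribute")
  }
  ord <- order(c_inc_wet, decreasing = TRUE)[seq_len(top_k)]
  predicted <- sum(predicted_sulfur_rate(c_inc_wet[ord], substrate, params) *
                     gill_wet_g[ord])
  pct <- 100 * predicted / (abs(aquarium_rate) * total_gill_wet_g)
  tibble::tibble(substrate = substrate, top_k = as.integer(top_k),
                 percent = pct, capped = pct > 100)
}

#' Excretion as a fraction of uptake on a sulfur-atom basis
#'
#' Expresses a positive excretion rate as a percentage of a negative uptake
#' rate, counting sulfur atoms so that compounds with different sulfur
#' content are comparable (a mole of excreted thiosulfate carries two sulfur
#' atoms per mole of consumed sulfide's one).
#'
#' When `excretion_sd`/`uptake_sd` are supplied, a band is propagated by
#' interval arithmetic on the +/- one-sd bounds (smallest and largest
#' quotient), reproducing range-style statements about excretion.
#'
#' @param excretion_rate Mean excretion rate, umol compound g-1 h-1 (>= 0).
#' @param uptake_rate Mean uptake rate, umol compound g-1 h-1 (< 0).
#' @param excreted,consumed Analyte names for the numerator and denominator.
#' @param params A [stoich_params()] list.
#' @param excretion_sd,uptake_sd Optional standard deviations for the band.
#' @return One-row tibble: `excreted`, `consumed`, `percent`, `percent_lo`,
#'   `percent_hi` (bounds NA when no sds given).
#' @examples
#' excretion_fraction(0.92, -6.8, "thiosulfate", "sulfide") # 27.06%
#' @export
excretion_fraction <- function(excretion_rate, uptake_rate, excreted, consumed,
                               params = stoich_params(),
                               excretion_sd = NULL, uptake_sd = NULL) {
  match_analyte(c(excreted, consumed))
  assert_number(excretion_rate, "excretion_rate", 0)
  if (!is.finite(uptake_rate) || uptake_rate >= 0) {
    abort("uptake_rate must be negative (net uptake)")
  }
  atoms_e <- unname(params$s_atoms[[excreted]])
  atoms_c <- unname(params$s_atoms[[consumed]])
  frac <- function(e, u) 100 * e * atoms_e / (abs(u) * atoms_c)
  pct <- frac(excretion_rate, uptake_rate)
  lo <- hi <- NA_real_
  if (!is.null(excretion_sd) || !is.null(uptake_sd)) {
    es <- excretion_sd %||% 0
    us <- uptake_sd %||% 0
    lo <- frac(max(excretion_rate - es, 0), uptake_rate - us) # larger |uptake|
    hi <- frac(excretion_rate + es, min(uptake_rate + us, -.Machine$double.eps))
  }
  tibble::tibble(excreted = excreted, consumed = consumed,
                 percent = pct, percent_lo = lo, percent_hi = hi)
}
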