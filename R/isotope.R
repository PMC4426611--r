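#' Physical constants for the tracer calculation
#'
#' @param MW_13C Molar mass of 13C, g/mol (exact isotope mass 13.00335).
#' @param natural_A_pct Natural-abundance atomic percent 13C (~1.11, from the
#'   VPDB isotope ratio).
#' @param vpdb_ratio VPDB 13C/12C reference ratio used by the delta-notation
#'   converters.
#' @return A list of class `isotope_constants`.
#' @export
isotope_constants <- function(MW_13C = 13.00335, natural_A_pct = 1.11,
                              vpdb_ratio = 0.0111802) {
  assert_number(MW_13C, "MW_13C", 0, strict = TRUE)
  structure(list(MW_13C = MW_13C, natural_A_pct = natural_A_pct,
                 vpdb_ratio = vpdb_ratio),
            class = "isotope_constants")
}

#' Percent of tissue carbon replaced by tracer
#'
#' Three-endmember mixing of atomic percent 13C: the symbiont-containing gill
#' is the labelled pool, the symbiont-free foot of the same individual is the
#' unlabelled baseline (it receives no appreciable translocated carbon on the
#' experiment's timescale), and the labelled input-water DIC is the source.
#'
#' @param A_pct_gill,A_pct_foot,A_pct_water Atomic percent 13C of gill tissue,
#'   foot tissue and input-water DIC. Vectorized.
#' @return Percent 13C incorporated:
#'   `100 * (gill - foot) / (water - foot)`. May be negative on noisy input;
#'   see `clamp` in [c_inc_pipeline()].
#' @examples
#' percent_13c_inc(1.47, 1.08, 5.00) # 9.949
#' @export
percent_13c_inc <- function(A_pct_gill, A_pct_foot, A_pct_water) {
  if (any(abs(A_pct_water - A_pct_foot) < .Machine$double.eps * 100)) {
    abort("A_pct_water equals A_pct_foot: no label contrast")
  }
  100 * (A_pct_gill - A_pct_foot) / (A_pct_water - A_pct_foot)
}

#' Grams of 13C incorporated into a gill sample
#'
#' @param pct_13c_inc Percent 13C incorporated ([percent_13c_inc()]).
#' @param DW_g Gill sample dry weight, grams.
#' @param C_frac Carbon content of the sample as a fraction of dry weight.
#' @return Grams 13C: `(pct/100) * DW_g * C_frac`. Vectorized.
#' @export
weight_13c_inc <- function(pct_13c_inc, DW_g, C_frac) {
  (pct_13c_inc / 100) * DW_g * C_frac
}

#' Dry-mass-specific carbon incorporation rate
#'
#' @param W13C_inc_g Grams 13C incorporated ([weight_13c_inc()]).
#' @param t_h Experiment duration, hours (> 0).
#' @param DW_g Gill sample dry weight, grams (> 0).
#' @param constants An [isotope_constants()] list.
#' @return Micromoles 13C per gram dry gill per hour:
#'   `1e6 * W13C / (MW_13C * t_h * DW_g)`. Vectorized.
#' @export
dry_c_inc <- function(W13C_inc_g, t_h, DW_g, constants = isotope_constants()) {
  if (any(t_h <= 0)) abort("t_h must be > 0")
  if (any(DW_g <= 0)) abort("DW_g must be > 0")
  1e6 * W13C_inc_g / (constants$MW_13C * t_h * DW_g)
}

#' Convert a dry-mass rate to a wet-mass rate
#'
#' @param dry_rate umol 13C per gram dry gill per hour.
#' @param DW_g,W_g Dry and wet weight of the same gill sample, grams.
#' @return umol 13C per gram wet gill per hour: `dry_rate * DW_g / W_g`.
#' @export
wet_c_inc <- function(dry_rate, DW_g, W_g) {
  if (any(W_g <= 0)) abort("W_g must be > 0")
  dry_rate * DW_g / W_g
}

#' Carbon-fixation rates from a tissue isotope table
#'
#' Runs the full tracer chain — mixing fraction, incorporated mass,
#' dry-specific rate, wet-specific rate — for each animal. Individuals whose
#' gill reads at or below the foot baseline (possible under measurement
#' noise) are reported as zero incorporation when `clamp = TRUE` (default),
#' with the `clamped` flag set; `clamp = FALSE` reports raw (possibly
#' negative) rates.
#'
#' @param samples Tibble with columns `animal_id`, `A_pct_gill`, `A_pct_foot`,
#'   `A_pct_water`, `DW_g`, `C_pct`, `W_g`, `t_h`.
#' @param constants An [isotope_constants()] list.
#' @param clamp Clamp negative raw incorporation to zero (default TRUE).
#' @param c_unit How `C_pct` is scaled: `"fraction"` (0-1, default) or
#'   `"percent"` (0-100); normalized internally to a fraction.
#' @return Tibble: `animal_id`, `pct_13C_inc`, `W13C_inc_g`, `dry_rate`,
#'   `wet_rate` (umol 13C per g wet gill per h), `clamped`.
#' @examples
#' s <- tibble::tibble(animal_id = "a1", A_pct_gill = 1.47, A_pct_foot = 1.08,
#'                     A_pct_water = 5, DW_g = 0.3, C_pct = 0.4, W_g = 3, t_h = 24)
#' c_inc_pipeline(s)
#' @export
c_inc_pipeline <- function(samples, constants = isotope_constants(),
                           clamp = TRUE, c_unit = c("fraction", "percent")) {
  c_unit <- match.arg(c_unit)
  need <- c("animal_id", "A_pct_gill", "A_pct_foot", "A_pct_water",
            "DW_g", "C_pct", "W_g", "t_h")
  missing <- setdiff(need, names(samples))
  if (length(missing) > 0L) {
    abort(sprintf("tissue table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  C_frac <- if (c_unit == "percent") samples$C_pct / 100 else samples$C_pct
  if (any(C_frac < 0 | C_frac > 1)) {
    abort("C_pct outside [0, 1] after unit normalization; check `c_unit`")
  }
  if (any(samples$DW_g > samples$W_g)) {
    abort("dry weight exceeds wet weight for at least one sample")
  }
  pct <- percent_13c_inc(samples$A_pct_gill, samples$A_pct_foot,
                         samples$A_pct_water)
  clamped <- clamp & pct < 0
  pct_eff <- if (clamp) pmax(pct, 0) else pct
  w13 <- weight_13c_inc(pct_eff, samples$DW_g, C_frac)
  dry <- dry_c_inc(w13, samples$t_h, samples$DW_g, constants)
  wet <- wet_c_inc(dry, samples$DW_g, samples$W_g)
  tibble::tibble(
    animal_id = samples$animal_id,
    pct_13C_inc = pct_eff,
    W13C_inc_g = w13,
    dry_rate = dry,
    wet_rate = wet,
    clamped = as.logical(clamped)
  )
}

#' Convert between delta-13C (per mil, VPDB) and atomic percent
#'
#' Convenience converters for mass-spectrometry output reported in delta
#' notation; the pipeline's native unit is atomic percent.
#'
#' @param delta delta-13C in per mil vs VPDB.
#' @param A_pct Atomic percent 13C.
#' @param constants An [isotope_constants()] list.
#' @return The converted value(s).
#' @examples
#' atom_pct_to_delta13c(delta13c_to_atom_pct(-25)) # -25
#' @export
delta13c_to_atom_pct <- function(delta, constants = isotope_constants()) {
  r <- constants$vpdb_ratio * (1 + delta / 1000)
  100 * r / (1 + r)
}

#' @rdname delta13c_to_atom_pct
#' @export
atom_pct_to_delta13c <- function(A_pct, constants = isotope_constants()) {
  r <- A_pct / (100 - A_pct)
  1000 * (r / constants$vpdb_ratio - 1)
}
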