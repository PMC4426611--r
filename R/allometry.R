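#' Fit a per-genus body-mass to gill-mass line
#'
#' Ordinary least-squares regression of gill wet mass on body wet mass, used
#' to estimate the gill mass of individuals whose gills were not directly
#' weighed. Linear on the raw scale by default; `log_log = TRUE` fits
#' `log(gill) ~ log(body)` instead (a power law).
#'
#' @param body_wet_g,gill_wet_g Paired training masses, grams; at least two
#'   pairs with distinct body masses.
#' @param genus Genus label carried on the model.
#' @param log_log Fit on log-log scale (default FALSE).
#' @return An object of class `allometry_fit`: list with `genus`, `slope`,
#'   `intercept`, `n`, `r_squared`, `log_log` and the underlying `lm` fit.
#' @examples
#' fit_allometry(c(10, 20, 30), c(2.1, 4.1, 6.1), genus = "Alviniconcha")
#' @export
fit_allometry <- function(body_wet_g, gill_wet_g, genus = NA_character_,
                          log_log = FALSE) {
  ok <- is.finite(body_wet_g) & is.finite(gill_wet_g)
  body <- body_wet_g[ok]
  gill <- gill_wet_g[ok]
  if (length(body) < 2L) abort("need at least two complete mass pairs")
  if (length(unique(body)) < 2L) {
    abort("all body masses identical: regression design is degenerate")
  }
  if (log_log && (any(body <= 0) || any(gill <= 0))) {
    abort("log-log fit requires strictly positive masses")
  }
  df <- if (log_log) data.frame(x = log(body), y = log(gill))
        else data.frame(x = body, y = gill)
  fit <- lm(y ~ x, data = df)
  structure(
    list(genus = genus,
         slope = unname(coef(fit)[2L]),
         intercept = unname(coef(fit)[1L]),
         n = length(body),
         # noiseless calibration sets are legitimate here; silence the
         # "essentially perfect fit" advisory from summary.lm
         r_squared = suppressWarnings(summary(fit)$r.squared),
         log_log = log_log,
         fit = fit),
    class = "allometry_fit"
  )
}

#' @export
print.allometry_fit <- function(x, ...) {
  scale <- if (x$log_log) "log(gill) ~ log(body)" else "gill ~ body"
  cat(sprintf("Allometric fit (%s), genus %s\n", scale, x$genus))
  cat(sprintf("  slope %.4g, intercept %.4g, n = %d, r^2 = %.3f\n",
              x$slope, x$intercept, x$n, x$r_squared))
  invisible(x)
}

#' Predict gill wet mass from body wet mass
#'
#' @param model An [fit_allometry()] object.
#' @param body_wet_g Body wet mass, grams (> 0). Vectorized.
#' @param floor_g Minimum returned mass (default 0); a prediction at or below
#'   the floor is floored with a warning.
#' @return Predicted gill wet mass, grams.
#' @export
predict_gill_mass <- function(model, body_wet_g, floor_g = 0) {
  if (!inherits(model, "allometry_fit")) abort("`model` must be an allometry_fit")
  if (any(body_wet_g <= 0)) abort("body_wet_g must be > 0")
  pred <- if (model$log_log) {
    exp(model$intercept + model$slope * log(body_wet_g))
  } else {
    model$intercept + model$slope * body_wet_g
  }
  low <- pred <= floor_g
  if (any(low)) {
    warn(sprintf("%d prediction(s) at or below %.3g g floored", sum(low), floor_g))
    pred[low] <- floor_g
  }
  pred
}

#' Fill missing gill masses in an animal table
#'
#' Fits one allometric line per genus on the animals with measured gills and
#' predicts the rest. Measured masses always override predictions.
#'
#' @param animals Tibble with columns `genus`, `body_wet_g` and
#'   `gill_wet_g` (NA where unmeasured).
#' @param log_log Passed to [fit_allometry()].
#' @return `animals` with `gill_wet_g_measured`, `gill_wet_g_predicted`,
#'   `gill_wet_g` (measured where available, else predicted) and
#'   `gill_source` (`"measured"`/`"predicted"`) columns.
#' @export
fill_gill_mass <- function(animals, log_log = FALSE) {
  animals$gill_wet_g_measured <- animals$gill_wet_g
  animals$..row <- seq_len(nrow(animals))
  parts <- split(animals, animals$genus)
  parts <- lapply(parts, function(d) {
    measured <- !is.na(d$gill_wet_g_measured)
    d$gill_wet_g_predicted <- NA_real_
    if (any(!measured)) {
      if (sum(measured) < 2L) {
        abort(sprintf(
          "genus %s: %d measured gill(s); need >= 2 to fit the allometric line",
          d$genus[[1L]], sum(measured)))
      }
      m <- fit_allometry(d$body_wet_g[measured], d$gill_wet_g_measured[measured],
                         genus = d$genus[[1L]], log_log = log_log)
      d$gill_wet_g_predicted[!measured] <-
        predict_gill_mass(m, d$body_wet_g[!measured])
    }
    d$gill_wet_g <- ifelse(measured, d$gill_wet_g_measured,
                           d$gill_wet_g_predicted)
    d$gill_source <- ifelse(measured, "measured", "predicted")
    d
  })
  out <- dplyr::bind_rows(parts)
  out <- out[order(out$..row), ]
  out$..row <- NULL
  out
}
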