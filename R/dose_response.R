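#' A dose-response series of influx constants vs competitor concentration
#'
#' Pairs fitted influx rate constants with the concentration of a non-labelled
#' competitor present during each assay. A zero-concentration (uninhibited)
#' point anchors the top of the curve and is recommended.
#'
#' @param competitor_conc competitor concentrations, nM; >= 0.
#' @param I_values fitted influx rate constants, s^-1; same length.
#' @param tracer,competitor labels.
#' @return An object of class `dose_response_series`.
#' @export
dose_response_series <- function(competitor_conc, I_values,
                                 tracer = "tracer", competitor = "competitor") {
  if (length(competitor_conc) != length(I_values))
    validation_error("competitor_conc and I_values must have equal length")
  if (any(!is.finite(competitor_conc)) || any(competitor_conc < 0))
    validation_error("competitor concentrations must be finite and >= 0")
  if (any(!is.finite(I_values)) || any(I_values < 0))
    validation_error("I values must be finite and >= 0")
  structure(list(competitor_conc = as.numeric(competitor_conc),
                 I_values = as.numeric(I_values),
                 tracer = tracer, competitor = competitor),
            class = "dose_response_series")
}

#' Evaluate the saturation model
#'
#' Influx rate constant as a function of competitor concentration,
#' `I(cK) = v_lim / (IC50 + cK) + D`: a saturable component that falls
#' hyperbolically with competitor load plus a residual, non-saturable influx
#' `D`. Strictly decreasing in `cK` whenever `v_lim > 0`.
#'
#' @param cK competitor concentration(s), nM; >= 0.
#' @param params a [saturation_params()] object.
#' @return Influx rate constant(s), s^-1.
#' @examples
#' eval_saturation(100, saturation_params(1, 100, 1e-3))  # 0.006 /s
#' @export
eval_saturation <- function(cK, params) {
  stopifnot(inherits(params, "saturation_params"))
  if (any(!is.finite(cK)) || any(cK < 0))
    validation_error("`cK` must be finite and >= 0")
  if (any(params$IC50 + cK == 0))
    validation_error("IC50 + cK = 0: saturation model undefined")
  params$v_lim / (params$IC50 + cK) + params$D
}

#' Fit the saturation model to a dose-response series
#'
#' Bounded least squares of the saturation model against influx constants at
#' each competitor concentration: lower bounds 0, initial guesses 1 for each
#' of `v_lim`, `IC50`, `D`, tolerances from `control`. When the fitted curve
#' is essentially flat and `IC50` runs away beyond any measured concentration
#' (no dose-dependent inhibition, so the half-saturation point is
#' unconstrained) the result carries `no_saturation = TRUE`.
#'
#' @param series a [dose_response_series()] with >= 4 points.
#' @param control a [solver_control()].
#' @return List of class `saturation_fit`: `params`
#'   ([saturation_params()]), `residual_norm`, `converged`, `no_saturation`,
#'   `tracer`, `competitor`.
#' @export
fit_saturation <- function(series, control = solver_control()) {
  stopifnot(inherits(series, "dose_response_series"))
  if (length(series$competitor_conc) < 4L)
    validation_error("need >= 4 dose-response points to fit 3 parameters")
  cK <- series$competitor_conc
  y <- series$I_values
  resid_fn <- function(p) y - (p[["v_lim"]] / (p[["IC50"]] + cK) + p[["D"]])
  lm <- run_lm(c(v_lim = control$init_sat, IC50 = control$init_sat,
                 D = control$init_sat),
               resid_fn, lower = c(0, 0, 0), control)
  p <- lm$par
  fitted <- p[["v_lim"]] / (p[["IC50"]] + cK) + p[["D"]]
  # diverging IC50 with a near-flat curve = no observable saturation
  flat <- diff(range(fitted)) <= 1e-6 * max(abs(y), 1e-30)
  no_sat <- (p[["IC50"]] > 1e6 * max(cK) && flat) ||
    (p[["v_lim"]] <= control$bound_tol && diff(range(y)) > 0 &&
       stats::cor(cK, y) > 0)
  structure(list(
    params = saturation_params(p[["v_lim"]], p[["IC50"]], p[["D"]]),
    residual_norm = lm$residual_norm, converged = lm$converged,
    no_saturation = isTRUE(no_sat),
    tracer = series$tracer, competitor = series$competitor),
    class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("<saturation_fit> %s vs %s: v_lim = %.4g nM/s, IC50 = %.4g nM, D = %.4g /s%s\n",
              x$tracer, x$competitor, x$params$v_lim, x$params$IC50,
              x$params$D,
              if (x$no_saturation) " [no saturation observed]" else ""))
  invisible(x)
}

#' Fold-change matrix of influx constants under competition
#'
#' Ratio of the median influx constant of each tracer in the presence of a
#' competitor to its uninhibited (tracer-alone) median: values below 1 mean
#' inhibition. Tracer/competitor combinations that were not assayed stay
#' `NA`; a zero control median makes the ratio undefined and is flagged.
#'
#' @param control_medians named numeric vector, tracer -> median I (s^-1)
#'   without competitor.
#' @param treated_medians data.frame with columns `tracer`, `competitor`,
#'   `median_I`.
#' @return Numeric matrix, tracers by competitors, with `NA` for untested
#'   cells; attribute `undefined` lists cells with a zero control.
#' @export
fold_change_matrix <- function(control_medians, treated_medians) {
  stopifnot(is.data.frame(treated_medians),
            all(c("tracer", "competitor", "median_I") %in% names(treated_medians)))
  missing_ctrl <- setdiff(unique(treated_medians$tracer), names(control_medians))
  if (length(missing_ctrl))
    validation_error(paste("no control median for tracer(s):",
                           paste(missing_ctrl, collapse = ", ")))
  tracers <- names(control_medians)
  competitors <- unique(treated_medians$competitor)
  m <- matrix(NA_real_, length(tracers), length(competitors),
              dimnames = list(tracers, competitors))
  undef <- character(0)
  for (i in seq_len(nrow(treated_medians))) {
    tr <- treated_medians$tracer[i]; cp <- treated_medians$competitor[i]
    ctrl <- control_medians[[tr]]
    if (ctrl == 0) {
      undef <- c(undef, paste(tr, cp, sep = " / "))
      next
    }
    m[tr, cp] <- treated_medians$median_I[i] / ctrl
  }
  attr(m, "undefined") <- undef
  m
}
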