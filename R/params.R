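#' Kinetic parameters of the tracer accumulation model
#'
#' Bundle of first-order rate constants describing tracer exchange across the
#' plasma membrane of suspension-cultured cells: influx rate constant `I`
#' (s^-1), efflux rate constant `E` (s^-1), the dimensionless surface
#' adsorption factor `K` (fraction of signal bound to cell surfaces rather
#' than internalised), and optionally `I_prime`, the influx rate constant
#' after a mid-assay treatment such as a protonophore application.
#'
#' All components must be non-negative.
#'
#' @param I influx rate constant, s^-1.
#' @param E efflux rate constant, s^-1.
#' @param K adsorption factor, dimensionless. Default 0.
#' @param I_prime optional post-treatment influx rate constant, s^-1.
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(I = 17.86e-3, E = 4e-3, K = 0.02)
#' @export
kinetic_params <- function(I, E, K = 0, I_prime = NULL) {
  check_number(I, "I", min = 0)
  check_number(E, "E", min = 0)
  check_number(K, "K", min = 0)
  if (!is.null(I_prime)) check_number(I_prime, "I_prime", min = 0)
  structure(list(I = I, E = E, K = K, I_prime = I_prime),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> I = %g /s, E = %g /s, K = %g", x$I, x$E, x$K))
  if (!is.null(x$I_prime)) cat(sprintf(", I' = %g /s", x$I_prime))
  cat("\n")
  invisible(x)
}

#' Saturation (dose-response) model parameters
#'
#' Parameters of the competitive-saturation model for the influx rate constant
#' as a function of competitor concentration,
#' `I(cK) = v_lim / (IC50 + cK) + D`: `v_lim` sets the scale of the saturable
#' transport component (nM s^-1 under this parameterisation), `IC50` (nM) is
#' the competitor concentration at which the saturable component is halved,
#' and `D` (s^-1) is the residual influx that persists at full saturation.
#'
#' @param v_lim saturable transport scale, nM s^-1; >= 0.
#' @param IC50 half-saturation competitor concentration, nM; >= 0.
#' @param D residual influx rate constant, s^-1; >= 0.
#' @return An object of class `saturation_params`.
#' @examples
#' saturation_params(v_lim = 1.8, IC50 = 112.21, D = 2e-3)
#' @export
saturation_params <- function(v_lim, IC50, D) {
  check_number(v_lim, "v_lim", min = 0)
  check_number(IC50, "IC50", min = 0)
  check_number(D, "D", min = 0)
  structure(list(v_lim = v_lim, IC50 = IC50, D = D),
            class = "saturation_params")
}

#' @export
print.saturation_params <- function(x, ...) {
  cat(sprintf("<saturation_params> v_lim = %g nM/s, IC50 = %g nM, D = %g /s\n",
              x$v_lim, x$IC50, x$D))
  invisible(x)
}

# --- internal validation helpers -------------------------------------------

validation_error <- function(msg) {
  stop(errorCondition(msg, class = c("ckflux_validation_error", "error")))
}

config_error <- function(msg) {
  stop(errorCondition(msg, class = c("ckflux_config_error", "error")))
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    validation_error(sprintf("`%s` must be a single finite number", name))
  if (strict && x <= min)
    validation_error(sprintf("`%s` must be > %g (got %g)", name, min, x))
  if (!strict && x < min)
    validation_error(sprintf("`%s` must be >= %g (got %g)", name, min, x))
  invisible(x)
}

# f*K < 1 keeps the measured dynamic fraction (1 - f*K) positive
check_fk <- function(f, K) {
  if (f * K >= 1)
    validation_error(sprintf(
      "f*K must be < 1 for a physically meaningful signal fraction (f = %g, K = %g)",
      f, K))
  invisible(NULL)
}
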