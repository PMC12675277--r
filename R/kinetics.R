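#' Evaluate the tracer accumulation model
#'
#' Closed-form measured intracellular tracer concentration at time `t` for a
#' cell suspension with first-order influx (`I`) and efflux (`E`) and a
#' surface-adsorption offset (`K`):
#'
#' \deqn{c_I(t) = \frac{I c_0}{f I + E}\left[1 - e^{-t(fI+E)}\right](1 - fK) + K c_0}
#'
#' The bracketed term is the solution of the mass balance
#' `dc/dt = I (c0 - f c) - E c` from `c(0) = 0`; the factor `(1 - fK)` maps
#' the internal dynamic pool to the measured signal and `K c0` is the
#' instantaneously adsorbed surface fraction. In the degenerate case
#' `f I + E = 0` the analytic limit `I c0 t (1 - fK) + K c0` is returned
#' instead of dividing by zero.
#'
#' @param t time, seconds; scalar or vector, all >= 0.
#' @param params a [kinetic_params()] object.
#' @param c0 initial extracellular tracer concentration, nM; > 0.
#' @param f dimensionless volume-correction factor; > 0.
#' @return Measured intracellular concentration(s), nM; same length as `t`.
#' @examples
#' p <- kinetic_params(I = 0.01, E = 0.005, K = 0)
#' eval_accumulation(300, p, c0 = 2, f = 0.05)  # ~2.938 nM
#' @export
eval_accumulation <- function(t, params, c0, f) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(!is.finite(t)) || any(t < 0))
    validation_error("`t` must be finite and >= 0")
  check_number(c0, "c0", min = 0, strict = TRUE)
  check_number(f, "f", min = 0, strict = TRUE)
  check_fk(f, params$K)
  accum_branch(t, params$I, params$E, c0, f) * (1 - f * params$K) +
    params$K * c0
}

# dynamic (pre-adsorption) accumulation term of the closed form, with the
# f*I + E -> 0 limit handled analytically
accum_branch <- function(t, I, E, c0, f) {
  r <- f * I + E
  if (r == 0) I * c0 * t else I * c0 / r * (1 - exp(-t * r))
}

#' Evaluate the accumulation model with a mid-assay treatment
#'
#' Piecewise extension of [eval_accumulation()] for assays in which a chemical
#' treatment applied at time `t_prime` changes the influx rate constant from
#' `I` to `I_prime` (efflux and adsorption are unchanged). For `t <= t_prime`
#' the ordinary model applies; afterwards the internal pool relaxes with rate
#' `f I' + E` from its value at `t_prime` towards the `I'` steady state:
#'
#' \deqn{c_I(t) = K c_0 + (1 - fK)\left\{\frac{I' c_0}{fI'+E}\left[1 -
#'   e^{(t'-t)(fI'+E)}\right] + \frac{I c_0}{fI+E}\left[1 -
#'   e^{-t'(fI+E)}\right] e^{(t'-t)(fI'+E)}\right\}}
#'
#' The two branches agree at `t = t_prime`.
#'
#' @inheritParams eval_accumulation
#' @param params a [kinetic_params()] with `I_prime` set.
#' @param t_prime treatment time, seconds; > 0.
#' @return Measured intracellular concentration(s), nM.
#' @export
eval_accumulation_treatment <- function(t, params, t_prime, c0, f) {
  stopifnot(inherits(params, "kinetic_params"))
  if (is.null(params$I_prime))
    config_error("`params$I_prime` must be set for a treatment evaluation")
  if (is.null(t_prime))
    config_error("`t_prime` must be supplied for a treatment evaluation")
  check_number(t_prime, "t_prime", min = 0, strict = TRUE)
  if (any(!is.finite(t)) || any(t < 0))
    validation_error("`t` must be finite and >= 0")
  check_number(c0, "c0", min = 0, strict = TRUE)
  check_number(f, "f", min = 0, strict = TRUE)
  check_fk(f, params$K)

  I <- params$I; E <- params$E; K <- params$K; Ip <- params$I_prime
  pre <- accum_branch(t, I, E, c0, f)
  rp <- f * Ip + E
  decay <- exp((t_prime - t) * rp)             # relaxation since treatment
  post <- accum_branch_post(t, t_prime, Ip, E, c0, f, decay) +
    accum_branch(t_prime, I, E, c0, f) * decay
  dynamic <- ifelse(t <= t_prime, pre, post)
  K * c0 + (1 - f * K) * dynamic
}

accum_branch_post <- function(t, t_prime, Ip, E, c0, f, decay) {
  rp <- f * Ip + E
  if (rp == 0) Ip * c0 * (t - t_prime) else Ip * c0 / rp * (1 - decay)
}

#' Steady-state accumulation level
#'
#' The `t -> Inf` limit of [eval_accumulation()]:
#' `I c0 / (f I + E) * (1 - fK) + K c0`. Diverges when `f I + E = 0` with
#' `I > 0` (influx without any removal term).
#'
#' @inheritParams eval_accumulation
#' @return Steady-state measured concentration, nM.
#' @export
steady_state <- function(params, c0, f) {
  stopifnot(inherits(params, "kinetic_params"))
  check_number(c0, "c0", min = 0, strict = TRUE)
  check_number(f, "f", min = 0, strict = TRUE)
  check_fk(f, params$K)
  r <- f * params$I + params$E
  if (r == 0) {
    if (params$I > 0)
      validation_error("f*I + E = 0 with I > 0: accumulation is unbounded")
    return(params$K * c0)
  }
  params$I * c0 / r * (1 - f * params$K) + params$K * c0
}

#' Model curve for visualisation with K forced to zero
#'
#' Plotting convention for comparing accumulation curves across assays: the
#' fitted `I` and `E` are kept but the adsorption offset `K` is set to 0 and a
#' common `c0` (default 2 nM) is imposed, so curves from assays with
#' different tracer batches align at the origin.
#'
#' @param params a [kinetic_params()] object (its `K` is ignored).
#' @param t_grid times at which to sample the curve, seconds.
#' @param c0 common extracellular concentration for display, nM; default 2.
#' @param f dimensionless volume-correction factor.
#' @return data.frame with columns `time_s`, `conc_nM_model`.
#' @export
visualization_curve <- function(params, t_grid, c0 = 2, f) {
  p0 <- kinetic_params(I = params$I, E = params$E, K = 0)
  data.frame(time_s = as.numeric(t_grid),
             conc_nM_model = eval_accumulation(t_grid, p0, c0 = c0, f = f))
}

#' Reference ODE integration of the accumulation model
#'
#' Independent fixed-step fourth-order Runge-Kutta integration of the mass
#' balance `dc/dt = I (c0 - f c) - E c` from `c(0) = 0`, switching `I` to
#' `I_prime` at `t_prime` when given, followed by the measured-signal mapping
#' `(1 - fK) c + K c0`. Used to validate the closed forms in
#' [eval_accumulation()] and [eval_accumulation_treatment()]; vectorised over
#' parameter sets so many random draws integrate in one sweep.
#'
#' @param times sample times, seconds; non-negative, increasing.
#' @param I,E,K numeric vectors (recycled to a common length) of parameter
#'   sets to integrate.
#' @param c0,f assay constants (scalars).
#' @param t_prime optional treatment time, seconds.
#' @param I_prime optional post-treatment influx vector (required with
#'   `t_prime`).
#' @param dt integration step, seconds; default 0.01.
#' @return Matrix of measured concentrations, `length(times)` rows by
#'   parameter-set columns.
#' @export
integrate_uptake_ode <- function(times, I, E, K = 0, c0, f,
                                 t_prime = NULL, I_prime = NULL, dt = 0.01) {
  n_set <- max(length(I), length(E), length(K),
               length(I_prime %||% 1))
  I <- rep_len(I, n_set); E <- rep_len(E, n_set); K <- rep_len(K, n_set)
  if (!is.null(t_prime)) {
    if (is.null(I_prime)) config_error("`I_prime` is required with `t_prime`")
    I_prime <- rep_len(I_prime, n_set)
  }
  times <- as.numeric(times)
  if (any(times < 0) || is.unsorted(times, strictly = FALSE))
    validation_error("`times` must be non-negative and increasing")

  out <- matrix(NA_real_, length(times), n_set)
  conc <- numeric(n_set)
  t_now <- 0
  next_i <- 1L
  # record any t = 0 samples
  while (next_i <= length(times) && times[next_i] <= 0) {
    out[next_i, ] <- conc
    next_i <- next_i + 1L
  }
  influx <- I
  while (next_i <= length(times)) {
    t_target <- times[next_i]
    while (t_now < t_target - 1e-12) {
      h <- min(dt, t_target - t_now)
      # split the step at t_prime so the influx switch lands exactly
      if (!is.null(t_prime) && t_now < t_prime && t_now + h > t_prime)
        h <- t_prime - t_now
      deriv <- function(c) influx * (c0 - f * c) - E * c
      k1 <- deriv(conc)
      k2 <- deriv(conc + h / 2 * k1)
      k3 <- deriv(conc + h / 2 * k2)
      k4 <- deriv(conc + h * k3)
      conc <- conc + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t_now <- t_now + h
      if (!is.null(t_prime) && abs(t_now - t_prime) <= 1e-12)
        influx <- I_prime
    }
    out[next_i, ] <- conc
    next_i <- next_i + 1L
  }
  sweep(out, 2, (1 - f * K), `*`) +
    matrix(K * c0, length(times), n_set, byrow = TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
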