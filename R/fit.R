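#' Solver configuration for bounded least-squares fits
#'
#' Settings passed to the Levenberg-Marquardt optimiser used throughout the
#' package. Defaults follow the curve-fitting setup used for the accumulation
#' model: function and step tolerances of 1e-15, initial guesses of 1e-3 for
#' the rate constants `I` and `E` and 0 for the adsorption factor `K`, all
#' parameters bounded below by 0.
#'
#' @param ftol relative reduction in the sum of squares at which to stop.
#' @param xtol relative parameter step at which to stop.
#' @param max_nfev cap on function evaluations.
#' @param init_I,init_E,init_K initial guesses for the kinetic parameters.
#' @param init_sat initial guess used for each saturation-model parameter
#'   (`v_lim`, `IC50`, `D`).
#' @param bound_tol parameters closer than this to a bound are flagged in
#'   `bound_hits`.
#' @return A list of class `solver_control`.
#' @export
solver_control <- function(ftol = 1e-15, xtol = 1e-15, max_nfev = 1e5,
                           init_I = 1e-3, init_E = 1e-3, init_K = 0,
                           init_sat = 1, bound_tol = 1e-12) {
  structure(list(ftol = ftol, xtol = xtol, max_nfev = max_nfev,
                 init_I = init_I, init_E = init_E, init_K = init_K,
                 init_sat = init_sat, bound_tol = bound_tol),
            class = "solver_control")
}

# shared wrapper around minpack.lm with the package's bounds/tolerance policy
run_lm <- function(par, resid_fn, lower, control) {
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = par, lower = lower, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      ftol = control$ftol, ptol = control$xtol,
      maxfev = as.integer(control$max_nfev), maxiter = 1024L)))
  list(par = fit$par,
       residual_norm = fit$deviance,
       converged = fit$info %in% 1:4,
       info = fit$info, message = fit$message)
}

fit_result <- function(params, shared = NULL, residual_norm, converged,
                       bound_hits = character(0), notes = character(0)) {
  structure(list(params = params, shared = shared,
                 residual_norm = residual_norm, converged = converged,
                 bound_hits = bound_hits, notes = notes),
            class = "ckflux_fit")
}

#' @export
print.ckflux_fit <- function(x, ...) {
  cat(sprintf("<ckflux_fit> %d assay(s), RSS = %.6g, converged: %s\n",
              nrow(x$params), x$residual_norm, x$converged))
  print(x$params, row.names = FALSE)
  if (length(x$bound_hits)) cat("at bound:", paste(x$bound_hits, collapse = ", "), "\n")
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Fit the accumulation model to a single assay
#'
#' Bounded nonlinear least squares of the closed-form accumulation model
#' against one time course, estimating `(I, E, K)` with lower bounds 0,
#' initial guesses from `control`, and the tight tolerances the model was
#' designed with. A trace that is essentially flat carries no flux
#' information; such fits return `E` with an unidentifiability note rather
#' than failing.
#'
#' @param assay an [accumulation_assay()].
#' @param control a [solver_control()].
#' @return A `ckflux_fit` with one row in `$params` (columns `assay_id`, `I`,
#'   `I_prime`, `E`, `K`), `residual_norm`, `converged`, `bound_hits`,
#'   `notes`.
#' @export
fit_single_assay <- function(assay, control = solver_control()) {
  stopifnot(inherits(assay, "accumulation_assay"))
  if (length(assay$time_s) < 4L)
    validation_error(sprintf(
      "assay '%s': need >= 4 time points to fit 3 parameters (got %d)",
      assay$assay_id, length(assay$time_s)))
  f <- assay$f
  resid_fn <- function(p) {
    assay$conc_nM - eval_accumulation(
      assay$time_s, kinetic_params(p[["I"]], p[["E"]], p[["K"]]),
      c0 = assay$c0, f = f)
  }
  lm <- run_lm(c(I = control$init_I, E = control$init_E, K = control$init_K),
               resid_fn, lower = c(0, 0, 0), control)
  p <- lm$par
  notes <- character(0)
  # flat trace: no usable flux signal -> E is unidentifiable
  if (diff(range(assay$conc_nM)) < 1e-9 * assay$c0 ||
      p[["I"]] <= control$bound_tol)
    notes <- c(notes, "flat or influx-free trace: E unidentifiable")
  fit_result(
    params = data.frame(assay_id = assay$assay_id, I = p[["I"]],
                        I_prime = NA_real_, E = p[["E"]], K = p[["K"]],
                        stringsAsFactors = FALSE),
    residual_norm = lm$residual_norm, converged = lm$converged,
    bound_hits = names(p)[p <= control$bound_tol],
    notes = c(notes, if (!lm$converged) lm$message))
}

#' Jointly fit a dataset with shared efflux and adsorption
#'
#' Global bounded least squares across all assays of a dataset: each assay
#' keeps its own influx constant `I` (and its own `c0`), while a single
#' efflux constant `E` and adsorption factor `K` are shared by every assay.
#' Residuals of all assays are stacked into one objective. This is the
#' constrained fit used when comparing influx across conditions, so that
#' condition differences load onto `I` alone.
#'
#' @param dataset an [assay_dataset()].
#' @param control a [solver_control()].
#' @return A `ckflux_fit`; `$params` has one row per assay and `$shared`
#'   holds the common `(E, K)`.
#' @export
fit_dataset_shared <- function(dataset, control = solver_control()) {
  stopifnot(inherits(dataset, "assay_dataset"))
  assays <- dataset$assays
  n <- length(assays)
  for (a in assays)
    if (length(a$time_s) < 2L)
      validation_error(sprintf("assay '%s': too few points", a$assay_id))
  if (sum(vapply(assays, function(a) length(a$time_s), integer(1))) < n + 2L)
    validation_error("dataset under-determined: fewer points than parameters")

  resid_fn <- function(p) {
    E <- p[[n + 1L]]; K <- p[[n + 2L]]
    unlist(lapply(seq_len(n), function(i) {
      a <- assays[[i]]
      a$conc_nM - eval_accumulation(
        a$time_s, kinetic_params(p[[i]], E, K), c0 = a$c0, f = a$f)
    }), use.names = FALSE)
  }
  par0 <- c(rep(control$init_I, n), control$init_E, control$init_K)
  names(par0) <- c(paste0("I_", names(assays)), "E", "K")
  lm <- run_lm(par0, resid_fn, lower = rep(0, n + 2L), control)
  p <- lm$par
  fit_result(
    params = data.frame(assay_id = names(assays), I = unname(p[seq_len(n)]),
                        I_prime = NA_real_, E = unname(p[[n + 1L]]),
                        K = unname(p[[n + 2L]]), stringsAsFactors = FALSE),
    shared = c(E = unname(p[[n + 1L]]), K = unname(p[[n + 2L]])),
    residual_norm = lm$residual_norm, converged = lm$converged,
    bound_hits = names(p)[p <= control$bound_tol],
    notes = if (!lm$converged) lm$message else character(0))
}

#' Fit the piecewise model to a mid-assay treatment time course
#'
#' Estimates `(I, I', E, K)` for an assay in which a treatment at `t_prime`
#' (for example a protonophore added 7 min into the assay) changes the influx
#' rate. `I'` starts from the same initial guess as `I`. When the assay has
#' no points after `t_prime` the ordinary three-parameter model is fitted
#' instead, with a warning.
#'
#' @param assay an [accumulation_assay()] with `t_prime` set.
#' @param control a [solver_control()].
#' @return A `ckflux_fit` with `I_prime` populated.
#' @export
fit_treatment_assay <- function(assay, control = solver_control()) {
  stopifnot(inherits(assay, "accumulation_assay"))
  if (is.null(assay$t_prime))
    config_error(sprintf("assay '%s' has no t_prime", assay$assay_id))
  if (!any(assay$time_s > assay$t_prime)) {
    warning(sprintf(
      "assay '%s': no points after t_prime; falling back to the untreated model",
      assay$assay_id))
    return(fit_single_assay(assay, control))
  }
  if (length(assay$time_s) < 5L)
    validation_error(sprintf(
      "assay '%s': need >= 5 time points to fit 4 parameters", assay$assay_id))
  resid_fn <- function(p) {
    assay$conc_nM - eval_accumulation_treatment(
      assay$time_s,
      kinetic_params(p[["I"]], p[["E"]], p[["K"]], I_prime = p[["I_prime"]]),
      t_prime = assay$t_prime, c0 = assay$c0, f = assay$f)
  }
  lm <- run_lm(c(I = control$init_I, I_prime = control$init_I,
                 E = control$init_E, K = control$init_K),
               resid_fn, lower = rep(0, 4L), control)
  p <- lm$par
  fit_result(
    params = data.frame(assay_id = assay$assay_id, I = p[["I"]],
                        I_prime = p[["I_prime"]], E = p[["E"]], K = p[["K"]],
                        stringsAsFactors = FALSE),
    residual_norm = lm$residual_norm, converged = lm$converged,
    bound_hits = names(p)[p <= control$bound_tol],
    notes = if (!lm$converged) lm$message else character(0))
}

#' Median influx constants by condition group
#'
#' Summarises fitted influx constants across replicate assays: the median of
#' per-assay `I` within each condition group (the even-count median is the
#' midpoint of the two central values, the usual convention). Empty groups
#' are dropped with a warning.
#'
#' @param fits a `ckflux_fit` or list of them.
#' @param grouping named character vector mapping `assay_id` to a group
#'   label.
#' @return data.frame with columns `group`, `n`, `median_I`; attribute
#'   `per_assay` carries the underlying per-assay table.
#' @export
summarize_influx <- function(fits, grouping) {
  if (inherits(fits, "ckflux_fit")) fits <- list(fits)
  per <- do.call(rbind, lapply(fits, `[[`, "params"))
  if (is.null(grouping) || is.null(names(grouping)))
    validation_error("`grouping` must be a named vector keyed by assay_id")
  missing_ids <- setdiff(per$assay_id, names(grouping))
  if (length(missing_ids))
    validation_error(paste("no group for assay(s):",
                           paste(missing_ids, collapse = ", ")))
  per$group <- unname(grouping[per$assay_id])
  empty <- setdiff(unique(grouping), per$group)
  if (length(empty))
    warning("omitting empty group(s): ", paste(empty, collapse = ", "))
  agg <- aggregate(I ~ group, data = per, FUN = stats::median)
  cnt <- aggregate(assay_id ~ group, data = per, FUN = length)
  out <- merge(cnt, agg, by = "group")
  names(out) <- c("group", "n", "median_I")
  attr(out, "per_assay") <- per
  out
}
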