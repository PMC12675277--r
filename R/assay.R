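#' A single radiotracer accumulation time course
#'
#' One accumulation assay: intracellular tracer concentration sampled at
#' increasing times after tracer addition to a cell suspension, together with
#' the experimental constants needed to interpret it (initial extracellular
#' tracer concentration `c0` and the intra/extracellular volume-correction
#' factor `f`). `t_prime`, when set, marks a mid-assay chemical treatment
#' after which the influx rate constant may change.
#'
#' @param assay_id character label identifying the assay.
#' @param time_s numeric vector of sampling times, seconds; strictly
#'   increasing, all >= 0.
#' @param conc_nM intracellular tracer concentrations, nM; same length as
#'   `time_s`, all >= 0.
#' @param c0 initial extracellular tracer concentration, nM; > 0.
#' @param f dimensionless volume-correction factor; > 0.
#' @param t_prime optional treatment time, seconds; must fall within the
#'   sampled time span.
#' @param condition named list of free-text metadata (tracer, competitor,
#'   treatment, replicate, ...).
#' @return An object of class `accumulation_assay`.
#' @export
accumulation_assay <- function(assay_id, time_s, conc_nM, c0, f,
                               t_prime = NULL, condition = list()) {
  if (!is.character(assay_id) || length(assay_id) != 1L)
    validation_error("`assay_id` must be a single character label")
  if (length(time_s) != length(conc_nM))
    validation_error(sprintf(
      "assay '%s': time_s and conc_nM must have equal length", assay_id))
  if (any(!is.finite(time_s)) || any(time_s < 0))
    validation_error(sprintf("assay '%s': time points must be finite and >= 0",
                             assay_id))
  if (any(diff(time_s) <= 0))
    validation_error(sprintf(
      "assay '%s': time points must be strictly increasing", assay_id))
  if (any(!is.finite(conc_nM)) || any(conc_nM < 0))
    validation_error(sprintf(
      "assay '%s': concentrations must be finite and >= 0", assay_id))
  check_number(c0, "c0", min = 0, strict = TRUE)
  check_number(f, "f", min = 0, strict = TRUE)
  if (!is.null(t_prime)) {
    check_number(t_prime, "t_prime", min = 0, strict = TRUE)
    if (t_prime < min(time_s) || t_prime > max(time_s))
      validation_error(sprintf(
        "assay '%s': t_prime (%g s) lies outside the sampled span [%g, %g] s",
        assay_id, t_prime, min(time_s), max(time_s)))
  }
  structure(list(assay_id = assay_id, time_s = as.numeric(time_s),
                 conc_nM = as.numeric(conc_nM), c0 = c0, f = f,
                 t_prime = t_prime, condition = condition),
            class = "accumulation_assay")
}

#' @export
print.accumulation_assay <- function(x, ...) {
  cat(sprintf("<accumulation_assay> '%s': %d points over [%g, %g] s, c0 = %g nM, f = %g%s\n",
              x$assay_id, length(x$time_s), min(x$time_s), max(x$time_s),
              x$c0, x$f,
              if (is.null(x$t_prime)) "" else sprintf(", t' = %g s", x$t_prime)))
  invisible(x)
}

#' A collection of accumulation assays sharing a volume-correction factor
#'
#' Groups assays for joint fitting. All assays must carry the same `f`;
#' `grouping` optionally maps assay ids to condition groups (e.g. tracer or
#' treatment) for downstream median summaries.
#'
#' @param assays list of [accumulation_assay()] objects; non-empty.
#' @param grouping optional named character vector mapping assay_id to a
#'   condition group.
#' @return An object of class `assay_dataset` with elements `assays`, `f`,
#'   `grouping`.
#' @export
assay_dataset <- function(assays, grouping = NULL) {
  if (length(assays) == 0L)
    validation_error("`assays` must be a non-empty list of accumulation assays")
  ok <- vapply(assays, inherits, logical(1), "accumulation_assay")
  if (!all(ok))
    validation_error("all elements of `assays` must be accumulation_assay objects")
  ids <- vapply(assays, `[[`, character(1), "assay_id")
  if (anyDuplicated(ids))
    validation_error("assay ids must be unique within a dataset")
  fs <- vapply(assays, `[[`, numeric(1), "f")
  if (diff(range(fs)) > 0)
    validation_error("all assays in a dataset must share the same f")
  names(assays) <- ids
  structure(list(assays = assays, f = fs[[1L]], grouping = grouping),
            class = "assay_dataset")
}

#' @export
print.assay_dataset <- function(x, ...) {
  cat(sprintf("<assay_dataset> %d assays, f = %g\n", length(x$assays), x$f))
  invisible(x)
}

#' Convert a dataset to the long-format assay table
#'
#' @param x an `assay_dataset`.
#' @param ... unused.
#' @return A data.frame in the long assay schema (see [read_assays()]).
#' @export
as.data.frame.assay_dataset <- function(x, ...) {
  meta_field <- function(a, key) {
    v <- a$condition[[key]]
    if (is.null(v)) NA else v
  }
  do.call(rbind, lapply(x$assays, function(a) {
    data.frame(
      assay_id = a$assay_id, time_s = a$time_s, conc_nM = a$conc_nM,
      c0_nM = a$c0, f = a$f,
      t_prime_s = if (is.null(a$t_prime)) NA_real_ else a$t_prime,
      tracer = meta_field(a, "tracer"),
      competitor = meta_field(a, "competitor"),
      competitor_conc_nM = meta_field(a, "competitor_conc_nM"),
      treatment = meta_field(a, "treatment"),
      replicate = meta_field(a, "replicate"),
      row.names = NULL, stringsAsFactors = FALSE)
  }))
}
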