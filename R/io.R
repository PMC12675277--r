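#' Read accumulation assays from a long-format CSV
#'
#' Expected header: `assay_id,time_s,conc_nM,c0_nM,f,t_prime_s,tracer,
#' competitor,competitor_conc_nM,treatment,replicate`. Rows are grouped by
#' `assay_id`; an empty `t_prime_s` means no mid-assay treatment. Schema
#' violations (missing columns, non-increasing times within an assay,
#' negative concentrations) raise an error naming the offending assay.
#'
#' @param path CSV file path.
#' @return An [assay_dataset()].
#' @export
read_assays <- function(path) {
  if (!file.exists(path)) validation_error(paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("assay_id", "time_s", "conc_nM", "c0_nM", "f")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    validation_error(paste("missing required column(s):",
                           paste(missing_cols, collapse = ", ")))
  optional <- c("t_prime_s", "tracer", "competitor", "competitor_conc_nM",
                "treatment", "replicate")
  for (col in optional) if (!col %in% names(df)) df[[col]] <- NA
  assays <- lapply(split(df, factor(df$assay_id, levels = unique(df$assay_id))),
                   function(rows) {
    rows <- rows[order(rows$time_s), , drop = FALSE]
    if (anyDuplicated(rows$time_s))
      validation_error(sprintf(
        "assay '%s': duplicated time point(s) at t = %s s",
        rows$assay_id[1L],
        paste(unique(rows$time_s[duplicated(rows$time_s)]), collapse = ", ")))
    tp <- rows$t_prime_s[1L]
    meta <- function(x) if (all(is.na(x))) NULL else x[1L]
    accumulation_assay(
      assay_id = as.character(rows$assay_id[1L]),
      time_s = rows$time_s, conc_nM = rows$conc_nM,
      c0 = rows$c0_nM[1L], f = rows$f[1L],
      t_prime = if (is.na(tp)) NULL else tp,
      condition = list(tracer = meta(rows$tracer),
                       competitor = meta(rows$competitor),
                       competitor_conc_nM = meta(rows$competitor_conc_nM),
                       treatment = meta(rows$treatment),
                       replicate = meta(rows$replicate)))
  })
  assay_dataset(unname(assays))
}

#' Write an assay dataset to the long-format CSV schema
#'
#' @param dataset an [assay_dataset()].
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_assays <- function(dataset, path) {
  stopifnot(inherits(dataset, "assay_dataset"))
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write fitted kinetic parameters
#'
#' One row per assay with columns `assay_id, I_per_s, I_prime_per_s, E_per_s,
#' K, shared_fit, residual_norm, converged`.
#'
#' @param fit a `ckflux_fit`.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "ckflux_fit"))
  out <- data.frame(assay_id = fit$params$assay_id,
                    I_per_s = fit$params$I,
                    I_prime_per_s = fit$params$I_prime,
                    E_per_s = fit$params$E, K = fit$params$K,
                    shared_fit = !is.null(fit$shared),
                    residual_norm = fit$residual_norm,
                    converged = fit$converged)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a dose-response series table
#'
#' Expected columns: `tracer,competitor,competitor_conc_nM,I_per_s`; one
#' [dose_response_series()] is built per tracer/competitor pair.
#'
#' @param path CSV file path.
#' @return List of `dose_response_series`.
#' @export
read_dose_series <- function(path) {
  if (!file.exists(path)) validation_error(paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("tracer", "competitor", "competitor_conc_nM", "I_per_s")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    validation_error(paste("missing required column(s):",
                           paste(missing_cols, collapse = ", ")))
  key <- paste(df$tracer, df$competitor, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(rows)
    dose_response_series(rows$competitor_conc_nM, rows$I_per_s,
                         tracer = rows$tracer[1L],
                         competitor = rows$competitor[1L]))
}

#' Read an RGB image (PNG or TIFF)
#'
#' @param path image file; extension selects the reader.
#' @return Numeric array height x width x 3 in [0, 1]; an alpha channel, if
#'   present, is dropped.
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) validation_error(paste("no such file:", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    validation_error(paste("unsupported image format:", ext)))
  if (length(dim(img)) == 2L)
    validation_error("expected an RGB image, got a single channel")
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB array as PNG
#'
#' @param img array height x width x 3 in [0, 1].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(img, path) {
  check_rgb(img)
  png::writePNG(img, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects solver settings, the volume-correction factor, segmentation
#' configuration, simulation defaults, the seed, and the output directory in
#' one validated object. Unknown keys are rejected so that typos in
#' configuration files fail loudly.
#'
#' @param f volume-correction factor used for fitting; default 0.05.
#' @param solver a [solver_control()].
#' @param segmentation a [segmentation_config()].
#' @param seed integer seed for the simulation stages.
#' @param out_dir output directory for pipeline artifacts.
#' @param log_level one of "quiet", "info".
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(f = 0.05, solver = solver_control(),
                            segmentation = segmentation_config(),
                            seed = 1L, out_dir = tempdir(),
                            log_level = "info") {
  check_number(f, "f", min = 0, strict = TRUE)
  stopifnot(inherits(solver, "solver_control"),
            inherits(segmentation, "segmentation_config"))
  if (!log_level %in% c("quiet", "info"))
    config_error("`log_level` must be 'quiet' or 'info'")
  structure(list(f = f, solver = solver, segmentation = segmentation,
                 seed = as.integer(seed), out_dir = out_dir,
                 log_level = log_level),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `f`, `seed`, `out_dir`, `log_level` plus nested `solver`
#' and `segmentation` blocks whose keys match the arguments of
#' [solver_control()] and [segmentation_config()]. Unknown keys at any level
#' are rejected.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_top <- c("f", "seed", "out_dir", "log_level", "solver", "segmentation")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown))
    config_error(paste("unknown configuration key(s):",
                       paste(unknown, collapse = ", ")))
  build <- function(block, ctor) {
    if (is.null(block)) return(ctor())
    bad <- setdiff(names(block), names(formals(ctor)))
    if (length(bad))
      config_error(paste("unknown configuration key(s):",
                         paste(bad, collapse = ", ")))
    do.call(ctor, block)
  }
  pipeline_config(
    f = raw$f %||% 0.05,
    solver = build(raw$solver, solver_control),
    segmentation = build(raw$segmentation, segmentation_config),
    seed = raw$seed %||% 1L,
    out_dir = raw$out_dir %||% tempdir(),
    log_level = raw$log_level %||% "info")
}

pipe_log <- function(config, ...) {
  if (config$log_level != "quiet") message(...)
  invisible(NULL)
}

#' Run pipeline stages in dependency order
#'
#' Executes the requested stages against the configuration: `simulate`
#' generates a seeded demonstration dataset (accumulation assays plus a
#' competition experiment) under `out_dir`; `fit` fits the simulated (or
#' previously written) assays with shared efflux/adsorption; `dose_response`
#' fits the saturation model to the fitted influx constants; `segment`
#' renders and segments a synthetic shoot scene; `rel` simulates a qPCR
#' plate and computes relative expression. An empty stage list is a no-op.
#' Each stage writes its artifacts as CSV (plus PNG for the scene) into
#' `out_dir` and a `run_log.txt` records the seed and configuration digest.
#'
#' @param config a [pipeline_config()].
#' @param stages character subset of
#'   `c("simulate", "fit", "dose_response", "segment", "rel")`.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config, stages = character(0)) {
  stopifnot(inherits(config, "pipeline_config"))
  known <- c("simulate", "fit", "dose_response", "segment", "rel")
  bad <- setdiff(stages, known)
  if (length(bad))
    config_error(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  if (length(stages) == 0L) return(invisible(list()))
  stages <- known[known %in% stages]   # dependency order
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  path_in <- function(name) file.path(config$out_dir, name)

  writeLines(c(sprintf("seed: %d", config$seed),
               sprintf("f: %g", config$f),
               sprintf("config_digest: %s",
                       paste(utils::capture.output(utils::str(config)),
                             collapse = ""))),
             path_in("run_log.txt"))

  if ("simulate" %in% stages) {
    pipe_log(config, "stage simulate: seeded competition experiment")
    design <- simulation_design(c0 = 2, f = config$f, seed = config$seed)
    truth_sat <- saturation_params(v_lim = 1.8, IC50 = 112.21, D = 2e-3)
    ds <- simulate_competition_experiment(truth_sat, shared_E = 4e-3,
                                          shared_K = 0.02, design = design)
    artifacts$assays <- write_assays(ds, path_in("assays.csv"))
    truth <- attr(ds, "truth")
    jsonlite::write_json(
      list(v_lim = truth$truth_sat$v_lim, IC50 = truth$truth_sat$IC50,
           D = truth$truth_sat$D, shared_E = truth$shared_E,
           shared_K = truth$shared_K, ladder = truth$ladder,
           I_ladder = truth$I_ladder),
      path_in("truth.json"), auto_unbox = TRUE, digits = NA)
    artifacts$truth <- path_in("truth.json")
  }

  fit <- NULL
  if ("fit" %in% stages) {
    pipe_log(config, "stage fit: shared-(E,K) constrained fit")
    ds <- read_assays(path_in("assays.csv"))
    fit <- fit_dataset_shared(ds, config$solver)
    pipe_log(config, sprintf("  converged: %s; bound hits: %s",
                             fit$converged,
                             paste(fit$bound_hits, collapse = ", ")))
    artifacts$params <- write_fit(fit, path_in("params.csv"))
  }

  if ("dose_response" %in% stages) {
    pipe_log(config, "stage dose_response: saturation fit of influx constants")
    if (is.null(fit)) {
      ds <- read_assays(path_in("assays.csv"))
      fit <- fit_dataset_shared(ds, config$solver)
    }
    cK <- as.numeric(sub("^cK_", "", fit$params$assay_id))
    series <- dose_response_series(cK, fit$params$I)
    sat <- fit_saturation(series, config$solver)
    utils::write.csv(
      data.frame(tracer = sat$tracer, competitor = sat$competitor,
                 v_lim = sat$params$v_lim, IC50_nM = sat$params$IC50,
                 D_per_s = sat$params$D,
                 no_saturation_flag = sat$no_saturation),
      path_in("saturation.csv"), row.names = FALSE)
    artifacts$saturation <- path_in("saturation.csv")
  }

  if ("segment" %in% stages) {
    pipe_log(config, "stage segment: synthetic scene -> areas")
    scene <- render_shoot_scene(
      blobs = list(list(center = c(160, 160), radius = 62),
                   list(center = c(352, 352), radius = 75)),
      distractors = list(list(center = c(100, 420), radius = 12)))
    artifacts$scene <- write_rgb_image(scene$image, path_in("scene.png"))
    seg <- segment_shoots(scene$image, config$segmentation)
    utils::write.csv(areas_report(seg), path_in("areas.csv"),
                     row.names = FALSE)
    artifacts$areas <- path_in("areas.csv")
  }

  if ("rel" %in% stages) {
    pipe_log(config, "stage rel: qPCR relative expression")
    plate <- simulate_qpcr_plate(
      true_rel = stats::setNames(rep(c(1, 4), each = 6),
                                 sprintf("s%02d", 1:12)),
      noise_sd = 0.2, seed = config$seed,
      genotype = rep(c("wt", "oe"), each = 6))
    plate$rel <- compute_rel(plate$cp_target, plate$cp_ref1, plate$cp_ref2)
    utils::write.csv(plate, path_in("rel.csv"), row.names = FALSE)
    artifacts$rel <- path_in("rel.csv")
  }

  invisible(artifacts)
}
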