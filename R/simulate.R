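#' Design of a simulated accumulation experiment
#'
#' Study conditions under which synthetic assays are generated: by default 12
#' regular samples over 0-900 s (assays run 15-30 min with sampling at
#' regular intervals), an initial extracellular tracer concentration of 2 nM,
#' a volume-correction factor of 0.05, and additive Gaussian measurement
#' noise with standard deviation 2% of `c0`, clipped at zero. Treatment
#' designs place the mid-assay treatment at 420 s (7 min) by default.
#'
#' @param time_grid sampling times, seconds.
#' @param c0 initial extracellular tracer concentration, nM.
#' @param f dimensionless volume-correction factor.
#' @param noise_sd measurement noise standard deviation, nM; default
#'   `0.02 * c0`.
#' @param seed integer seed; required for any noisy simulation.
#' @param t_prime optional treatment time, seconds (use 420 for treatment
#'   designs).
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(time_grid = seq(0, 900, length.out = 12),
                              c0 = 2, f = 0.05, noise_sd = 0.02 * c0,
                              seed = NULL, t_prime = NULL) {
  check_number(c0, "c0", min = 0, strict = TRUE)
  check_number(f, "f", min = 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  if (!is.null(t_prime)) check_number(t_prime, "t_prime", min = 0, strict = TRUE)
  if (any(diff(time_grid) <= 0) || any(time_grid < 0))
    validation_error("`time_grid` must be non-negative and strictly increasing")
  if (noise_sd > 0 && is.null(seed))
    validation_error("a `seed` is required when noise_sd > 0")
  structure(list(time_grid = as.numeric(time_grid), c0 = c0, f = f,
                 noise_sd = noise_sd, seed = seed, t_prime = t_prime),
            class = "simulation_design")
}

#' Simulate one accumulation assay from known kinetics
#'
#' Samples the accumulation model (or its mid-assay treatment variant when
#' the design carries a `t_prime`) on the design's time grid and adds
#' independent Gaussian noise clipped at zero. Deterministic given the seed.
#' The returned assay carries its generating parameters in
#' `attr(, "truth")`.
#'
#' @param truth a [kinetic_params()] object (with `I_prime` for treatment
#'   designs).
#' @param design a [simulation_design()].
#' @param assay_id label for the generated assay.
#' @return An [accumulation_assay()] with a `truth` attribute.
#' @export
simulate_assay <- function(truth, design, assay_id = "sim") {
  stopifnot(inherits(truth, "kinetic_params"),
            inherits(design, "simulation_design"))
  clean <- if (is.null(design$t_prime)) {
    eval_accumulation(design$time_grid, truth, c0 = design$c0, f = design$f)
  } else {
    if (is.null(truth$I_prime))
      config_error("treatment design needs `truth$I_prime`")
    eval_accumulation_treatment(design$time_grid, truth,
                                t_prime = design$t_prime,
                                c0 = design$c0, f = design$f)
  }
  conc <- clean
  if (design$noise_sd > 0) {
    set.seed(design$seed)
    conc <- pmax(0, clean + stats::rnorm(length(clean), 0, design$noise_sd))
  }
  a <- accumulation_assay(assay_id, design$time_grid, conc,
                          c0 = design$c0, f = design$f,
                          t_prime = design$t_prime)
  attr(a, "truth") <- truth
  a
}

#' Simulate a competition (dose-response) experiment
#'
#' Builds one assay per competitor concentration of the ladder: the true
#' influx constant at each concentration follows the saturation model, while
#' the efflux constant and adsorption factor are shared across the whole
#' dataset (the constrained-fit scenario). The default ladder is the
#' six-step series 0, 2, 20, 200, 2000, 20000 nM. Pushing the result through
#' [fit_dataset_shared()] and [fit_saturation()] should recover `truth_sat`.
#'
#' @param truth_sat a [saturation_params()] object (ground truth).
#' @param shared_E shared efflux rate constant, s^-1.
#' @param shared_K shared adsorption factor.
#' @param ladder competitor concentrations, nM.
#' @param design a [simulation_design()]; per-assay seeds are derived from
#'   `design$seed`.
#' @return An [assay_dataset()] with a `truth` attribute (list of
#'   `truth_sat`, `shared_E`, `shared_K`, `I_ladder`).
#' @export
simulate_competition_experiment <- function(truth_sat, shared_E, shared_K,
                                            ladder = c(0, 2, 20, 200, 2000, 20000),
                                            design = simulation_design(seed = 1)) {
  stopifnot(inherits(truth_sat, "saturation_params"))
  if (length(ladder) == 0L)
    validation_error("`ladder` must be non-empty")
  I_true <- eval_saturation(ladder, truth_sat)
  assays <- lapply(seq_along(ladder), function(i) {
    d <- design
    if (!is.null(design$seed)) d$seed <- design$seed + i
    simulate_assay(kinetic_params(I_true[i], shared_E, shared_K), d,
                   assay_id = sprintf("cK_%g", ladder[i]))
  })
  ds <- assay_dataset(assays)
  attr(ds, "truth") <- list(truth_sat = truth_sat, shared_E = shared_E,
                            shared_K = shared_K, ladder = ladder,
                            I_ladder = I_true)
  ds
}

#' Render a synthetic top-view shoot scene
#'
#' Paints solid rosette-like disks in a green whose CIELAB coordinates pass
#' the default segmentation thresholds, on a near-white background, plus
#' small distractor objects meant to fall below the pre-closing size filter.
#' Rendering is deterministic; the ground-truth mask and per-blob pixel
#' areas (overlapping blobs merged) are returned alongside the image.
#'
#' @param blobs list of `list(center = c(row, col), radius = r)` rosette
#'   disks; optional `color` per blob (sRGB triple in [0,1]).
#' @param distractors like `blobs`; small objects, default gray-green.
#' @param canvas `c(height, width)` in pixels.
#' @param blob_color default sRGB for rosettes; the default
#'   `(0.20, 0.60, 0.20)` maps to approximately L* 56, a* -50, b* 44.
#' @param background sRGB background triple; default slightly warm white.
#' @return List of class `shoot_scene`: `image` (H x W x 3), `truth_mask`
#'   (logical), `truth_areas` (pixel counts per merged blob, raster order),
#'   `truth_count`.
#' @export
render_shoot_scene <- function(blobs, distractors = list(),
                               canvas = c(512L, 512L),
                               blob_color = c(0.20, 0.60, 0.20),
                               background = c(0.96, 0.96, 0.93)) {
  h <- canvas[1L]; w <- canvas[2L]
  img <- array(rep(background, each = h * w), dim = c(h, w, 3L))
  truth <- matrix(FALSE, h, w)
  paint <- function(img, center, radius, color) {
    rows <- pmax(1L, floor(center[1L] - radius)):pmin(h, ceiling(center[1L] + radius))
    cols <- pmax(1L, floor(center[2L] - radius)):pmin(w, ceiling(center[2L] + radius))
    rr <- outer(rows - center[1L], rep(1, length(cols)))
    cc <- outer(rep(1, length(rows)), cols - center[2L])
    inside <- rr^2 + cc^2 <= radius^2
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[rows, cols][inside] <- color[ch]
      img[, , ch] <- plane
    }
    attr(img, "painted") <- cbind(rows[row(inside)[inside]],
                                  cols[col(inside)[inside]])
    img
  }
  for (b in blobs) {
    if (b$center[1L] - b$radius < 1 || b$center[1L] + b$radius > h ||
        b$center[2L] - b$radius < 1 || b$center[2L] + b$radius > w)
      validation_error("blob extends beyond the canvas")
    img <- paint(img, b$center, b$radius, b$color %||% blob_color)
    px <- attr(img, "painted")
    truth[px] <- TRUE
  }
  for (d in distractors)
    img <- paint(img, d$center, d$radius, d$color %||% c(0.55, 0.62, 0.55))
  attr(img, "painted") <- NULL
  truth_labels <- label_components(truth, 4L)
  n <- max(truth_labels)
  areas <- if (n > 0L) as.integer(tabulate(truth_labels[truth_labels > 0L], n))
           else integer(0)
  structure(list(image = img, truth_mask = truth, truth_areas = areas,
                 truth_count = n),
            class = "shoot_scene")
}

#' Simulate a qPCR plate with known relative expression
#'
#' Generates crossing-point records whose noiseless relative expression
#' equals the supplied ground truth: both reference genes cross at `ref_cp`
#' and the target at `ref_cp - log2(true_rel)`, plus optional Gaussian cycle
#' noise on every crossing point.
#'
#' @param true_rel named numeric vector of true relative expression levels,
#'   one per sample; > 0.
#' @param ref_cp reference-gene crossing point, cycles; default 20.
#' @param noise_sd crossing-point noise standard deviation, cycles; default
#'   0.
#' @param seed integer seed (required when `noise_sd > 0`).
#' @param genotype optional character vector of group labels per sample.
#' @return data.frame with columns `sample_id`, `genotype`, `cp_target`,
#'   `cp_ref1`, `cp_ref2` and a `truth` attribute.
#' @export
simulate_qpcr_plate <- function(true_rel, ref_cp = 20, noise_sd = 0,
                                seed = NULL, genotype = NULL) {
  if (any(!is.finite(true_rel)) || any(true_rel <= 0))
    validation_error("`true_rel` must be finite and > 0")
  check_number(ref_cp, "ref_cp", min = 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  n <- length(true_rel)
  ids <- names(true_rel) %||% sprintf("s%02d", seq_len(n))
  cp_t <- ref_cp - log2(true_rel)
  cp_r1 <- rep(ref_cp, n); cp_r2 <- rep(ref_cp, n)
  if (noise_sd > 0) {
    if (is.null(seed)) validation_error("a `seed` is required when noise_sd > 0")
    set.seed(seed)
    cp_t <- cp_t + stats::rnorm(n, 0, noise_sd)
    cp_r1 <- cp_r1 + stats::rnorm(n, 0, noise_sd)
    cp_r2 <- cp_r2 + stats::rnorm(n, 0, noise_sd)
  }
  out <- data.frame(sample_id = ids,
                    genotype = genotype %||% rep("g", n),
                    cp_target = cp_t, cp_ref1 = cp_r1, cp_ref2 = cp_r2,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- true_rel
  out
}
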