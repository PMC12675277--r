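test_that("noiseless simulation lies exactly on the model curve", {
  truth <- kinetic_params(I = 17.86e-3, E = 4e-3, K = 0.02)
  d <- noiseless_design()
  a <- simulate_assay(truth, d, "clean")
  expect_equal(a$conc_nM, eval_accumulation(d$time_grid, truth, d$c0, d$f))
  expect_identical(attr(a, "truth"), truth)
  # treatment designs sample the piecewise curve
  truth_t <- kinetic_params(0.02, 4e-3, 0.02, I_prime = 0.002)
  dt <- noiseless_design(t_prime = 420)
  at <- simulate_assay(truth_t, dt, "treat")
  expect_equal(at$conc_nM,
               eval_accumulation_treatment(dt$time_grid, truth_t, 420,
                                           dt$c0, dt$f))
})

test_that("simulation is deterministic given a seed and non-negative", {
  truth <- kinetic_params(I = 5e-3, E = 2e-3, K = 0.01)
  d <- noisy_design(seed = 123)
  a1 <- simulate_assay(truth, d, "s")
  a2 <- simulate_assay(truth, d, "s")
  expect_identical(a1$conc_nM, a2$conc_nM)
  a3 <- simulate_assay(truth, noisy_design(seed = 124), "s")
  expect_false(identical(a1$conc_nM, a3$conc_nM))
  expect_true(all(a1$conc_nM >= 0))
  # a seed is mandatory for noisy designs
  expect_error(simulation_design(noise_sd = 0.04),
               class = "ckflux_validation_error")
})

test_that("measurement noise is unbiased within the CLT bound", {
  truth <- kinetic_params(I = 17.86e-3, E = 4e-3, K = 0.02)
  d0 <- noiseless_design()
  clean <- eval_accumulation(d0$time_grid, truth, d0$c0, d0$f)
  resids <- vapply(1:1000, function(i) {
    a <- simulate_assay(truth, noisy_design(seed = 2000 + i), "r")
    mean(a$conc_nM - clean)
  }, numeric(1))
  n_obs <- 1000 * length(clean)
  se <- 0.04 / sqrt(n_obs)
  # clipping at zero leaves a sub-SE positive bias at the t = 0 point only
  expect_lt(abs(mean(resids)), 3 * se + 0.04 * 0.0833 / length(clean))
})

test_that("competition experiments carry a recoverable truth record", {
  truth_sat <- saturation_params(1.8, 112.21, 2e-3)
  ds <- simulate_competition_experiment(truth_sat, shared_E = 4e-3,
                                        shared_K = 0.02,
                                        design = noiseless_design())
  truth <- attr(ds, "truth")
  expect_equal(truth$ladder, c(0, 2, 20, 200, 2000, 20000))
  expect_equal(length(ds$assays), 6L)
  expect_equal(truth$I_ladder, eval_saturation(truth$ladder, truth_sat))
  # a one-point ladder cannot support a 3-parameter saturation fit
  ds1 <- simulate_competition_experiment(truth_sat, 4e-3, 0.02, ladder = 0,
                                         design = noiseless_design())
  fit1 <- fit_dataset_shared(ds1)
  expect_error(fit_saturation(dose_response_series(0, fit1$params$I)),
               class = "ckflux_validation_error")
})

test_that("rendered scenes are deterministic with exact truth areas", {
  mk <- function() render_shoot_scene(
    blobs = list(list(center = c(100, 100), radius = 64),
                 list(center = c(300, 300), radius = 70)),
    distractors = list(list(center = c(50, 300), radius = 10)),
    canvas = c(400, 400))
  s1 <- mk(); s2 <- mk()
  expect_identical(s1$image, s2$image)
  expect_equal(s1$truth_count, 2L)
  expect_equal(s1$truth_areas, c(sum((-64:64 %o% rep(1, 129))^2 +
                                     (rep(1, 129) %o% -64:64)^2 <= 64^2),
                                 sum((-70:70 %o% rep(1, 141))^2 +
                                     (rep(1, 141) %o% -70:70)^2 <= 70^2)))
  # overlapping blobs merge into one ground-truth object
  sm <- render_shoot_scene(
    blobs = list(list(center = c(100, 100), radius = 60),
                 list(center = c(100, 180), radius = 60)),
    canvas = c(300, 300))
  expect_equal(sm$truth_count, 1L)
  expect_equal(sum(sm$truth_areas), sum(sm$truth_mask))
  expect_equal(render_shoot_scene(list(), canvas = c(64, 64))$truth_count, 0L)
  expect_error(render_shoot_scene(
    blobs = list(list(center = c(5, 5), radius = 30)), canvas = c(64, 64)),
    class = "ckflux_validation_error")
})

test_that("simulated qPCR plates invert through compute_rel", {
  plate <- simulate_qpcr_plate(c(s1 = 1, s2 = 8, s3 = 0.25), ref_cp = 20)
  rel <- compute_rel(plate$cp_target, plate$cp_ref1, plate$cp_ref2)
  expect_equal(rel, c(1, 8, 0.25))
  # true_rel = 8 puts the target 3 cycles below the reference mean
  expect_equal(plate$cp_target[2], 20 - 3)
  expect_error(simulate_qpcr_plate(c(s1 = -1)),
               class = "ckflux_validation_error")
})

test_that("a noisy two-group plate separates at the 0.05 level", {
  plate <- simulate_qpcr_plate(
    true_rel = stats::setNames(rep(c(1, 4), each = 6), sprintf("s%02d", 1:12)),
    noise_sd = 0.25, seed = 31,
    genotype = rep(c("wt", "oe"), each = 6))
  plate$rel <- compute_rel(plate$cp_target, plate$cp_ref1, plate$cp_ref2)
  out <- group_compare(split(plate$rel, plate$genotype))
  expect_lt(out$p_value, 0.05)
})
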