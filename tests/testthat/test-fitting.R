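test_that("single-assay fit recovers noiseless ground truth", {
  truth <- kinetic_params(I = 5e-3, E = 2e-3, K = 0.01)
  a <- simulate_assay(truth, noiseless_design(n_points = 16), "a1")
  fit <- fit_single_assay(a)
  expect_true(fit$converged)
  expect_equal(fit$params$I, truth$I, tolerance = 1e-6)
  expect_equal(fit$params$E, truth$E, tolerance = 1e-6)
  expect_equal(fit$params$K, truth$K, tolerance = 1e-6)
  # scaling c0 leaves the fitted rate constants unchanged
  a2 <- simulate_assay(truth, noiseless_design(n_points = 16, c0 = 4), "a2")
  fit2 <- fit_single_assay(a2)
  expect_equal(fit2$params$I, fit$params$I, tolerance = 1e-6)
  expect_equal(fit2$params$E, fit$params$E, tolerance = 1e-6)
})

test_that("flat traces are reported as unidentifiable, not fitted silently", {
  d <- noiseless_design()
  a <- accumulation_assay("flat", d$time_grid,
                          rep(0.05 * 2, length(d$time_grid)),
                          c0 = 2, f = 0.05)
  fit <- fit_single_assay(a)
  expect_lt(fit$params$I, 1e-8)
  expect_equal(fit$params$K, 0.05, tolerance = 1e-6)
  expect_match(paste(fit$notes, collapse = " "), "unidentifiable")
})

test_that("under-determined fits are refused", {
  a <- accumulation_assay("tiny", c(0, 100, 200), c(0.1, 0.5, 0.8),
                          c0 = 2, f = 0.05)
  expect_error(fit_single_assay(a), class = "ckflux_validation_error")
})

test_that("shared-parameter fit recovers a joint noiseless dataset exactly", {
  I_true <- c(2, 4, 6, 8, 10, 12) * 1e-3
  d <- noiseless_design()
  assays <- lapply(seq_along(I_true), function(i)
    simulate_assay(kinetic_params(I_true[i], 4e-3, 0.02), d, paste0("a", i)))
  fit <- fit_dataset_shared(assay_dataset(assays))
  expect_true(fit$converged)
  expect_equal(fit$params$I, I_true, tolerance = 1e-6)
  expect_equal(unname(fit$shared[["E"]]), 4e-3, tolerance = 1e-6)
  expect_equal(unname(fit$shared[["K"]]), 0.02, tolerance = 1e-6)

  # permuting assay order leaves the shared parameters unchanged
  fit_perm <- fit_dataset_shared(assay_dataset(assays[c(4, 1, 6, 2, 5, 3)]))
  expect_equal(unname(fit_perm$shared), unname(fit$shared), tolerance = 1e-8)
})

test_that("a one-assay shared fit matches the single-assay fit", {
  truth <- kinetic_params(I = 7e-3, E = 3e-3, K = 0.015)
  a <- simulate_assay(truth, noiseless_design(n_points = 16), "solo")
  single <- fit_single_assay(a)
  joint <- fit_dataset_shared(assay_dataset(list(a)))
  expect_equal(joint$params$I, single$params$I, tolerance = 1e-6)
  expect_equal(unname(joint$shared[["E"]]), single$params$E, tolerance = 1e-6)
  expect_equal(unname(joint$shared[["K"]]), single$params$K, tolerance = 1e-6)
})

test_that("treatment fit recovers the pre- and post-treatment influx", {
  truth <- kinetic_params(I = 0.02, E = 0.004, K = 0.02, I_prime = 0.002)
  a <- simulate_assay(truth, noiseless_design(n_points = 16, t_prime = 420),
                      "cccp")
  fit <- fit_treatment_assay(a)
  expect_true(fit$converged)
  expect_equal(fit$params$I, 0.02, tolerance = 1e-5)
  expect_equal(fit$params$I_prime, 0.002, tolerance = 1e-5)
  expect_equal(fit$params$E, 0.004, tolerance = 1e-5)
  expect_equal(fit$params$K, 0.02, tolerance = 1e-5)

  # degenerate treatment (no change in influx) is recovered as I' = I
  truth_eq <- kinetic_params(I = 0.02, E = 0.004, K = 0.02, I_prime = 0.02)
  a_eq <- simulate_assay(truth_eq, noiseless_design(n_points = 16,
                                                    t_prime = 420), "mock")
  fit_eq <- fit_treatment_assay(a_eq)
  expect_equal(fit_eq$params$I_prime, fit_eq$params$I, tolerance = 1e-4)
})

test_that("treatment fit without post-treatment points falls back with a warning", {
  truth <- kinetic_params(I = 0.02, E = 0.004, K = 0.02)
  d <- noiseless_design(n_points = 8, t_max = 420)
  a <- simulate_assay(truth, d, "early")
  a$t_prime <- 420  # treatment at the final sample: nothing after it
  expect_warning(fit <- fit_treatment_assay(a), "falling back")
  expect_true(is.na(fit$params$I_prime))
  expect_equal(fit$params$I, 0.02, tolerance = 1e-5)
})

test_that("refitting from the optimum does not increase the objective", {
  set.seed(11)
  truth <- kinetic_params(I = 17.86e-3, E = 4e-3, K = 0.02)
  a <- simulate_assay(truth, noisy_design(seed = 12), "n1")
  fit <- fit_single_assay(a)
  refit <- fit_single_assay(a, solver_control(init_I = fit$params$I,
                                              init_E = fit$params$E,
                                              init_K = fit$params$K))
  expect_lte(refit$residual_norm, fit$residual_norm * (1 + 1e-10))
})

test_that("noisy joint recovery meets the study's error budget", {
  n_assays <- 8
  I_true <- 17.86e-3 * exp(seq(-0.35, 0.35, length.out = n_assays))
  assays <- lapply(seq_len(n_assays), function(i)
    simulate_assay(kinetic_params(I_true[i], 4e-3, 0.02),
                   noisy_design(seed = 500 + i), paste0("a", i)))
  fit <- fit_dataset_shared(assay_dataset(assays))
  rel_I <- abs(fit$params$I - I_true) / I_true
  expect_lt(stats::median(rel_I), 0.10)
  expect_lt(abs(fit$shared[["E"]] - 4e-3) / 4e-3, 0.15)
})

test_that("median influx summaries follow the midpoint convention", {
  fits <- lapply(1:4, function(i) {
    a <- simulate_assay(kinetic_params(i * 1e-3, 2e-3, 0),
                        noiseless_design(), paste0("a", i))
    fit_single_assay(a)
  })
  grouping <- c(a1 = "odd", a2 = "even", a3 = "odd", a4 = "even")
  s <- summarize_influx(fits, grouping)
  expect_equal(s$median_I[s$group == "odd"], 2e-3, tolerance = 1e-5)
  expect_equal(s$median_I[s$group == "even"], 3e-3, tolerance = 1e-5)
  expect_equal(s$n, c(2L, 2L))
  # a group with an odd count uses the middle value
  s3 <- summarize_influx(fits[1:3], c(a1 = "g", a2 = "g", a3 = "g"))
  expect_equal(s3$median_I, 2e-3, tolerance = 1e-5)
  expect_error(summarize_influx(fits, c(a1 = "g")),
               class = "ckflux_validation_error")
})

test_that("seeded noisy group medians land near the generating truth", {
  I_true <- 17.86e-3
  fits <- lapply(1:10, function(i) {
    a <- simulate_assay(kinetic_params(I_true, 4e-3, 0.02),
                        noisy_design(seed = 700 + i), paste0("r", i))
    fit_single_assay(a)
  })
  s <- summarize_influx(fits, stats::setNames(rep("tZ", 10),
                                              paste0("r", 1:10)))
  expect_lt(abs(s$median_I - I_true) / I_true, 0.10)
})
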