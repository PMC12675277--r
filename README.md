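# ckflux

Quantitative analysis of cytokinin membrane transport in plant cell
suspensions, built around radiotracer accumulation assays and the supporting
measurements of a typical transport study. The package is for experimentalists
who run uptake assays in BY-2-style suspension cultures (or re-analyse such
data) and need defensible rate constants, IC50s, shoot areas and expression
levels from them — with every estimator testable on synthetic data whose
ground truth is known.

## The models

**Accumulation kinetics.** The measured intracellular tracer concentration
follows a one-compartment exchange model with first-order influx *I* and
efflux *E* (s⁻¹), a surface-adsorption factor *K*, a volume-correction factor
*f* and initial extracellular concentration *c₀*:

```
c_I(t) = I·c0/(f·I + E) · [1 − exp(−t(fI+E))] · (1 − fK) + K·c0
```

A piecewise variant handles a mid-assay treatment at *t′* that changes the
influx constant to *I′*. Fits are bounded Levenberg–Marquardt least squares
(lower bounds 0, guesses I = E = 10⁻³, K = 0, tolerances 10⁻¹⁵), either per
assay or jointly across a dataset with *E* and *K* shared so that condition
effects load onto *I* alone.

**Dose–response.** Influx constants measured at increasing competitor
concentrations c_K are summarised by the saturation model
`I(c_K) = v_lim/(IC50 + c_K) + D`, with honest "no saturation observed"
reporting when the data cannot constrain a half-saturation point.

**Shoot areas.** Top-view RGB scans are segmented in CIELAB space
(a\* ≤ −9.5, b\* ≥ −9.5, L\* ≥ 18.5, size filters 2048/8192 px around a
disk-8 morphological closing) and per-object pixel areas are reported, with
mm² conversion at a known dpi.

**qPCR.** Relative expression against two reference genes,
`REL = 2^((CP_R1+CP_R2)/2 − CP)`, plus Kruskal–Wallis group comparisons with
the usual n.s./\*/\*\*/\*\*\* classes.

Each stage has a seeded generator (`simulate_assay()`,
`simulate_competition_experiment()`, `render_shoot_scene()`,
`simulate_qpcr_plate()`) that emits data together with a machine-readable
truth record.

## A worked example

Simulate a competition experiment on the standard competitor ladder
(0–20 µM), fit it with shared (E, K), and recover the IC50:

```r
library(ckflux)

truth <- saturation_params(v_lim = 1.8, IC50 = 112.21, D = 2e-3)
design <- simulation_design(c0 = 2, f = 0.05, noise_sd = 0, seed = NULL)
ds <- simulate_competition_experiment(truth, shared_E = 4e-3, shared_K = 0.02,
                                      design = design)

fit <- fit_dataset_shared(ds)
fit$shared
#>     E     K
#> 0.004 0.020

ladder <- attr(ds, "truth")$ladder
sat <- fit_saturation(dose_response_series(ladder, fit$params$I,
                                           tracer = "tZ", competitor = "tZ"))
sat
#> <saturation_fit> tZ vs tZ: v_lim = 1.8 nM/s, IC50 = 112.2 nM, D = 0.002 /s
```

The shared efflux constant and adsorption factor come back at their
generating values, and the fitted IC50 of 112.2 nM matches the truth the
ladder was simulated from: an uninhibited influx of ≈ 0.018 s⁻¹ that decays
hyperbolically with competitor concentration towards the residual
D = 0.002 s⁻¹. With 2% measurement noise the same pipeline recovers the IC50
to within a few percent (see the acceptance script below).

A thin command-line wrapper over the same functions is installed at
`inst/scripts/ckflux.R` (subcommands `simulate`, `fit`, `dose-response`,
`segment`, `rel`, `run`).

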