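---
title: "Quantifying cytokinin membrane transport with ckflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cytokinin membrane transport with ckflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckflux)
```

## The measurement and the model

Radiotracer accumulation assays follow the uptake of a labelled cytokinin by
suspension-cultured plant cells (typically tobacco BY-2): a tracer is added to
the medium at an initial extracellular concentration $c_0$ (nanomolar scale)
and the intracellular signal is sampled at regular intervals over 15–30
minutes. Two first-order rate constants summarise the exchange across the
plasma membrane — influx $I$ and efflux $E$ (both s$^{-1}$) — while a
dimensionless adsorption factor $K$ captures the fraction of signal that is
merely bound to cell surfaces and a volume-correction factor $f$ accounts for
the very different sizes of the intra- and extracellular compartments. The
measured intracellular concentration is

$$
c_I(t) = \frac{I\,c_0}{fI + E}\left[1 - e^{-t(fI+E)}\right](1 - fK) + K c_0 .
$$

The bracketed factor is the solution of the mass balance
$\mathrm{d}c/\mathrm{d}t = I(c_0 - fc) - Ec$ from $c(0)=0$; the $(1-fK)$
factor maps the dynamic pool to the measured signal and $Kc_0$ appears
instantaneously at $t = 0$. `eval_accumulation()` implements the closed form;
`integrate_uptake_ode()` is an independent fixed-step RK4 integration of the
same mass balance (step 0.01 s) kept in the package purely to validate the
closed form — the two routes agree below $10^{-11}$ nM over the physiological
parameter ranges, and the test suite asserts $10^{-8} c_0$.

When an inhibitor (for example the protonophore CCCP) is applied mid-assay at
time $t'$, the influx constant may change from $I$ to $I'$ while $E$ and $K$
are assumed unaffected. For $t > t'$ the internal pool relaxes from its value
at $t'$ towards the $I'$ steady state with rate $fI' + E$
(`eval_accumulation_treatment()`); the two branches are continuous at $t'$,
which the tests check explicitly along with convergence to the $I'$ steady
state.

Three modelling conventions are worth making explicit:

* **$f$ is a configuration constant, not a fitted parameter.** It describes
  the geometry of the suspension, not the biology of a tracer, so fitting it
  per assay would soak up variance that belongs to $I$. The synthetic default
  is 0.05.
* **Degenerate kinetics** ($fI + E = 0$) are evaluated as the analytic limit
  $Ic_0t(1-fK) + Kc_0$ rather than risking a division by zero.
* **Units are fixed** to seconds and nM; influx constants are conventionally
  reported on the $10^{-3}\,\mathrm{s}^{-1}$ scale.
* $fK < 1$ is enforced at validation so the measured dynamic fraction
  $(1-fK)$ stays positive.

## Fitting: per assay, jointly, and across a treatment

All fits are bounded nonlinear least squares via Levenberg–Marquardt
(`minpack.lm::nls.lm`) with lower bounds 0 on every parameter, initial
guesses $I = E = 10^{-3}$, $K = 0$, and function/step tolerances of
$10^{-15}$ (`solver_control()`). Function evaluations are capped at $10^5$
with a convergence flag rather than an exception, and any parameter that
finishes within $10^{-12}$ of a bound is listed in `bound_hits` so that
boundary solutions are never silent.

`fit_single_assay()` estimates $(I, E, K)$ from one curve.
`fit_dataset_shared()` stacks the residuals of every assay in a dataset into
one objective in which each assay keeps its own $I$ (and $c_0$) but a single
$(E, K)$ pair is shared — the constrained mode used when comparing influx
across conditions, so that condition effects load onto $I$ alone.
`fit_treatment_assay()` estimates $(I, I', E, K)$ of the piecewise model; with
no samples after $t'$ it falls back to the plain model with a warning.
`summarize_influx()` reports the median $I$ per condition group across
replicate assays (midpoint convention for even counts), which is the
customary summary because single-assay $I$ estimates are skewed and
occasionally hit the zero bound.

A flat trace (concentration constant at $Kc_0$) contains no flux information:
$I$ fits to zero, $K$ to the plateau, and $E$ is unidentifiable — the fit says
so in `notes` instead of returning a confident number. Residuals are
unweighted throughout; no error model for the scintillation counts is
assumed.

## Dose–response and IC50

Competition experiments repeat the assay with increasing concentrations
$c_K$ of an unlabelled competitor — the standard ladder is 0, 2, 20, 200,
2000, 20000 nM — and the fitted influx constants are summarised by the
saturation model

$$
I(c_K) = \frac{v_\mathrm{lim}}{\mathrm{IC}_{50} + c_K} + D ,
$$

with $v_\mathrm{lim}$ the saturable-transport scale (units
$\mathrm{nM\,s^{-1}}$ under this parameterisation), $\mathrm{IC}_{50}$ the
competitor concentration halving the saturable component, and $D$ the
non-saturable residual influx. The formula is implemented exactly as written;
note that with this form the saturable part of $I(0)$ is
$v_\mathrm{lim}/\mathrm{IC}_{50}$, and the half-way interpretation applies to
the saturable component relative to its uninhibited value.
`fit_saturation()` uses guesses of 1 for all three parameters, bounds 0, the
same tolerances. Two honest failure modes are detected rather than smoothed
over: a fitted $\mathrm{IC}_{50}$ diverging beyond $10^6\times$ the largest
tested concentration with an essentially flat curve, or a saturable scale
pinned at zero while the series trends upward, both reported as
`no_saturation` (a dose ladder that does not inhibit cannot constrain a
half-saturation point). `fold_change_matrix()` expresses treated/control
ratios of median influx (values below 1 = inhibition), leaving untested
tracer–competitor combinations `NA` rather than 0.

## Shoot segmentation

Top-view scans of isolated rosette shoots are segmented in CIELAB space
(sRGB input assumed, D65 illuminant, $L^*\in[0,100]$): keep pixels with
$a^* \le -9.5$ (green side), $b^* \ge -9.5$, $L^* \ge 18.5$; drop connected
components under 2048 px; morphologically close with a disk of radius 8 px;
drop components under 8192 px; label and measure areas
(`segment_shoots()`, `areas_report()` with px $\to$ mm$^2$ conversion at a
given dpi). Connectivity is faces-only (4-neighbour) by default and
configurable; labelling delegates to `EBImage::bwlabel`, the closing to
`EBImage::closing` with a disk brush. `estimate_thresholds()` offers
multi-Otsu class boundaries (3 classes per channel by default, exhaustive
between-class-variance search over a 256-bin histogram) as advisory starting
points for new imaging setups; the pipeline itself always runs the fixed
thresholds above. Whole images are processed in memory; scans larger than
memory are out of scope.

## qPCR relative expression and group comparisons

Relative expression against two reference genes assumes amplification
efficiency 2:

$$
\mathrm{REL} = \frac{2^{(CP_{R1}+CP_{R2})/2}}{2^{CP}}
             = 2^{(CP_{R1}+CP_{R2})/2 - CP},
$$

i.e. the geometric mean of the reference signals over the target — the only
reading of a two-reference normalisation in which swapping the references is
a no-op and one extra target cycle halves REL; both identities are tested.
Group differences use the Kruskal–Wallis rank test
(`stats::kruskal.test`) with the reporting classes n.s. ($P \ge 0.05$), \*
($P<0.05$), \*\* ($P<0.01$), \*\*\* ($P<0.001$); p-values are
per-comparison, with no multiplicity correction, matching how such panels
are conventionally annotated.

## What the synthetic data emulate — and what they do not

Every stage has a seeded generator that emits data plus a machine-readable
truth record, so recovery is always judged against the generating truth and
never against hard-coded numbers:

* `simulate_assay()` samples the (piecewise) accumulation model on 12 regular
  points over 0–900 s with $c_0 = 2$ nM, $f = 0.05$, and additive Gaussian
  noise of sd 2% of $c_0$ clipped at zero (no noise model is dictated by the
  assay itself; 2% is a realistic scintillation-scale placeholder and is
  configurable). Clipping rather than resampling leaves a sub-standard-error
  positive bias only where the curve sits within one sd of zero (the $t=0$
  point at small $K$), quantified in the tests.
* `simulate_competition_experiment()` drives the true influx of each ladder
  assay through the saturation model with shared $(E, K)$, the scenario the
  constrained fit plus `fit_saturation()` must invert. Default truths use
  realistic magnitudes ($I \approx 17.86\times10^{-3}\,\mathrm{s^{-1}}$ for a
  trans-zeatin-like tracer, $\mathrm{IC}_{50} = 112.21$ nM).
* `render_shoot_scene()` paints solid green disks (default sRGB (0.20, 0.60,
  0.20), approximately $L^* 56$, $a^* -50$, $b^* 44$ — comfortably inside the
  thresholds) on near-white, plus sub-2048-px distractors; areas are exact
  rasterised pixel counts and overlapping blobs merge in the truth.
* `simulate_qpcr_plate()` places both references at a common crossing point
  and the target $\log_2(\mathrm{REL})$ cycles away, with optional cycle
  noise.

Passing these tests shows the estimators invert their own generating models
at the stated noise level. It does not certify behaviour on real data, whose
curves carry tracer metabolisation, pipetting error and non-Gaussian counting
noise; whose rosettes are concave, serrated and shadowed rather than solid
disks; and whose qPCR efficiencies differ from 2. Those effects are exactly
why the honest-failure paths (convergence flags, bound hits, no-saturation,
unidentifiability notes) exist.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run deliberately modest problem
sizes — 100 random parameter sets for the closed-form/RK4 cross-check, 8–10
assays per recovery experiment, 512×512 scenes, 12-sample plates — chosen as
the smallest designs at which the error budgets (median relative error of
recovered $I$ under 10%, shared $E$ under 15%, noiseless recovery to
$10^{-6}$, IC50 to $10^{-3}$ noiseless / 20% at 2% noise, exact segmentation
areas) are meaningful. Seeds are explicit everywhere; every generator is
bit-reproducible given its seed. Ties in medians use the midpoint; CSV output
is full-precision so identical configuration plus seed reproduces
byte-identical tables.

## Known limitations

No confidence intervals (point estimates and medians only), no model
selection between the plain and treatment kinetics (the caller chooses by
supplying $t'$), no competitive-inhibition $K_i$ or Hill extensions of the
saturation model, no amplification-efficiency correction, no per-leaf
instance separation in segmentation, and no modelling of tracer metabolic
conversion — the influx constant $I$ approximates initial-rate kinetics
precisely to limit sensitivity to downstream metabolism.
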