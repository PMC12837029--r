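---
title: "Sampling designs and multivariate calibration: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling designs and multivariate calibration: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speccal)
```

# The problem

Two co-administered β-lactam antibiotics with strongly overlapping UV
absorption bands cannot be quantified at a single wavelength: within the
200–335 nm working window both analytes absorb nearly everywhere, so any
univariate calibration is confounded. The standard chemometric answer is
full-spectrum multivariate calibration: record each mixture's spectrum on a
fine wavelength grid, and regress the concentration vector on the whole
spectrum. `speccal` implements that workflow end to end — mixture design,
spectral simulation, model fitting, wavelength selection, and a validation
battery — with an emphasis on *how the calibration and validation mixtures
are placed in concentration space*, because the quality of a multivariate
model is bounded by how representative its design is.

# Mixture designs

A `design_space()` is a hyper-rectangle of analyte concentrations (default
10–30 µg/mL per analyte). Four samplers place points in it:

* **Full factorial** (`factorial_calibration_design()`): equally spaced coded
  levels (default −2…2) mapped affinely onto the bounds, −2 → lower and
  +2 → upper. Five levels in two variables give the classical 25-mixture
  calibration set.
* **Monte Carlo** (`monte_carlo_design()`): `x = x_min + r (x_max − x_min)`,
  `r ~ U[0,1)` i.i.d. Simple, but prone to clustering and gaps at small n.
* **Latin hypercube** (`latin_hypercube_design()`): each variable's range is
  split into n equal strata; `x = x_min + ((k − r)/n)(x_max − x_min)` with a
  fresh `r` per stratum and the stratum order `k` permuted independently per
  variable. Every margin is covered exactly once per stratum.
* **Sobol sequence** (`sobol_design()`): deterministic low-discrepancy points
  generated by XOR of direction numbers in Gray-code order. The direction
  numbers are the standard primitive-polynomial initialisations for up to 10
  dimensions at 30-bit resolution; the generator was cross-checked against an
  independent quasi–Monte Carlo implementation and is tested through the
  dyadic balance property (any `2^m` consecutive points fill every dyadic
  interval of width `2^-m` exactly once per coordinate). Index 0 is the
  origin — an all-lower-bound "blank" mixture — and is skipped by default
  (`skip_zero = TRUE`); a seeded digital scramble is available but off by
  default because the plain deterministic sequence is the documented method.

Space-filling quality is quantified in the *coded* unit hypercube (so the
metrics are unit-free) by the minimum pairwise Euclidean distance and by grid
coverage — the percentage of occupied cells of a regular grid, 10 cells per
dimension by default. A 100-cell grid is the only resolution at which 13
points can produce the ~12–13 % coverage figures typically quoted for
13-mixture validation sets, which is why 10 is the default; it is a
parameter, not a constant. Points on the upper boundary belong to the last
cell. Realized values of both metrics are seed-dependent for MC and LHS, so
the package asserts only the *mean-over-seeds ordering* (structured samplers
≥ MC), never specific published realizations.

# Spectral simulation

Each pure component is a sum of Gaussian bands (center, width σ, peak
absorptivity per µg/mL). The defaults emulate the qualitative structure of
the two-analyte case: component A dominant at 200–250 nm (220 nm, σ 12)
with a broad shoulder to ~340 nm (290 nm, σ 30); component B with its main
broad band at 260–330 nm (298 nm, σ 20) and a secondary short-wavelength
band (215 nm, σ 15). Amplitudes were fixed once so that (a) 10–30 µg/mL
mixtures span roughly 0.1–1.2 AU and (b) the two pure spectra are
*positively* correlated on the working window (r ≈ 0.30). The correlation
constraint matters: weaker shoulder amplitudes yield anticorrelated spectra,
which would make the simulated problem easier than the real one (a
univariate trick would almost work); the chosen amplitudes preserve the
collinearity that motivates multivariate resolution. These are synthetic
stand-ins for unpublished experimental spectra, not fitted values.

Mixing is Beer–Lambert: `A(λ) = Σ_k c_k ε_k(λ)`, exactly additive at zero
noise (a tested invariant). The noise model adds, per spectrum, i.i.d.
additive noise (default SD 0.003 AU), signal-proportional noise (0.5 %), and
a baseline offset (SD 0.002 AU); a baseline tilt is available but defaults
to zero. All draws are seeded and reproducible.

The default grid is 200–400 nm at 0.2 nm: a 0.2 nm export spacing is the
only step for which the 200.0–335.0 nm working window holds exactly 676
points, even though instruments often scan at 0.1 nm; both grids are
supported (`default_grid(step = 0.1)`), and trimming is inclusive on both
ends. `bin_spectra()` averages non-overlapping windows (new step must be an
integer multiple; a trailing incomplete window is dropped with a warning),
and `snr_profile()` estimates SNR as |window mean| / SD of residuals from a
local linear detrend, flagging wavelengths where the residual SD is below
machine tolerance — the estimator is a package choice, since published SNR
numbers rarely define theirs.

# Calibration engines

**PLS** is NIPALS with per-component deflation (PLS2 for the two-analyte
response), on mean-centered X and Y. The latent-variable count is chosen by
leave-one-out cross-validation; the default pick is the *one-standard-error
rule* (smallest k whose RMSECV is within one SE of the curve minimum), with
the plain minimiser behind `rule = "min"`. When the data rank is below the
requested maximum, the RMSECV curve simply ends at the attainable count;
`fit_pls()` itself treats rank deficiency as an error. At full rank the fit
equals ordinary least squares (tested), and scores are mutually orthogonal
to 1e−8.

**ANN** is a single-hidden-layer network `ŷ = f(W₂ g(W₁x + b₁) + b₂)` with 6
hidden neurons, identity ("purelin") transfers on both layers by default and
`tanh` optionally. Note that a purelin–purelin network is an affine map — it
cannot represent nonlinearities, whatever the surrounding folklore says — so
on linear noiseless data it must converge to the least-squares solution,
which is exactly the tested linear-limit property. Training is
Levenberg–Marquardt on the MSE: `w ← w − (JᵀJ + µI)⁻¹Jᵀe`, with µ starting
at 1e−3, ×10 on a rejected step (training MSE not reduced), ÷10 on
acceptance; when the parameter count exceeds the residual count the
algebraically identical form `Jᵀ(JJᵀ + µI)⁻¹e` is solved instead (a 50×50
system rather than 4000×4000 for 676-wavelength inputs). Early stopping
holds out a random 10 % of samples and stops after 6 epochs without
validation improvement, keeping the best-validation weights; split fraction
and patience are package defaults (published descriptions rarely state
them) and are recorded in the training record along with per-epoch
train/validation MSE. Inputs and outputs are centered and scaled to unit SD
per column; all scaling is stored in the model. Weight initialisation is
small seeded uniform noise; a fixed seed reproduces weights and training
record bit-for-bit.

# Wavelength selection

`ga_select()` runs a binary-coded GA over wavelength masks: tournament
selection (size 2), uniform crossover, per-bit mutation (default 1 %),
elitism 1, defaults of 30 chromosomes × 50 generations. Chromosomes with
fewer than `min_selected` (default 5) bits are repaired by switching random
bits on. Fitness (minimised) is either

* `cv_rmse`: k-fold cross-validated RMSE of a PLS fit on the selected
  columns (conventional GA-PLS), or
* `icomp`: the information-complexity score of the fit,
  `ICOMP = −2 log L + 2 C(Σ)` with `−2 log L = n ln(2πσ̂²) + n`
  (σ̂² = RSS/n, Gaussian ML) and Bozdogan's
  `C(Σ) = ½[(tr Σ)² − tr(Σ²)]` on the residual covariance across the two
  responses. `tr(Σ)²` is read as `(tr Σ)²`; the alternative reading makes
  the penalty identically zero. For a single response the trace penalty
  vanishes, so `icomp_score(..., c1 = TRUE)` offers the C1 eigenvalue form.
  With two responses the likelihood term uses the stacked residual vector.
  A perfect fit (RSS = 0) returns −Inf with a warning rather than an error:
  it is a legitimate degenerate minimum.

Per chromosome the LV count comes from LOO CV capped at `lv_cap` (default
5); `lv_rule = "fixed"` skips the inner LOO for speed — useful in multi-seed
simulation studies, and consistent with the observation that the optimal LV
count stays at 3 across selections. Fitness values are memoized by
chromosome, the best-ever chromosome is returned (so the best-fitness trace
is non-increasing by construction), and `compare_selection()` benchmarks
full-spectrum PLS against any set of GA configurations on *identical* CV
folds (the fold assignment hash is recorded).

# Validation battery

All error metrics use the `n`-denominator RMSE so RMSEC/RMSECV/RMSEP share
one formula; this is also the convention under which the published
comparison statistics recompute exactly from printed SDs. Recovery is
`100·ŷ/y` per sample; %RSD is `100·SD/mean` of recoveries; `R² = r²` of the
predicted-vs-actual line.

* `nested_cv()`: outer k-fold (default 5) with *all* tuning delegated to the
  model factory, which only ever receives outer-training rows (the per-fold
  row indices are recorded so leakage is auditable); pooled outer residuals
  feed a seeded percentile bootstrap (default 1000 resamples) for the 95 %
  CI.
* `y_randomization()`: refits on permuted responses (identity permutation
  excluded). The correlation is computed from cross-validated predictions
  under the identical fold protocol for original and permuted fits — with
  hundreds of wavelengths and ~25 samples, *training* correlations stay
  near 1 even for permuted responses, so only predictive r can make the
  "permuted r < 0.5" criterion meaningful. Verdict: original r above every
  permuted r and mean permuted r < 0.5.
* `applicability_domain()`: Williams-plot table with leverage
  `h_i = t_iᵀ(TᵀT)⁻¹t_i + 1/n` in latent-score space, critical leverage
  `h* = 3(p+1)/n` (p = number of LVs; the formula is the usual QSAR
  convention, fixed here because published text typically says only that h*
  "was calculated"), standardized residuals relative to the assessed set's
  residual SD, and the in-domain rule |std res| < 3 ∧ h < h*.
* `pooled_t_test()` / `variance_ratio_f()`: summary-statistic two-sample
  comparisons with explicit conventions. The F ratio takes a caller-chosen
  numerator because published tables are not always consistent about which
  variance goes on top (the bundled acceptance test documents one such
  inconsistency); critical values are two-tailed 0.05 for t, one-tailed 0.05
  for F.
* `friedman_test()`: tie-corrected rank χ² with average ranks,
  `df = k − 1`; validated against `stats::friedman.test`.

# The workflow

`run_experiment()` chains everything from one `experiment_config()`: 25-mixture
factorial calibration, 13-mixture validation sets from each of MC/LHS/Sobol
(the 25:13 ≈ 2:1 calibration-to-validation ratio), simulation, model fitting
(PLS, GA-PLS, ANN), a (sampler × model × analyte) table of RMSEP/R²/%RSD,
per-sampler uniformity reports, and a Friedman test across samplers using the
per-(model, analyte) RMSEP values as matched blocks. Every stage seed is
derived from the master seed by hashing (seed, stage label), so stages are
decoupled and the whole run — including written CSV/JSON artifacts and their
md5 manifest — is byte-reproducible from one integer. GA selection inside
the workflow runs on 1-nm binned spectra by default (`bin_step = 1`):
binning to 0.5–1 nm is known not to change model performance on this kind of
data, and it bounds GA cost; `bin_step = NULL` uses the full grid.

# Greenness

`greenness_index()` is the weighted mean (equal weights by default) of five
1–10 SDS-derived criterion scores divided by 10, so the attainable range is
[0.1, 1]; an optional min-max rescale maps it to [0, 1]. The aggregation is
deliberately simple and monotone (raising any score never lowers the index —
a tested invariant). Whole-method scores from external published tools
(AGREE, BAGI) are recorded verbatim in the report, never recomputed. The
bundled solvent table is an illustrative synthetic fixture; per-solvent
published scores were not available.

# What the synthetic generator does and does not establish

The simulator reproduces: Beer–Lambert additive mixing of two overlapping
absorbers, realistic absorbance ranges, additive + proportional noise and
baseline wander, and design-driven concentration structure. It does not
model instrument slit functions, stray light, scan-speed artifacts, matrix
effects of real dosage forms, or any true spectral nonlinearity — so a green
parameter-recovery test establishes that the estimators are correct and
well-conditioned *under the stated noise model*, not that any instrument
will achieve those error levels. Published prediction errors measured on
real spectra are therefore never asserted; only arithmetic that is fully
derivable from printed tables is reproduced exactly, and everything else is
tested as seeded statistical properties (orderings, intervals, sign tests)
on the synthetic world.

# Numerical choices and degenerate inputs

* NIPALS stops a component when the weight norm falls below a relative
  1e−12 threshold; requesting more components than the data rank is an
  error in `fit_pls()` and a truncated curve in `select_lv_loocv()`.
* LM damping escalates ×10 up to 1e12 before giving up an epoch; singular
  damped normal equations are retried at higher µ.
* Grid coverage places upper-boundary points in the last cell; coincident
  points occupy one cell.
* `icomp_score` requires symmetric Σ (1e−8 relative tolerance) and n ≥ 2.
* Zero-variance targets train to a constant network; constant responses make
  correlation-based tests error out explicitly rather than return NaN.
* All seeds are 31-bit; library functions never disturb the caller's RNG
  state (`with_seed` restores `.Random.seed`).

# Known limitations

* Sobol direction numbers cover 10 dimensions — ample for mixture design,
  not for high-dimensional screening.
* The GA is a plain generational binary GA; no interval selection, PSO, or
  hybrid operators.
* `nested_cv` expects factories that encapsulate their own tuning; it does
  not orchestrate inner folds itself.
* The CLI uses JSON (not YAML) for configs and sidecars, reflecting the
  offline dependency set.
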