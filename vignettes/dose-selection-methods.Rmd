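---
title: "Methods: subpharmacological dose selection for PK studies in hemodialysis patients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subpharmacological dose selection for PK studies in hemodialysis patients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdpkdose)
```

## Scope and rationale

`hdpkdose` plans PK studies in intermittently hemodialyzed, anuric
patients for drugs whose active moiety is renally excreted and therefore
accumulates in end-stage renal disease. The package's premise is that a
subpharmacological dose — low enough to be safe, high enough to be
quantifiable — carries all the information needed to pick the dose for a
full PK study, *provided* the kinetics are dose-linear over the range of
interest. The workflow is therefore: establish linearity (Step 1), measure
the low dose and extrapolate (Step 2), validate (Step 3).

All times are hours since dosing, with the dose given immediately after a
dialysis session and the next session at 44–48 hr, so the printed clock of
the motivating design is preserved throughout. Doses are mg and
concentrations ng/mL; the mg→ng factor of 10^6 is applied only inside
clearance computations (CL/F in L/hr, CL_HD in mL/hr), never stored in
data.

## Non-compartmental analysis

AUC_last uses the linear trapezoid over the quantifiable samples, with
linear interpolation at non-sampled window boundaries; this makes AUC
exactly additive over adjacent windows and exactly homogeneous in the
concentrations, two properties the test suite checks. The partial AUC over
the dialysis session (AUC_HD) is the same trapezoid restricted to the
session window. Cmax/Tmax are read directly off the observed samples with
ties broken by the earliest time.

**BLOQ rule.** Assay limits (defaults 0.2 ng/mL parent, 2 ng/mL
metabolite) censor the data. The package zeroes below-limit records before
the first quantifiable sample (the pre-absorption phase) and excludes
embedded and trailing ones, so AUC_last ends at the last quantifiable
time. This is the dominant NCA convention, declared here as a package
choice: nothing in the motivating design prescribes one, and other rules
(e.g. LLOQ/2 imputation) are defensible. The rule is idempotent, and an
all-BLOQ profile is flagged unusable rather than silently dropped.

**Terminal slope.** The terminal rate constant λz is estimated by
log-linear least squares over every suffix of at least three positive
quantifiable points ending at the last one and excluding Tmax; candidates
with non-negative slope are discarded and the largest adjusted R² wins,
ties (within 10^-4) going to the longer window. This mirrors the default
of the commercial NCA tools practitioners use. λz exists in this package
solely to extend profiles for superposition — the workflow never reports a
half-life as an endpoint — and on exactly mono-exponential data the true
rate is recovered to machine precision.

**Dialytic clearance** uses the recovery method: CL_HD = R/AUC_HD with
R the trapezoidal integral of dialysate concentration × dialysate flow
(default 500 mL/min) over the session. On dense noiseless simulator output
this estimator recovers the programmed dialytic clearance to 0.1%, which
is the cross-check the suite runs.

## Dose-proportionality gate

The gate fits the power model ln(y) = α + β·ln(D) by OLS to per-subject
parameter values pooled across the escalation periods, and accepts
proportionality when the 95% CI (β ± t₀.₉₇₅,ₙ₋₂·se) contains 1.0 for
every parameter. Two declared choices:

* the interval is **closed** — a CI touching 1.0 exactly still passes
  (the permissive reading of "included 1.0");
* period and subject effects are **not** modeled. The pilot is a
  within-subject escalation (4 subjects × 3 doses = 12 observations), and
  plain log-log regression is the method stated for the motivating design.
  A mixed-effects dose-proportionality analysis is out of scope and noted
  as a limitation.

Kruskal–Wallis on the dose-normalized Cmax and AUC_last (tie-corrected H,
chi-squared p on k−1 df) accompanies the gate as a distribution-free
cross-check; with n = 4 per dose its power is minimal, which is precisely
why the CI gate, not the p-value, decides.

Because a 4-subject pilot can fail the gate by chance even under perfectly
linear kinetics, the pipeline exposes `force_gate = TRUE` to proceed with
a warning; the default is to halt at Step 1 with the full report.

The CI's operating characteristics are simulated at the exposure level:
under linear kinetics with log-normal inter-individual variability,
subject exposure is exactly (dose-proportional constant) × (log-normal
deviate), so `simulate_beta_coverage()` draws exposures directly from that
model rather than re-integrating ODEs 24,000 times. The acceptance suite
checks ~95% coverage over 2,000 replicates of the 12-observation design.

## Nonparametric superposition

The predicted concentration under a regimen of doses D_k at times t_k is

C_pred(t) = Σ_k (D_k / D_ref) · C_ref(t − t_k),

with C_ref the reference (low-dose) profile: linearly interpolated within
the observed range, extended beyond the last sample as
C(t_last)·exp(−λz·(t−t_last)), and zero before dosing. No structural model
is assumed; the method stands or falls with dose-linearity, which is what
Step 1 certifies. Numerical choices:

* evaluation uses a dense 0.1-hr grid augmented with every reference
  sample time shifted to every dose event, so the piecewise-linear
  segments are represented exactly and the single-dose superposition at
  the reference dose reproduces the reference profile to machine
  precision;
* AUC of a superposed profile is the trapezoid on that grid, which bounds
  the discretization error well below reporting precision (the suite
  checks multi-dose predictions against independent brute-force summation
  at 10^-9 relative).

The default regimen template is a single dose observed over 0–72 hr with
the 44–48 hr dialysis session embedded in the reference profile. This
encodes an assumption worth stating plainly: every simulated dosing cycle
repeats the same dialysis schedule the reference was measured under. The
terminal extension likewise uses a λz fitted across the dialysis dip, a
deliberate simplification (post-dialysis rebound was not characterized in
the motivating data); for the default single-dose template over 0–72 hr
the extension is never actually evaluated, so the choice only matters for
multi-dose templates.

The dose–exposure curve is built **per subject** and averaged across
subjects at each grid dose (the grid default is 2.5–150 mg in 2.5-mg
steps); the reported curve carries the between-subject standard error.
Inversion at the target AUC is monotone linear interpolation, exact in the
linear single-dose case where D* = D_ref·target/AUC_ref. The exact dose is
rounded **up** to the practical increment (default 5 mg) — never down,
since the target exposure is a floor, not a ceiling, for study
detectability.

## Validation metrics

Predictions are paired with observations at the observed quantifiable
times, per subject and per analyte/matrix series, then pooled. Reported
metrics: MAPE, average fold error AFE = 10^mean(|log10(pred/obs)|) (≥ 1 by
construction, symmetric in over/under-prediction), and the fraction of
points within 2-fold (boundary inclusive). The automated pass/fail
conventions — AFE ≤ 1.3 and ≥ 80% within 2-fold — are package
declarations chosen to operationalize "close visual agreement"; they are
deliberately looser than assay precision and tighter than the 2-fold
standard used for population-PK external validation.

## The synthetic study generator

`simulate_study()` emulates the motivating design: single oral dose after
dialysis, sampling at 0, 1, 1.5, 2, 2.5, 3, 6, 12, 24, 44, 48, 72 hr,
hourly dialysate collection during the 44–48 hr session, LLOQs 0.2 and
2 ng/mL. The structural model is a linear three-state cascade:

* gut: dA_g/dt = −ka·A_g, initialized at F·D;
* parent: dA_p/dt = ka·A_g − (CL_p/V_p)·A_p, a fraction fm of parent
  elimination appearing as metabolite;
* metabolite: dA_m/dt = fm·(CL_p/V_p)·A_p − (CL_m(t)/V_m)·A_m with
  CL_m(t) = CL_m,inter + CL_HD·1{t ∈ dialysis window};
* dialysate concentration CL_HD·C_m/Q_d during the session.

Integration is piecewise `deSolve::lsoda` (rtol 10^-9) with segment breaks
at the session boundaries, so the clearance discontinuity never sits
inside an integrator step; cumulative dialysate recovery, interdialytic
elimination and non-metabolite parent loss are co-integrated so the suite
can close mass balance to 10^-6. The linear no-dialysis case is checked
against the closed-form three-exponential cascade solution, an oracle
independent of the integrator.

Typical values (ka 1.5/hr, V_p 620 L, CL_p 620 L/hr, fm 0.8, V_m 14 L,
CL_m,inter 0.18 L/hr, CL_HD 3 L/hr) were fixed once so that a 2.5-mg dose
gives a metabolite AUC_last near 5,600 ng·hr/mL and Cmax near 130 ng/mL,
the parent is quantifiable only for the first few hours, and CL/F lands in
the several-hundred-L/hr range — tuning targets that make the synthetic
study resemble the motivating low-dose summaries, not claims of
mechanistic fidelity. Between-subject variability is log-normal (default
CV 30% on ka, CL_p, V_p, V_m, CL_m,inter, CL_HD) and residual error is
proportional log-normal (default CV 15%).

What the generator does **not** emulate, hence what green tests do not
establish about real data:

* metabolite Tmax. One-compartment disposition with fast conversion peaks
  the metabolite around 6 hr; observed hemodialysis-patient data peak much
  later (24–44 hr), implying distribution kinetics the generator omits.
  Superposition itself is agnostic to the shape, so this mainly limits
  realism of early-curve validation metrics;
* post-dialysis rebound (no peripheral compartment by default);
* the published dialytic-clearance magnitude. The motivating summary
  tables print CL_HD of a few mL/hr, which is mutually inconsistent with
  dialysate concentrations being quantifiable at a 2 ng/mL LLOQ (it would
  put them two orders of magnitude below the limit). The generator uses
  CL_HD = 3 L/hr so that dialysate profiles are measurable and the
  recovery method is exercisable end to end; it makes no attempt to
  reproduce that printed value;
* nonlinearity, except through `saturable_variant()`, which replaces the
  parent clearance with Michaelis–Menten elimination (Vmax = CL_p·km, so
  km → ∞ recovers linearity) to exercise the gate's failure mode.

## Problem sizes

The test and acceptance runs use the study sizes of the motivating design:
a 4-subject pilot at 2.5/5/10 mg (crossover), a 10-subject low-dose study
at 2.5 mg, and a 10-subject validation occasion at the recommended
practical dose simulated as a second crossover period of the same
subjects. CI coverage uses 2,000 replicates; ground-truth AUCs use a
0.01-hr integration grid; dense NCA-vs-truth checks use 0.1-hr sampling.
With those sizes the whole suite runs in well under a minute.

## Known limitations

* The power model ignores the crossover structure (no subject/period
  effects); with n = 12 observations the CI is wide, and the gate is
  correspondingly permissive.
* The exact regimen behind a "continuous dosing" extrapolation is a
  configuration choice (`regimen()`); the package defaults to the
  single-dose template and makes no claim that any particular multi-dose
  template reproduces external recommendations.
* The validation thresholds are conventions; a regulatory-grade
  equivalence claim would need pre-specified acceptance ranges and a
  powered design.
* Extrapolation beyond the dose range certified by Step 1 (here 4× the
  top pilot dose) rests entirely on the linearity assumption; the
  saturable variant shows how badly that can fail when it is false, which
  is exactly why the gate exists.
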