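---
title: "Modeling CYP induction drug-drug interactions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling CYP induction drug-drug interactions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypind)
```

## The problem

Enzyme inducers such as rifampicin accelerate the metabolism of
co-administered drugs, sometimes to the point of therapeutic failure. For
CYP3A4 this risk is routinely quantified before clinical studies: in vitro
fold-induction data are translated through the ICH M12 basic static model.
For the CYP2C family the same translation has historically failed, for two
reasons. First, conventional hepatocyte monocultures show little or no
CYP2C induction (fold changes below the regulatory 2-fold threshold), so
parameters cannot be estimated; all-human triculture (HTC) hepatocyte
systems recover a usable dynamic range. Second, no clinical CYP2C substrate
is metabolized by a single enzyme, so a one-enzyme static calculation
misattributes clearance. `cypind` implements the resulting workflow as an
open, testable pipeline:

1. fit sigmoidal Emax/EC50 induction curves to HTC fold-change data, with
   the <2-fold no-call rule (`fit_induction()`);
2. evaluate the basic static model R3 with fraction-metabolized (fm)
   weighting across enzymes (`r3()`, `net_auc_ratio()`, `msm()`);
3. simulate the interaction dynamically with an enzyme-turnover model
   driven by multiple-dose perpetrator pharmacokinetics (`run_ddi()`);
4. compare both predictions, and optional clinical observations, against
   the 0.8-1.25 bioequivalence and 0.5-2.0 no-DDI bands
   (`build_comparison()`, `classify_band()`).

## Concentration-response model

Fold induction relative to vehicle is fitted as a three-parameter sigmoid
anchored at baseline 1. The printed GraphPad-style form is a logistic in
`X`; a fold-change curve must satisfy `Y(0) = 1`, which forces `X` to be
log-concentration and a fixed bottom of 1, so the default form is

\[
Y = 1 + \frac{E_{max} - 1}{1 + \exp(-(\log_{10} C - \log_{10} EC_{50})/s)},
\]

with the equivalent Hill form `Y = 1 + (Emax-1) C^h / (EC50^h + C^h)`
(`h = 1/(s \ln 10)`) available via `form = "hill"`. Nominal medium
concentrations are used throughout: the assay medium is albumin-free and
compound loss over the dosing interval is within analytical error (the
`stability_metrics()` helper quantifies that loss from measured
concentrations via the linear trapezoid).

Decisions where practice varies:

* **No-call first.** If the maximum mean fold change is below 2 (strict
  inequality) no parameters are estimated; `nc = TRUE` is a first-class
  result that propagates through the static model (a no-call enzyme is
  *refused*, not silently set to R3 = 1).
* **Weighting.** Quadruplicate SDs are too noisy to use point-wise as
  `1/SD^2` weights; because fold-change noise is multiplicative, the
  replicate scatter is pooled into a single relative SD and means are
  weighted `1/(\text{pooled CV} \times \text{mean})^2`. With no replicate
  scatter the fit is unweighted. This choice measurably tightens the tails
  of the EC50 recovery distribution (see the test suite's operating
  characteristics).
* **Bounds and starts.** `Emax` starts at the maximum mean fold and is
  bounded above by twice that value (an estimated plateau should never be
  far above what was observed); `EC50` starts at the concentration nearest
  half-maximal response and is bounded within `[min conc/10, max conc x 10]`
  -- a fit landing on those bounds is reported non-converged; the Hill
  exponent is bounded in `[0.3, 5]`. Optimization is Levenberg-Marquardt
  (`minpack.lm::nlsLM`). Duplicate concentrations are averaged before
  fitting.

Precision is limited by the assay design itself: with quadruplicates at
10% CV on an 8-point dilution series, the recovery harness in the test
suite shows a median relative EC50 error of roughly 10%, with ~94% of
estimates within +/-30% of truth. Expecting substantially better than that
from such data would be optimistic regardless of estimator.

## Static model

Per enzyme, `R3 = 1/(1 + d (Emax - 1) I/(EC50 + I))` with `d = 1` and
`I = 10 x Imax,u` by default; the 10x correction was calibrated for CYP3A4
mRNA data and is applied to all enzymes unless a named per-enzyme
`multiplier` vector is supplied. The fitted `Emax` here is total fold
(baseline 1), hence the amplitude `Emax - 1`; `emax_convention =
"fold_minus_one"` accepts guidance-style amplitudes directly. Victim
exposure combines enzymes through the net-effect clearance sum

\[
AUCR = \frac{1}{\sum_i fm_i \cdot FC_i + (1 - \sum_i fm_i)},
\qquad FC_i = 1/R3_i ,
\]

so unlisted clearance is uninduced. `msm()` evaluates this per hepatocyte
donor and reports the mean and range; `Imax,u` is never hard-coded -- it is
an explicit argument defaulting to the packaged, cited fixture value.

## Dynamic model

The simulator is a deliberately minimal, calibrated backbone rather than a
full physiological model:

* **Perpetrator:** linear one-compartment first-order oral kinetics.
  Multiple-dose profiles are exact Bateman superpositions (no integrator).
  The induction driver is the unbound hepatic-inlet concentration
  (systemic plus `ka x gut amount / Q_h`), switchable to unbound systemic.
* **Enzymes:** turnover `dE/dt = kdeg [1 + (Emax-1) Cu/(EC50 + Cu)] - kdeg E`
  per enzyme, baseline 1. The stimulation is hyperbolic (slope 1): fitted
  Hill slopes are deliberately not propagated, matching standard induction
  modeling. Induction parameters default to the geometric mean over
  non-no-call donors of the mRNA readout (mRNA has full donor coverage;
  activity data leave many cells no-call); per-donor runs give the
  donor-range spread.
* **Victim:** single oral dose, one compartment, all clearance hepatic and
  partitioned by fm: `CLint(t) = CLint0 [sum_i fm_i E_i(t) + (1 - sum fm)]`
  in a well-stirred liver, with hepatic first pass applied to the absorbed
  dose, so for constant enzymes `AUC_po = Fa Fg D/(fu CLint)` holds
  exactly. Baseline `CLint0` is derived from the cited systemic clearance.
* **Gut CYP3A4:** for substrates with CYP3A4-mediated intestinal first
  pass (midazolam, alfentanil, atorvastatin, glyburide, repaglinide) an
  enterocyte enzyme pool with its own faster `kdeg` is driven by the
  absorption-phase surrogate `ka x gut amount / Q_gut`, and
  `Fg(t) = 1/(1 + (1/Fg0 - 1) E_g(t))`. Without this pool, >90% reductions
  of midazolam exposure are unreachable with hepatic induction alone.
* **Outcome:** the victim arm is integrated twice (enzymes at baseline vs
  induced) with `deSolve::lsoda` at `rtol 1e-8 / atol 1e-10`; AUC to
  infinity is trapezoid plus `C_last/k_el` terminal extrapolation, with a
  warning above 20% extrapolated fraction and a refusal to extrapolate
  when no reliable terminal slope exists. The victim dose cancels from the
  ratio (linear PK).

Parameters that matter, with defaults:

| parameter | default | units | rationale |
|---|---|---|---|
| `q_h` | 90 | L/h | hepatic blood flow, ~1.5 L/min adult |
| `q_gut` | 18 | L/h | villous blood flow of minimal gut models |
| `kdeg` CYP3A4 / 2C8 / 2C9 / 2C19 / 2B6 | 0.0193 / 0.030 / 0.0067 / 0.026 / 0.022 | 1/h | enzyme-turnover literature; sets induction onset/offset |
| `kdeg` gut CYP3A4 | 0.030 | 1/h | faster enterocyte turnover |
| grid step | 0.05 | h | resolves absorption; enzyme stepping error is O(h^2) |
| victim window | 96 | h | >5 half-lives for every packaged victim |

All are editable arguments, not constants. Compound fixtures (PK, `fu`,
`Fg0`, fm maps) carry literature citations in the registry
(`registry_dump()`); they stand in for proprietary simulator compound
files and were chosen once from the primary clinical-PK literature, with
the perpetrator profile checked against observed steady-state exposure
(the packaged rifampicin fixture reproduces its literature AUC within the
0.8-1.25 band -- asserted in the test suite). Regimen timing follows the
clinical designs: "victim after perpetrator on day N" is represented as
1 h after that day's dose; the glyburide/repaglinide designs dose the
victim 12.5 h after the final perpetrator dose; bupropion is dosed on the
morning of day 8 of evening perpetrator dosing. Warfarin's weight-based
design assumes a 70 kg subject and its compound model ships as
experimental (enantiomer kinetics are not modelled).

### Numerical choices

The enzyme ODE is linear in `E` given the forcing, so it is advanced with
an exact exponential step per grid interval (trapezoidal forcing average):
unconditionally stable for any `kdeg`, with error second-order in the
0.05 h step. The victim arm uses a stiff-capable solver; halving its
tolerances moves reported AUCRs by far less than 0.5% (property-tested).
Dynamic-static consistency is also property-tested: under constant
perpetrator exposure and enzymes at steady state, the simulated AUCR
matches the fm-weighted static model within 2%.

## Synthetic data

`sim_induction_response()` emulates the assay's data-generating process:
quadruplicate fold changes around a true sigmoid with multiplicative
log-normal noise (mean-corrected so the expectation equals the truth
curve), default 10% CV -- an assumed value, since replicate CVs are not
reported for the assay; it is exposed as a parameter. The default
concentration design is an 8-point 3-fold dilution series from 30 uM.
`sim_pk_observations()` samples the closed-form PK profiles with
multiplicative or additive residual error. Both are pure functions of
their arguments and a mandatory seed.

What the generators deliberately do not emulate: donor-to-donor biological
variability, cytotoxic concentration ranges, qPCR/LC-MS measurement
artifacts upstream of fold changes, and nonlinear or time-dependent
perpetrator kinetics (e.g. rifampicin autoinduction is folded into the
fixture's steady-state clearance rather than modelled). Passing recovery
tests therefore demonstrate estimator correctness under the stated noise
model, not robustness to every feature of real assay data.

## Known limitations

* Transporters are outside the model. Rifampicin both induces CYPs and
  inhibits hepatic OATP1B1 uptake; for OATP substrates among the victims
  (pioglitazone, glyburide, repaglinide) a CYP-only model systematically
  over-predicts the net AUC reduction. This is a scope boundary, not a
  calibration defect.
* Single representative subject; no virtual population or inter-individual
  variability.
* Induction only: reversible and time-dependent inhibition terms of the
  full net-effect equation are not modelled.
* The victim backbone targets exposure ratios, not absolute profiles:
  shapes are one-compartment approximations.

## A worked pass through the pipeline

```{r pipeline, eval = FALSE}
# 1. fit synthetic assay data and inspect the model object
d <- sim_induction_response(ec50 = 0.0655, emax = 5.60, seed = 7)
f <- fit_induction(d, form = "hill")
summary(f)

# 2. static prediction, per donor
msm("rifampicin", "midazolam")

# 3. dynamic prediction for the packaged clinical design
out <- run_ddi("rifampicin", "midazolam")
out
plot(out, "enzymes")

# 4. assemble the comparison against the shipped clinical observations
victims <- setdiff(trial_designs()$victim, "warfarin")
cmp <- build_comparison(
  lapply(victims, function(v) run_ddi("rifampicin", v)),
  lapply(victims, function(v) msm("rifampicin", v)),
  observed_reductions()
)
cmp
```
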