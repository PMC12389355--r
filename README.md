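# cypind

Quantitative assessment of cytochrome P450 **induction**-mediated
drug-drug interactions (DDIs), with a focus on the CYP2C family, for DMPK
scientists who have in vitro hepatocyte induction data and need a
defensible clinical risk estimate before (or instead of) a dedicated DDI
study.

Conventional hepatocyte monocultures barely induce CYP2C enzymes, and no
clinical CYP2C substrate is cleared by a single enzyme — so the standard
CYP3A4-style static translation breaks down. `cypind` implements the full
alternative workflow as an open, tested pipeline:

* **Induction curve fitting** — sigmoidal fold-change models anchored at
  the vehicle baseline,
  `Y = 1 + (Emax − 1) / (1 + exp(−(log10 C − log10 EC50)/s))`
  (equivalently `Y = 1 + (Emax − 1) C^h/(EC50^h + C^h)`), fitted by
  bounded Levenberg–Marquardt on replicate means with the regulatory
  <2-fold **no-call** rule applied first. `fit_induction()` returns a
  classed model object with `print`, `summary`, `coef`, `predict`,
  `residuals` and `plot` methods.
* **Mechanistic static model (MSM)** — the ICH M12 basic induction model
  `R3 = 1/(1 + d (Emax − 1) I/(EC50 + I))` with `I = 10 × Imax,u`,
  combined across enzymes by the fraction-metabolized (fm) weighted
  net AUC ratio `AUCR = 1/(Σ fm_i FC_i + (1 − Σ fm_i))`, per hepatocyte
  donor (`r3()`, `net_auc_ratio()`, `msm()`).
* **Dynamic enzyme-turnover simulator** — multiple-dose perpetrator PK
  drives per-enzyme turnover
  `dE/dt = kdeg [1 + (Emax − 1) Cu/(EC50 + Cu)] − kdeg E` in liver (and
  enterocytes for gut CYP3A4 substrates); victim clearance is
  fm-partitioned in a well-stirred liver and the victim arm is simulated
  with and without the perpetrator (`run_ddi()`, `sensitivity_scan()`).
* **Registry and reporting** — cited parameter fixtures for rifampicin,
  efavirenz, carbamazepine, apalutamide and nine victim drugs
  (`load_compound()`, `registry_dump()`), synthetic-data generators for
  end-to-end testing, and comparison tables classified against the
  0.8–1.25 bioequivalence and 0.5–2.0 no-DDI bands
  (`build_comparison()`, `classify_band()`).

## Worked example

```r
library(cypind)

# fit a synthetic quadruplicate induction dataset (truth: EC50 0.0655 uM,
# Emax 5.60-fold, 10% CV noise)
d <- sim_induction_response(ec50 = 0.0655, emax = 5.60, seed = 7)
fit_induction(d, form = "hill")
#> synthetic / CYP / 1 / mrna
#> EC50 0.06302 uM, Emax 5.78-fold, slope 0.965  [hill, SD-weighted]

# dynamic simulation of the packaged rifampicin-midazolam clinical design
run_ddi("rifampicin", "midazolam")
#> Dynamic induction DDI: rifampicin -> midazolam
#>   perpetrator 600 mg x 5 q24h; victim 3 mg at 97 h
#>   AUC alone 0.1218 uM*h, with perpetrator 0.01519 uM*h
#>   AUCR 0.125 -> 87.5% AUC reduction
```

The fitted curve recovers the generating parameters within the precision
the quadruplicate noise allows; the simulation predicts that five days of
rifampicin 600 mg reduces midazolam exposure by ~88% (AUC ratio 0.125, a
"significant" DDI — far outside the 0.5–2.0 band), driven by hepatic
CYP3A4 abundance rising ~5-fold plus induced intestinal first pass.
`msm("rifampicin", "midazolam")` gives the static counterpart (mean AUCR
0.161 across the three donors, an 84% reduction).

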