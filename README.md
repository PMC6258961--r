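# bloodscore

Blood doping — transfusions, recombinant erythropoietin (rhEPO), volume
manipulation — leaves a signature across routine hematology: hemoglobin and
haematocrit rise, reticulocyte production surges during stimulation and
collapses after withdrawal, and the red-cell indices drift together. The
**Abnormal Blood Profile Score (ABPS)** condenses seven markers measured by
any standard analyzer —

| marker | meaning | unit |
|--------|---------|------|
| HCT  | haematocrit | % |
| HGB  | hemoglobin | g/dL |
| MCH  | mean corpuscular hemoglobin | pg |
| MCHC | mean corpuscular hemoglobin concentration | g/dL |
| MCV  | mean corpuscular volume | fL |
| RBC  | red blood cell count | 10⁶/µL |
| RETP | reticulocytes | % |

— into a single unitless score that discriminates doped from clean profiles
better than any marker alone. `bloodscore` is a trainable, openly specified
implementation of this scheme for laboratories and anti-doping researchers:
it fits the two-classifier ensemble on a labeled cohort, calibrates the
score against a reference distribution, and scores new profiles in batch
from R or from the shell.

## The model

Two classifiers are trained on the seven clipped markers *x* of a labeled
cohort (control vs doped):

* a **naive Bayes classifier** with kernel-density class-conditional
  densities; its raw score is the log odds
  `s_NB(x) = Σ_m [ log f_doped(x_m) − log f_control(x_m) ] + log prior-odds`,
  with per-marker Gaussian KDEs (Silverman bandwidth) and equal priors by
  default;
* a **soft-margin SVM** with RBF kernel
  `k(u,v) = exp(−‖u−v‖² / 2w²)` in standardized marker space; its raw score
  is the signed decision-function value `s_SVM(x) = Σ_i α_i y_i k(x_i, x) + b`.

The two raw scores are combined by **ensemble averaging**: each is
standardized by its mean and standard deviation over the training controls
and the two are averaged. A strictly monotone piecewise-linear **quantile
map**, fitted on the control population, then calibrates the combined score
so that a clean reference population has mean −0.67 and standard deviation
0.87, with 95% of values between −2.35 and 1. On that scale:

* **score > 1** — abnormal (expected in ~1 in 1,000 clean male athletes),
* **0 ≤ score ≤ 1** — possible suspicion of doping,
* **score < 0** — typical.

Before scoring, every marker is clipped to its allowed range (HGB to
[12.9, 18.2] g/dL; the other defaults are documented in `?marker_ranges`),
with a warning for each modified value.

The package also computes the **OFF-score** `HGB×10 − 60×RETP` (HGB in
g/dL), an indirect marker of withdrawn erythropoietic stimulation; values
over 133 are considered evidence of doping in the worst-case population
(male, low altitude). Unit heuristics warn when inputs look like g/L
hemoglobin, fractional haematocrit, or absolute reticulocyte counts.

Because the original training database (402 clean controls and 189 rhEPO
profiles) is not public, the package includes a **synthetic cohort
generator**: clean profiles are drawn from a multivariate lognormal over
the primary markers (HGB, RBC, MCV, RETP) per sex, with the derived indices
computed through the hematological identities (HCT = MCV·RBC/10,
MCH = HGB/RBC·10, MCHC = HGB/HCT·100) plus bounded noise; doped profiles
add rhEPO-style shifts with ON-phase (elevated RETP) and OFF-phase
(suppressed RETP) variants. Scores from a model trained on synthetic data
are *not* comparable to official ABPS values — the original trained
parameters are unpublished — but the machinery, calibration, and decision
bands are the same.

## Worked example

```r
library(bloodscore)

cohort <- simulate_cohort(cohort_spec(seed = 1))   # 402 control + 189 doped
fit <- abps_fit(cohort, seed = 1)
print(fit)
#> Abnormal Blood Profile Score model
#>   markers: HCT, HGB, MCH, MCHC, MCV, RBC, RETP
#>   training: 402 control + 189 doped profiles (seed 1)
#>   SVM: RBF width 3.369, C = 1, 284 support vectors
#>   calibration: 'reference_all' (47 knots)

doping <- make_fixture("doping13")    # synthetic longitudinal series
res <- score_profiles(doping, fit)
res$off <- off_score(doping)
print(res[c(1, 5, 8, 9, 13), ], digits = 3)
#>    sample_id    abps      band   off
#> 1        D01 -1.9275   typical  65.0
#> 5        D05 -0.7982   typical  92.2
#> 8        D08  0.2125 suspicion 114.6
#> 9        D09  1.3032  abnormal 137.4
#> 13       D13  4.6555  abnormal 148.0
```

The series tracks a simulated athlete over six years: hemoglobin climbs
from 13.1 to 15.8 g/dL while reticulocytes collapse, so the ABPS rises from
clearly typical (−1.93) through the suspicion band into abnormal (4.66),
and the OFF-score crosses the 133 threshold at the same samples.

The same pipeline runs from the shell:

```sh
Rscript inst/exec/abps simulate --out cohort.csv --seed 1
Rscript inst/exec/abps train    --in cohort.csv --out model.json --seed 1
Rscript inst/exec/abps score    --in profiles.csv --model model.json --out scores.csv
Rscript inst/exec/abps offscore --in profiles.csv --out off.csv
```

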