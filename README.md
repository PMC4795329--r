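# pcmcat

Computerized adaptive testing (CAT) for polytomous patient-experience
questionnaires under the Rasch partial credit model (PCM).

Long inpatient surveys are a burden on the patients they are meant to hear
from. `pcmcat` implements the item-response-theory answer: a calibrated item
bank, maximum-likelihood person measurement, and an adaptive engine that asks
the most informative remaining question at each step and stops once the
estimate is stable — then evaluates, by simulation, how much accuracy an
adaptive short test retains relative to the full form.

## The model

Item *i* has step thresholds δ<sub>i1</sub>…δ<sub>im</sub> (mean = item
difficulty, logits). A person of ability θ scores category *k* with

    P(X_i = k | θ) ∝ exp Σ_{j≤k} (θ − δ_ij),   Σ over the empty set = 0,

all items sharing discrimination 1. Item information is the score variance
W<sub>i</sub>(θ); the person standard error is `1/√(Σ W_i(θ̂))`; person
reliability for the stopping rule is `(1 − SEM)²`. Estimation is safeguarded
Newton on the score equation `Σ(x_i − E_i(θ)) = 0`. The adaptive session
opens with a random pool item, continues with maximum-information selection,
and stops on reliability ≥ 0.80, or once ≥ 5 items are answered and the mean
of the last five |Δθ̂| falls below 0.05 logits, or on pool exhaustion.
Skip items (conditional questionnaire paths) are supported through per-item
route maps; unanswered pool items can be completed with model-expected
responses at the final θ̂.

The bundled bank (`default_nhs_bank()`) holds 24 inpatient-experience items
— ward environment, doctors, nurses, care and treatment — with published
difficulties from −2.20 to 2.17 logits and 1–3 score steps each.

## Worked example

One adaptive session against a simulated respondent of true ability 1.2:

```r
library(pcmcat)
bank <- default_nhs_bank()
cohort <- simulate_cohort(bank, n_persons = 1, theta_mean = 1.2,
                          theta_sd = 1e-9, seed = 5)
session <- run_cat(cohort_respondent(cohort, 1), bank, cat_rules(), seed = 5)
session
#> Adaptive session: 21 items, stopped on residual
#>   final theta 1.467 (SEM 0.402, reliability 0.358); outfit MNSQ 1.22
head(write_session_trace(session), 3)
#>   step item_id answer    theta       sem  residual trend_corr
#> 1    1      16      1 4.000000 3.2842751        NA         NA
#> 2    2      37      1 2.318291 1.1960654        NA         NA
#> 3    3      27      0 1.209397 0.8815599        NA         NA
```

The session answered 21 of 24 items and stopped because the estimate had
stabilised (mean of the last five changes < 0.05 logits); the final measure
1.47 ± 0.40 logits covers the generating ability, and an outfit mean square
of 1.22 (< 2) shows nothing aberrant in the pattern. The trace columns are
the step-by-step provisional estimate, its standard error, the convergence
residual and the trend correlation of the recent estimates.

The three-scenario study — everyone answers all 24 items (AAI), a random
12-item short form (RSM), and an adaptive session scored after
expected-response imputation (CAT):

```r
cmp <- run_scenarios(bank, n_persons = 200, seed = 101, rsm_k = 12,
                     cat_scoring = "imputed")
cmp
#> Scenario comparison: 200 persons (seed 101 , CAT scoring: imputed )
#>   corr with true ability: AAI 0.951 | RSM 0.917 | CAT 0.943
#>   mean items answered:    AAI 24.0  | RSM 12.0  | CAT 19.66
```

Adaptive testing tracks the truth essentially as well as the full form while
asking fewer questions, and beats the random short form outright;
`correlation_table(cmp)` gives the full matrix over estimates and raw sums,
`write_report(cmp, dir)` writes the per-person table, the correlation matrix
with means/SDs, and a run log.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/pcmcat.R run --theta 1.2 --seed 5 --out trace.csv
Rscript inst/cli/pcmcat.R compare --n 1000 --seed 1 --cat-scoring imputed --out report/
```

(`run --mode interactive` administers the bank one question per prompt.)

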