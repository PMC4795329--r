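---
title: "Adaptive testing under the partial credit model: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive testing under the partial credit model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmcat)
```

## The measurement problem

Long inpatient-experience questionnaires burden exactly the people they are
meant to serve. `pcmcat` implements the standard remedy from item response
theory: administer items adaptively, choosing each next question to be
maximally informative about the respondent's current ability estimate, and
stop as soon as the estimate is precise or stable enough. The package
ships a 24-item inpatient-experience pool (ward environment, doctors,
nurses, care and treatment), calibrated in logits, and everything needed to
run and evaluate an adaptive survey against it.

## The response model

Responses are modelled with the Rasch partial credit model (PCM). Item $i$
has $m_i$ score steps with thresholds $\delta_{i1} \le \dots \le
\delta_{im_i}$ (in practice ordered here, though the model does not require
it), and a person with ability $\theta$ scores category $k \in \{0, \dots,
m_i\}$ with probability

$$
P(X_i = k \mid \theta) =
\frac{\exp \sum_{j \le k} (\theta - \delta_{ij})}
     {\sum_{h=0}^{m_i} \exp \sum_{j \le h} (\theta - \delta_{ij})},
\qquad \textstyle\sum_{j \le 0} \equiv 0 .
$$

All items share a discrimination of 1 (pure Rasch, not the generalized
PCM); this is what makes the raw sum a sufficient statistic and keeps item
information additive. The item information used throughout is the score
variance $W_i(\theta) = \sum_k k^2 P_k - E_i(\theta)^2$, which for the Rasch
family also equals $\partial E_i / \partial \theta$; the test standard error
is $1/\sqrt{\sum_i W_i(\hat\theta)}$.

The bank stores only each item's overall difficulty and step count, so step
thresholds are generated symmetrically around the difficulty with a fixed
spacing (default 1.0 logit, a typical spread for adjacent-category
thresholds of 3–4-category survey items): one step gives $[\delta]$, two
steps $[\delta \mp 0.5]$, three steps $[\delta - 1, \delta, \delta + 1]$.
The spacing is a constructor argument (`default_nhs_bank(threshold_spacing=)`),
and the threshold mean always reproduces the published difficulty. Absolute
model-implied quantities (test information, hence achievable correlations)
depend mildly on this choice; the scenario *ordering* reported below does
not.

## Person estimation

`estimate_theta()` maximises the PCM likelihood by safeguarded Newton
iteration on the score equation $\sum_i (x_i - E_i(\theta)) = 0$: steps are
`score/information`, clamped to 1 logit per iteration, the estimate confined
to $\pm$`theta_bound` (default 4 logits, roughly the range a 24-item
polytomous test can distinguish), convergence at $|\Delta\theta| < 10^{-5}$
or 50 iterations. Extreme vectors (all-minimum or all-maximum) have no
finite maximiser and are clamped to the bound and flagged `at_bound`; we
deliberately use plain clamping rather than score adjustments or weighted
likelihood corrections, keeping the estimator's contract simple and the flag
honest. The test suite checks the estimator against a brute-force
likelihood grid (step 0.001 over $[-6, 6]$), which is possible here because
the grid oracle reduces exactly under sufficiency.

### Reliability

The stopping quantity labelled person reliability is $(1 - \mathrm{SEM})^2$.
This is not the conventional form $1 - \mathrm{SEM}^2/\mathrm{Var}(\theta)$;
both are available (`reliability_form`), the squared-complement form being
the default because it is the form the stopping rule is defined on. One
guard is ours: the raw expression rebounds toward 1 once SEM exceeds 1
(e.g. $(1-2)^2 = 1$), which would stop a session after its first,
maximally uncertain item, so reliability is floored at 0 for SEM $\ge$ 1.
Note that with 24 polytomous items the maximum attainable test information
is about 13, so $(1-\mathrm{SEM})^2 \ge 0.80$ (SEM $\le 0.106$, information
$\ge 90$) is out of reach and the residual rule below is the practical
terminator — consistent with short-but-not-minimal adaptive test lengths.

### Fit statistics

Person fit uses the standard Rasch residual machinery: $z_i = (x_i -
E_i)/\sqrt{W_i}$, outfit = mean $z_i^2$, infit = $\sum (x_i - E_i)^2 / \sum
W_i$. An outfit of 2.0 or more flags a possibly aberrant pattern (careless
or random responding). Item-level fit (`item_fit()`) pools person residuals
per item; simulated cohorts sit inside the conventional 0.5–1.5
unidimensionality screen.

## The adaptive engine

A session (`run_cat()`) starts from a provisional ability of 0 (the pool is
roughly centred there) and a uniformly random first item — information-
optimal openers are a known refinement, deliberately not used here. Each
subsequent item maximises information at the provisional estimate, ties
broken toward the lowest item number. After every answer the ability is
re-estimated from all responses so far. Stopping combines three rules with
OR, checked in order:

1. **reliability**: $(1-\mathrm{SEM})^2 \ge$ 0.80 (no minimum-item gate);
2. **residual**: at least 5 items answered *and* the mean absolute change
   over the last 5 estimate updates is below 0.05 logits (the residual);
3. **exhaustion**: the pool (or `max_items`) is used up.

Only the residual rule is gated behind the minimum item count; the OR
combination and the precedence order are our reading of an ambiguously
worded rule set, chosen because rule 1 is practically unreachable (above)
and rule 2 then reproduces sensible adaptive lengths. The session also
reports the trend correlation — the Pearson correlation of the last five
estimates against their step numbers; a flat trend (correlation near 0,
defined as exactly 0 for a zero-variance window) signals convergence.

One numerical caveat, verified by simulation: the SEM trajectory is not
perfectly monotone. When the provisional ability moves by up to 0.2 logits
in a step, the information of already-administered items can drop by
slightly more than the newly added item contributes; rises are tiny (worst
observed 0.004 logits over thousands of steps) and the property tests allow
exactly that curvature slack.

### Skip-item routing

Real questionnaires contain conditional-path (skip) items whose answer
selects the next question. Routing metadata lives on the bank
(`routes`, e.g. answer `1` on item 39 leads to item 40, answer `2` to item
41); ordinary items fall through sequentially and routed items may not be
pool members. A small synthetic demonstration bank
(`demo_routing_bank()`) exercises the traversal; it emulates the *structure*
of skip logic only — the wording and branch probabilities of any real
instrument are not reproduced.

### Imputation of unanswered items

Because an adaptive session leaves most of the pool unanswered, item-level
service reporting needs a completion step: each unanswered pool item
receives its model-expected score at the final ability, rounded half-up
(deterministic, documented, and exactly the convention that maps an
expected 0.5 on a dichotomous item to 1) and clipped to the category range.
Scoring after imputation is also one of the two adaptive scoring modes in
the scenario study below.

## The synthetic cohort generator

`simulate_cohort()` draws abilities i.i.d. Normal(0, 1) — the study
condition for the headline comparison — and responses by inverse-CDF
sampling from the PCM at each person's true ability. Each person gets a
deterministic substream derived from the master seed, so person $i$ is
unchanged when the cohort grows. What the generator emulates is exactly the
model the estimator assumes: unidimensional, equal-discrimination,
locally independent responding with a symmetric ability distribution. Real
satisfaction data violate several of these — ceiling effects and negative
skew, multidimensionality across ward/doctor/nurse domains, aberrant
respondents — so passing simulations demonstrate internal consistency of
the engine, not field validity of the instrument.

## The scenario study

`run_scenarios()` compares three administrations of the same simulated
cohort:

* **AAI** — answer all 24 pool items (the long form);
* **RSM** — a random 12-item short form; by default a fresh uniform subset
  per person (`rsm_mode = "per_person"`), the stricter reading of random
  selection. A cohort-shared subset (`"shared"`) is also available: note
  that per-person subsets leave the *raw sums* on incommensurable scales
  (an easy subset inflates the sum), attenuating the within-scenario
  sum-versus-estimate correlation from ≈0.98 (shared) to ≈0.94, while the
  MLE, which conditions on subset difficulty, is unaffected;
* **CAT** — one adaptive session per person, answered from that person's
  pre-simulated responses, scored either from administered items only
  (default) or after expected-response imputation (`cat_scoring =
  "imputed"`). Imputed scoring is what makes the adaptive estimate
  directly comparable to the long form at the full-pool scale.

With the default rules the adaptive sessions answer about 20 of 24 items on
average — the reliability target is unreachable (above), so sessions run
until the estimate stabilises — and the accuracy ordering is stable across
seeds: long form ≈ adaptive > random short form in correlation with the
generating abilities.

```{r example, eval = FALSE}
bank <- default_nhs_bank()
cmp <- run_scenarios(bank, n_persons = 1000, seed = 101,
                     rsm_k = 12, cat_scoring = "imputed")
round(correlation_table(cmp), 3)
```

## Problem sizes and numerical choices

The packaged checks run the headline comparison at the full 1000-person
cohort size and verify the cross-seed accuracy ordering on 50 replicate
seeds of 250 persons each — the ordering of scenario correlations does not
depend on cohort size, and the smaller replicates keep the suite quick.
Other fixed numerics: probability normalisation is overflow-safe via
max-subtraction; the Newton step is clamped to 1 logit; ties in item
selection break toward the lowest item number; zero-information items
(possible only at extreme evaluation points) are excluded from fit sums
with a warning; trend correlation of a flat window is 0 by convention.

## Limitations

The 24-item calibration is taken as fixed and known — the package estimates
persons, not items. The generated thresholds are a modelling convention,
not estimates; absolute correlation levels shift slightly under other
spacings. The full 70-item questionnaire, its per-category weighted scores
and the branch probabilities of its nine skip items are not reproduced;
routing is demonstrated on a synthetic bank. Bayesian scoring (EAP/MAP),
Warm's weighted likelihood, exposure control and content balancing are out
of scope.
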