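---
title: "Estimating screening impact on stage-specific incidence and mortality: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating screening impact on stage-specific incidence and mortality: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenimpact)
```

This vignette is the package's account of its statistical machinery: the
model behind each step, the assumptions it rests on, the tunable parameters
and why their defaults are what they are, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## 1. The estimation problem

Organised cervical screening prevents invasive cancer by treating precursor
lesions, and *downstages* the cancers it does not prevent. Mortality is the
end point that matters, but deaths are too few and too late for direct
case-control estimation. The package therefore combines two ingredients:

* stage-specific **odds ratios** of developing cancer by screening
  regularity, estimated from an incidence case-control audit with matched
  sets (1 case : 1–2 age-matched controls); and
* external **5-year relative survival** by stage and age, converted to case
  fatality $\rho = 1 - S_5$.

Because both the odds ratios and the case fatality depend strongly on
stage, their stage-wise product captures the mortality benefit of stage
shift that a stage-blind analysis would miss.

Key assumptions, inherited by every downstream number: the estimated
associations are causal (no residual confounding beyond the age matching;
self-selection of healthy attenders is not corrected); one minus 5-year
relative survival equals the probability of dying of the cancer (no deaths
beyond 5 years, relative survival = cause-specific survival); and
stage-specific survival does not depend on the route to diagnosis.

## 2. Screening-history classification

Smear histories are reduced to the **maximum screening interval**: the
longest period inside the screening window containing no adequate smear.
Both boundary gaps count — from the window start to the first adequate
smear, and from the last adequate smear to the window end — otherwise a
single test 14 years before diagnosis would pass as regular screening.
Inadequate tests are ignored entirely.

The window and cut-offs are keyed to age at the reference (diagnosis) date:

| Age at reference | Window | regular | irregular | very irregular |
|---|---|---|---|---|
| 35–49 | 15 y before reference | gap ≤ 3.5 y | ≤ 7.5 y | ≤ 13 y |
| 50–64 | 15 y before reference | gap ≤ 5.5 y | ≤ 7.5 y | ≤ 13 y |
| 65+   | ages 50–64            | gap ≤ 5.5 y | ≤ 7.5 y | ≤ 13 y |

Anything beyond 13 years (or an empty window) is *not screened*. Ties at a
cut-off resolve toward the more regular category, matching the "≤" in the
definitions. Ages 25.5–34 use an attendance rule instead of a gap rule:
*regular* requires at least one adequate smear in every required 3-year age
slice (22.5–25.5; plus 25.5–28.5 from age 28.5; plus 28.5–31.5 from age
31.5), *irregular* requires at least one adequate smear in the window.
Under age 28.5 only one slice is required, so *irregular* is structurally
unreachable there. Women under 25.5 are excluded: a prevalence peak of
mostly stage-1A cancers at the first invitation would otherwise bias the
incidence association.

Numerical conventions: ages are decimal years at 365.25 days per year;
bands are half-open $[\ell, u)$; the 35–64 rule (not the 50–64 window
rule) applies up to exactly age 65; and the regular cut-off follows age at
reference, not age at each smear, because the definitions are keyed to age
at diagnosis. The lookback length (`window_years`, default 15) is the main
sensitivity switch; 12- and 8-year variants tighten the exposure window.

## 3. Conditional logistic regression

With one case per matched set, conditioning on the set removes the
set-level nuisance parameters, leaving

$$\ell(\beta) = \sum_{k} \Big[ x_{case,k}'\beta - \log \sum_{m \in k}
\exp(x_m'\beta) \Big],$$

which is concave. `fit_clr_matrix()` maximises it by Newton–Raphson with
analytic gradient and Hessian, starting at $\beta = 0$ (safe under
concavity), with step-halving so iterates are monotone in the likelihood.
Convergence: change in log-likelihood below $10^{-10}$ or gradient
max-norm below $10^{-8}$, at most 50 iterations — conservative defaults; the
fit typically converges in under 10 iterations. Sets with constant
covariates contribute a constant and are dropped from the iteration (their
likelihood offset is restored afterwards). Sets with a single control are
handled by the same likelihood with set size 2. Complete separation makes
the conditional likelihood monotone; a coefficient exceeding 15 in absolute
value is flagged (`converged = FALSE`, with the runaway direction), since
the gradient itself underflows to zero there.

Intervals are Wald, $\exp(\hat\beta \pm 1.96\,\widehat{se})$, because the
delta-method combination downstream consumes the log-scale standard error;
profile-likelihood intervals would have no corresponding variance. The
linear-trend model scores categories 0 (not screened) to 3 (regular) as
integers. `stage_specific_ors()` fits one categorical model per (age band,
stage), keeping each selected case's controls regardless of their own
status; empty strata are left absent rather than zero-filled.

## 4. Missing-stage reallocation

Stage 1A is assumed always recorded (microinvasive disease is diagnosed
histologically), so unknown-stage cases are reallocated to 1B/2/3+ within
their age band, proportionally to the band's known stage mix. The printed
tables carry no screening histories for the unknown-stage cases, so within
a receiving stage the unknowns follow that stage's category distribution —
implemented as one common scale factor per receiving cell. This is the
neutral choice and an acknowledged approximation. Counts stay fractional
end to end, since everything downstream is linear in $N$. Variants
(`none`, `all_stage2`, `all_stage3`, `proportional_all`) mirror the
sensitivity analyses; band totals are conserved to $10^{-9}$ in all modes.

## 5. Case-fatality raking

England-wide survival is available by stage *or* by age, not jointly. The
raking step builds the joint table from three inputs: a grid carrying the
joint age-within-stage dependence (e.g. from a large external registry),
stage-marginal survival targets, and age-marginal survival targets.
"Applying a hazard ratio $h$" to a 5-year survival $s$ means $s^h$ —
proportional hazards on the cumulative excess hazard, the standard
actuarial identity. Two passes: per stage, solve
$\sum_i w_{i|s}\, s_{is}^{h_s} = S_s$; then per age band, solve the
analogous equation for $h_i$. Each equation is strictly monotone in $h$, so
the root is bracketed on $[10^{-3}, 10^3]$ whenever the target is
attainable, and solved by Brent's method with a Newton polish to a
$10^{-10}$ marginal tolerance; unattainable targets raise an error naming
the stage or band. Marginalisation weights default to case counts — the
natural estimand when the table will multiply case counts.

Two documented caveats. The age pass perturbs the stage marginals just
matched (the default stops after one cycle, reproducing the two-step
narrative; `iterate = TRUE` alternates passes to joint convergence). And
while a single common power preserves within-stage ordering, the later
per-age-band powers can in principle reorder cells within a stage.
Iterated raking converges only when the two marginal sets are jointly
attainable; independently specified stage and age targets generally imply
different grand means and cannot both be matched exactly.

The packaged `england_audit` fatality table is shipped as data: the exact
joint survival inputs behind it are not published, so the raking algorithm
is validated on synthetic grids (marginals matched to $10^{-8}$, agreement
with an independent bisection oracle) and by the fixed-point property —
raking the packaged table to its own marginals returns it unchanged.

## 6. Counterfactual projection and indirect relative risks

With $\mathrm{OR}_{i,s,0} = 1$ for the never screened, the cancers that
would have been diagnosed absent screening are $\sum_j N_{isj} /
\mathrm{OR}_{isj}$ per (band, stage); under universal regular screening
each term is further multiplied by $\mathrm{OR}_{is,\text{regular}}$.
Excess deaths are $\sum N \rho$ with one substitution: never-screened
stage-1A cells take stage-1B fatality, because stage 1A is essentially a
screen-detected diagnosis and would present later without screening. The
substitution applies to every never-screened stage-1A cell, in the current
scenario as well — the rule concerns the women, not the scenario — and is
relaxed by `fatality_rule_1a = "keep_1a"` as a sensitivity analysis.

The indirect relative risk for category $j$ in a band is
$$RR_j = \frac{\sum_s N_{sj}\,\rho_s}{\sum_s (N_{sj}/\mathrm{OR}_{sj})\,
\rho^*_s},$$
with $\rho \equiv 1$ for the incidence end point and $\rho^*$ the
never-screened fatality (with the 1A→1B substitution) for mortality. It is
a weighted harmonic-type mean of the stage-specific ORs, so it always lies
between their extremes, and when ORs fall and fatality rises with stage the
mortality RR cannot exceed the incidence RR — stage shift made checkable.
The variance of $\log RR$ is the delta-method combination $\sum_s w_s^2
\widehat{se}_s^2$ with $w_s$ the stage's share of the denominator
(the numerator uses observed counts and carries no OR variance). A
parametric bootstrap (resampling log ORs from their normal approximations)
is provided as an independent check; on the packaged tables the two CI
constructions agree within a percent.

Because the odds ratios are published for pooled bands (35–64, 65–79)
while fatality is tabulated finer, the fatality rows are collapsed by
unweighted per-stage means (35–49 with 50–64; 65–69 with 70–79) unless
per-sub-band weights are supplied. The pooled-band estimates therefore
differ slightly from computations done at finer internal strata; the
package's regression tests pin its own values.

`scenario_rr()` generalises the combination to whole scenarios (estimated
deaths under a counterfactual over deaths under current screening), with
the delta-method weights obtained by numeric differentiation of the log
total in each log OR — exact weights become unwieldy once a cell's OR
enters both as divisor and as regular-screening multiplier.

## 7. Deaths-prevented accounting

Deaths within five years of diagnosis at ages $[\ell, u)$ occur at ages
$[\ell, u+5)$; the accounting therefore maps each diagnosis band to a
shifted age-at-death band before multiplying relative mortality by
observed national deaths. Deaths outside the covered diagnosis ages (under
25 or over 79 at diagnosis) are not preventable by screening ages 25–64
and are carried into every scenario unchanged. When a printed covered-bands
subtotal is available it takes precedence over the sum of the rounded
per-band averages, and when a projection table carries per-band death
estimates computed at higher precision than its rounded relative risks,
those estimates are used for the point accounting while the relative risks
supply the variances. Interval estimates use
$\mathrm{var}(\sum_b RR_b O_b) = \sum_b (RR_b O_b)^2
\mathrm{var}(\log RR_b)$ on the log scale of the total.

## 8. The synthetic cohort generator

`simulate_cohort()` exists so that every estimator can be tested against a
known truth. Per set: an age band is drawn from the case age distribution
(defaults 29% / 39% / 19.5% / 12.5% across 25.5–34 / 35–49 / 50–64 /
65–79); controls are age-matched within half a year and never across a
classification boundary; control categories follow the band's prevalence;
the case's stage is drawn from the never-screened stage mix and its
category from the prevalence *tilted* by the true odds ratios,
$P(j \mid s) \propto p_j\,\mathrm{OR}_{sj}$ — exactly the exponential-family
tilt under which conditional logistic regression is correctly specified, so
parameter recovery is a theorem being verified, not a coincidence. Stage is
blanked to unknown with probability 1579/11619. Smear histories then
*realise* the drawn category: evenly spaced adequate smears whose common
gap is drawn inside the category's interval with a 0.1-year guard band
against the cut-offs (day-rounding moves a gap by at most 0.003 y), slice
placement for the young bands, occasional inadequate tests that the
classifier must ignore, and out-of-window tests for never-screened women.
The round trip — generator's intended category versus classifier output —
must agree for 100% of women, and does.

Default true odds ratios and stage distributions come from the packaged
audit tables, so the generator's conditions are the study's. Free
parameters not derivable from print were fixed once: 1% single-control
sets ("very occasionally" in the source data), a control category
prevalence resembling English coverage by age (65% regular at 35–64,
lower and more polarised at 65–79), and uniform ages within band.

What the generator does **not** emulate: residence matching (no spatial
structure enters any estimator), HPV status, hysterectomy exclusions,
participation or self-selection bias, under-registration, and
calendar-time structure (for the 65–79 band, realised smear dates may
precede the 1988 start of computerised records that bounds real audit
extracts). Passing closed-loop tests therefore demonstrates internal
consistency of classifier, likelihood and combination under the assumed
generative model — not robustness to the confounding and measurement
problems of real records.

## 9. Problem sizes and test design

The suite validates the likelihood against an independently coded direct
evaluation and a grid-search maximiser on small instances, against
`survival::clogit` on a moderate cohort, and recovers generator parameters
on 5000 matched sets (about 15 s to simulate, classify and fit); raking is
checked against a bisection oracle and on random 3×4 grids; the
delta-method intervals are checked against a 10 000-replicate parametric
bootstrap. These sizes were chosen so the whole suite runs in about a
minute while keeping Monte Carlo standard errors small enough for 3-SE
recovery checks to be sharp.

## 10. Known limitations

Fixed, not estimated: the reallocation of unknown-stage cases assumes
missingness at random given age (above stage 1A); the pooled-band fatality
collapse uses unweighted sub-band means; delta-method intervals ignore the
(multinomial) sampling variance of the observed counts, which the source
analysis also conditioned on. The deaths accounting groups deaths by age at
diagnosis, takes observed deaths as a fixed denominator, and inherits the
5-year horizon: deaths from cervical cancer more than five years after
diagnosis are invisible to it. None of these can be relaxed from published
aggregate tables alone; all of them can be explored with the synthetic
generator.
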