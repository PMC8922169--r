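---
title: "Compliance testing strategies for occupational exposure limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compliance testing strategies for occupational exposure limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohcompliance)
```

## The problem

Workplace air monitoring asks a deceptively simple question: do the
full-shift exposures of a *similar exposure group* (SEG) — workers
assumed to share one exposure distribution — comply with the
occupational exposure limit (OEL) for the agent? Because shift-to-shift
exposure concentrations are strongly right-skewed, the universal working
assumption is lognormality: the natural logs of the concentrations are
treated as normal with mean $\mu$ and standard deviation $\sigma$ (so the
geometric mean is $e^{\mu}$ and the geometric standard deviation
$e^{\sigma}$). A handful of measurements must then support a decision in
{compliance, uncertain, non-compliance}. This package implements the
three decision strategies in European use and lets them be compared on
the same data.

## The three strategies

### Preliminary screens

With only 1–5 measurements no distribution can be fitted, so both EN689
editions screen each value against a fraction of the OEL:

| measurements | 1995 rule | 2018 rule |
|---|---|---|
| 1 | value < 0.1 × OEL | — |
| 3 | all < 0.25 × OEL | all < 0.1 × OEL |
| 4 | — | all < 0.15 × OEL |
| 5 | — | all < 0.2 × OEL |

All values below the screen: compliance. Any value above the OEL
itself: non-compliance. Anything else: uncertain — collect more
measurements. The screening fraction relaxes with sample size in the
2018 edition because the more values have been seen below a level, the
stronger the evidence that the upper tail is controlled. Measurements
enter in sampling-date order ([`select_preliminary_subset()`]), emulating
a survey where the screen is applied as results arrive.

### Statistical tests (n ≥ 6)

The 1995 test, in the simplified binary form used here (the original
green/orange zoning is deliberately not implemented), estimates the
*exceedance fraction* by plugging the sample moments of the logs into
the lognormal tail:
$$\hat p = 1 - \Phi\!\left(\frac{\ln \mathrm{OEL} - \hat\mu}{\hat\sigma}\right),$$
and declares compliance when $\hat p < 5\%$.

The 2018 test replaces the point estimate with a confidence-bounded
quantity, the one-sided **upper tolerance limit** of the 95th percentile
at 70% confidence:
$$\mathrm{UTL}_{95,70} = \exp(\hat\mu + k(n)\,\hat\sigma), \qquad
k(n) = \frac{t^{-1}_{0.70}\bigl(\mathrm{df}=n-1,\ \mathrm{ncp}=z_{0.95}\sqrt n\bigr)}{\sqrt n},$$
with compliance when $\mathrm{UTL}_{95,70} < \mathrm{OEL}$. The factor
$k(n)$ is computed exactly from the non-central $t$ quantile rather than
by interpolating printed tables; it exceeds $z_{0.95} = 1.6449$ for every
finite $n$ and decreases towards it, which yields a clean dominance
property: a SEG compliant under the 2018 test is always compliant under
the 1995 test, never the reverse. The Monte-Carlo checks in the test
suite confirm both the 70% coverage of the UTL and the dominance on
simulated SEGs.

### BOHS-NVvA individual compliance

The group tests ignore that workers within a SEG may differ
systematically. The BOHS-NVvA criterion models the logs with one-way
random effects: worker $i$ has personal mean $b_i \sim N(\mu,
\sigma^2_B)$ and day-to-day scatter $N(0, \sigma^2_W)$.
[`variance_components()`] estimates these by the classical ANOVA moment
method with the unbalanced-design correction
$n_0 = (N - \sum_i n_i^2/N)/(K-1)$; a negative between-worker moment
estimate is clamped to zero. The estimated fraction of *overexposed
workers* — those whose personal 95th percentile exceeds the OEL — is
$$\theta = 1 - \Phi\!\left(\frac{\ln \mathrm{OEL} - \hat\mu -
z_{0.95}\sqrt{\hat\sigma^2_W}}{\sqrt{\hat\sigma^2_B}}\right),$$
and the SEG complies when more than 80% of members are *not*
overexposed, i.e. $\theta < 0.20$ (strictly; exactly 80% fails).

The individual criterion is only informative when workers genuinely
differ, so [`bohs_nvva_test()`] routes on the between-worker share
$\rho_B = \sigma^2_B/(\sigma^2_B + \sigma^2_W)$: SEGs with
$\rho_B \ge 0.20$ take the individual test, the rest fall back to the
group 5%-exceedance test on the pooled fit. Which group-level test to
use on the homogeneous route is a genuinely open design point; the
plug-in exceedance rule was chosen because it is the group test of the
same (point-estimate) character as $\theta$ itself, and because as
$\sigma^2_B \to 0$ the individual decision converges exactly to it
(verified property): $\theta$ degenerates to the indicator that the
common 95th percentile exceeds the OEL, which is the 5%-exceedance
decision.

## Decision conventions and numerical choices

* **Strict inequalities everywhere.** Compliance requires being strictly
  under the threshold (screen fraction, OEL, 5%, $\theta = 0.20$); ties
  go to the unfavourable outcome. Ties are measure-zero for real data;
  the convention only matters for constructed inputs.
* **Degenerate fits.** A zero log-SD makes the lognormal a point mass at
  the GM: the exceedance is then 0, 1, or 0.5 for GM below, above, or at
  the OEL, and the UTL collapses to the GM.
* **Single-worker SEGs.** With one worker there is no between-worker
  contrast; $\sigma^2_B$ is set to 0 and the SEG routes to the group
  test. SEGs where no worker has repeats are rejected: $\sigma^2_W$ is
  not estimable.
* **Date ties.** Same-day measurements keep input-file order (a stable
  sort), so preliminary subsets are reproducible.
* **Natural logs** throughout, matching the GM/GSD convention.
* **Strictly positive concentrations.** Zero or negative values are
  rejected at the CSV boundary rather than imputed; censored-data
  handling is out of scope.

## The synthetic SEG generator

[`generate_seg()`] draws from exactly the random-effects lognormal model
the analyses assume; [`generate_study()`] assembles a survey-shaped
collection: every SEG has at least 6 measurements (the statistical-test
minimum) and a chosen number of SEGs contain repeated measurements of at
least one worker. Default parameter ranges — GM drawn log-uniformly from
0.02–0.8 mg/m³ against an OEL of 1 mg/m³, total GSD 1.5–3.5, a
between-worker variance share of 0–0.5, SEG sizes 6–8 — were chosen once
to span the range from clearly compliant to clearly non-compliant SEGs
and to bracket the 20% routing threshold, the territory a respirable-dust
survey of mineral-industry workplaces typically occupies. Each SEG is
driven by its own deterministically derived seed, so SEG $k$ is
unchanged when the study grows, and the global RNG stream is never
disturbed.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: temporal autocorrelation,
values below detection limits, non-lognormal tails, site/job structure
behind SEG membership, and unequal sampling campaigns. The tests
establish that the decision machinery is correct *under the model
assumptions*, not that the assumptions hold in any particular workplace.

## Validation scales

The package validates itself at sizes chosen to make Monte-Carlo error
negligible relative to the tolerance being asserted: $10^5$ simulated
SEGs per sample size for the 70% UTL coverage (binomial SE ≈ 0.0015
against a ±0.01 band), $10^6$ draws per grid point for the exceedance
and $\theta$ oracles (SE ≤ 0.0005 against ±0.002), $10^4$ generated SEGs
for the stringency-dominance sweep, and 200 replicate SEGs of 50 workers
× 10 repeats for variance-component recovery. A full simulated survey
of 210 SEGs (158 with repeats, 1383 measurements) exercises the pipeline
end to end; `scripts/acceptance.R` recomputes all of these from scratch.

## Limitations

* The exceedance test uses the plug-in estimate, deliberately: the
  confidence-bounded philosophy is represented by the UTL test, and
  keeping the 1995 arm point-estimate-based is what makes the two arms
  an informative contrast.
* $\theta$ is computed from point estimates of the variance components;
  no uncertainty in $\hat\sigma^2_B, \hat\sigma^2_W$ propagates into the
  individual decision.
* Moment (ANOVA) estimators are used rather than REML — the convention
  of the guidance this test comes from; with few repeated workers both
  are noisy, which is why [`sensitivity_filter()`] exists to drop SEGs
  with only one repeated worker.
* No lognormality diagnostics are applied before the statistical tests;
  with $n \ge 6$ such gates have little power and neither strategy is
  specified with one here.
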