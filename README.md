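# ohcompliance

Compliance testing of workplace exposure measurements against
occupational exposure limits (OELs), for occupational hygienists and
exposure scientists. The package implements, side by side, the three
decision strategies in common European use for similar exposure groups
(SEGs):

* **EN689:1995** — the preliminary screen on 1 or 3 measurements
  (compliant when below 0.1 × OEL, resp. all below 0.25 × OEL) and the
  statistical test declaring a SEG compliant when the plug-in exceedance
  fraction of the fitted lognormal, `P(X > OEL) = 1 − Φ((ln OEL − μ̂)/σ̂)`,
  is below 5%.
* **EN689:2018** — the preliminary screen on 3, 4 or 5 measurements
  (all below 0.1/0.15/0.2 × OEL respectively) and the statistical test
  declaring compliance when the upper tolerance limit of the 95th
  percentile at 70% confidence, `UTL₉₅,₇₀ = exp(μ̂ + k(n)·σ̂)` with
  `k(n) = t⁻¹₀.₇₀(df = n−1, ncp = z₀.₉₅√n)/√n`, falls below the OEL.
* **BOHS-NVvA individual compliance** — a one-way random-effects
  decomposition of log exposures into between-worker (σ²_B) and
  within-worker (σ²_W) variance. When workers differ appreciably
  (σ²_B ≥ 20% of total variance) the SEG complies only if more than 80%
  of its members have at least 95% of their personal exposure
  distribution below the OEL, i.e. the estimated overexposed fraction
  `θ = 1 − Φ((ln OEL − μ̂ − z₀.₉₅√σ²_W)/√σ²_B)` is below 0.20; otherwise
  the group 5%-exceedance test applies.

Because full multi-site exposure surveys are rarely shareable, the
package also ships a synthetic SEG generator with the same
lognormal/random-effects structure, and a pipeline that tallies the
decisions of every strategy over a dataset.

## Worked example

One SEG of 8 respirable-dust measurements on 4 workers, OEL = 1 mg/m³:

```r
library(ohcompliance)
seg <- generate_seg(seg_spec("quarry_mill", c(3, 2, 2, 1), mu_log = log(0.25),
                             sigma2_B = 0.15, sigma2_W = 0.35, seed = 42))
fit <- fit_lognormal(seg$measurements$concentration)
fit
#> Lognormal fit: n = 8, GM = 0.5278, GSD = 1.882
exceedance_probability(fit, 1)   # 0.1562
utl_95_70(fit)                   # 1.9566
statistical_test_1995(fit, oel_spec(1))
#> [EN689_1995_STAT] non_compliance (statistic = 0.1562), n = 8
statistical_test_2018(fit, oel_spec(1))
#> [EN689_2018_STAT] non_compliance (statistic = 1.957), n = 8
bohs_nvva_test(seg, oel_spec(1))
#> BOHS-NVvA: rho_B = 0.009 -> group_test
#>   theta = 1, decision: non_compliance
```

The fitted geometric mean is 0.53 mg/m³ with GSD 1.9, so an estimated
15.6% of full shifts exceed 1 mg/m³ (≥ 5%: non-compliant under
EN689:1995) and the UTL₉₅,₇₀ of 1.96 mg/m³ is above the OEL
(non-compliant under EN689:2018). The between-worker share of variance
is under 20%, so the BOHS-NVvA assessment falls back to the group test.

A whole simulated survey (210 SEGs, 158 with repeated measurements,
1383 measurements in total):

```r
study <- generate_study(210, 158, study_parameters(total_measurements = 1383),
                        seed = 1)
run_comparison(study, oel_spec(1))
#> Compliance comparison: 210 SEGs (158 with repeats), OEL = 1 mg/m3
#>
#> == all segs ==
#>  variant                  compliance uncertain non_compliance
#>  EN689:1995 prelim #1     93 (44%)   104 (50%) 13 (6%)
#>  EN689:1995 prelim #3     100 (48%)  87 (41%)  23 (11%)
#>  EN689:2018 prelim #3     50 (24%)   137 (65%) 23 (11%)
#>  EN689:2018 prelim #4     58 (28%)   126 (60%) 26 (12%)
#>  EN689:2018 prelim #5     65 (31%)   114 (54%) 31 (15%)
#>  EN689:1995 stat 5% exc.  155 (74%)            55 (26%)
#>  EN689:2018 stat UTL95,70 127 (60%)            83 (40%)
#>
#> == repeats only ==
#>  ...
#>  BOHS-NVvA I.C.           117 (74%)            41 (26%)
```

Each cell is `count (percent%)` of SEGs per decision. The preliminary
screens leave many SEGs uncertain (more samples needed); the EN689:2018
UTL test always declares at least as many SEGs non-compliant as the
1995 exceedance test, because `k(n) > z₀.₉₅` for every finite sample
size; and the BOHS-NVvA individual criterion lands between the two.
`write_report()` serialises these tables to CSV or markdown.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ohcompliance.R", package = "ohcompliance"))')
Rscript "$CLI" simulate --n-segs 210 --n-with-repeats 158 --seed 1 --output measurements.csv
Rscript "$CLI" run --input measurements.csv --oel 1 --output report.md --format markdown
```

Input CSVs carry the columns `seg_id, worker_id, sample_date,
concentration` (ISO-8601 dates, concentrations in mg/m³, strictly
positive).

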