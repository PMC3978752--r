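# latebloom

Time-dependent biomarker analysis of distant recurrence in ER-positive
breast cancer.

## The problem

In ER-positive breast cancer treated with adjuvant endocrine therapy,
roughly half of distant recurrences happen *after* the first five years.
Prognostic signatures built around proliferation identify early relapse
well but say little about late relapse, and a single 10-year hazard
ratio hides effects that reverse over time. `latebloom` implements the
analysis pattern for this question:

1. **Signature scoring.** A proliferation score (MKS: mean log2
   expression of 12 mitotic kinases) and an estrogen-related score
   (ERS: mean of the four ER-associated Oncotype DX genes — ESR1, PGR,
   BCL2, SCUBE2) are computed per sample. Median splits on a declared
   reference cohort give four biomarker groups:
   `lowMKS/highERS` (reference), `lowMKS/lowERS`, `highMKS/highERS`,
   `highMKS/lowERS`.
2. **Time-cohort survival analysis.** Landmark restriction to windows
   (0–2.5, 2.5–5, 0–5, 5–10, 0–10 years), Cox models per window with
   Efron tie handling and Wald inference, scaled-Schoenfeld
   proportional-hazards diagnostics, landmark Kaplan–Meier curves, and
   boundary-corrected Epanechnikov kernel hazard curves per group.
3. **Neoadjuvant response analysis.** For a letrozole arm profiled at
   day 0/14/90: molecular response = MKS change from baseline, clinical
   response = volume reduction > 50%, response rates compared across
   baseline ERS levels (continuity-corrected chi-square / Fisher) and
   MKS dynamics compared by Wilcoxon rank-sum.
4. **Synthetic cohorts.** A generator with group-conditional scores,
   gene-level expression, clinical covariates, and piecewise-constant
   group-specific hazards, so the full pipeline is testable without the
   original microarray series.

The core survival model is the Cox proportional-hazards model
`λ(t | x) = λ₀(t) exp(βᵀx)`; non-proportionality is diagnosed by the
correlation of scaled Schoenfeld residuals with (KM-transformed) time,
and time-varying effects are then *estimated* by refitting within
landmark windows `(t₀, t₁]` (entry requires event-free survival past
`t₀`; follow-up is administratively censored at `t₁`).

## Worked example

```r
library(latebloom)

co <- simulate_cohort(default_paper_like_config(2000), seed = 1)
scored <- score_cohort(co$expr)                 # MKS/ERS + median-split groups
cl <- co$clinical
cl$group <- scored$group[match(cl$sample_id, scored$sample_id)]

cox_fit(cl, "group", time_window(0, 2.5))
#> <cox_result> n = 2000, events = 119, window 0-2.5 yr
#>                  term   hr ci_lo ci_hi       p
#>    grouplowMKS/lowERS 1.71 0.940  3.13 7.9e-02
#>  grouphighMKS/highERS 1.18 0.615  2.27 6.2e-01
#>   grouphighMKS/lowERS 3.26 1.920  5.54 1.2e-05

cox_fit(cl, "group", time_window(5, 10))
#> <cox_result> n = 1602, events = 185, window 5-10 yr
#>                  term    hr ci_lo ci_hi       p
#>    grouplowMKS/lowERS 1.350 0.885  2.07 1.6e-01
#>  grouphighMKS/highERS 2.190 1.480  3.23 8.1e-05
#>   grouphighMKS/lowERS 0.977 0.620  1.54 9.2e-01

schoenfeld_ph_test(cox_fit(cl, "group", time_window(0, 10)))
#> <ph_test> transform = km
#>                  term  chisq df       p
#>    grouplowMKS/lowERS 0.0105  1 0.91800
#>  grouphighMKS/highERS 2.3730  1 0.12300
#>   grouphighMKS/lowERS 8.3610  1 0.00383
#> GLOBAL chisq = 27.03, df = 3, p = 5.81e-06
```

Read: the `highMKS/lowERS` group carries the early excess risk
(HR 3.26 in years 0–2.5) but is indistinguishable from the reference
after year 5 (HR 0.98), while `highMKS/highERS` is quiet early
(HR 1.18) and becomes the highest-risk group late (HR 2.19) — exactly
the crossing pattern the global proportional-hazards test rejects over
the full decade (p ≈ 6e-6). `run_time_cohort_suite()` packages all of
this (plus KM and hazard curves) into one report; `write_report()`
serializes it.

The neoadjuvant side, on the response counts 7/15 (low-ERS) versus
11/11 (high-ERS) among baseline high-proliferation tumors:

```r
compare_response_by_ers(records)   # records: response + baseline levels
#> rates: 46.7% vs 100.0%, chi2 p = 0.013, fisher p = 0.0074
```

## Command line

```sh
Rscript inst/cli/latebloom simulate --n 683 --seed 1 --out sim/
Rscript inst/cli/latebloom score    --expression sim/expression.tsv --out scores.tsv
Rscript inst/cli/latebloom analyze  --expression sim/expression.tsv \
    --clinical sim/clinical.tsv --out report/
Rscript inst/cli/latebloom crosstab --clinical sim/clinical.tsv \
    --row group --col her2 --out ct.tsv
```

Gene sets are overridable with `--genesets sets.json`
(`{"MKS": [...], "ERS": [...]}`).

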