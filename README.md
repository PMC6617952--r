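# silverphen

Weakly supervised detection of probable **undiagnosed dementia** from
electronic health records (EHRs).

Dementia is widely under-coded: a large fraction of patients with clinically
evident disease never receive a diagnosis code, so supervised phenotyping has
no gold-standard labels to learn from. `silverphen` implements a
silver-standard pipeline for this setting, aimed at clinical informaticians
and epidemiologists who have cohort, code, and note data but no annotations:

1. **Cohort** — diagnosed cases and matched (default 5:1, by gender, age
   within 5 years, and Charlson comorbidity category) undiagnosed controls,
   each observed over a 3-year window ending the day before an index date.
2. **Topic features** — clinical notes are thinned to one note per
   subject-day, tokenized, and modelled with latent Dirichlet allocation
   (collapsed Gibbs, own implementation) **three times with distinct
   seeds**. Topics reproduced across all runs (mutual best match by cosine
   similarity of topic-word distributions, all pairwise cosines ≥ 0.8) are
   kept as *stable topics*. A stable topic is *present* in a note when at
   least 2 of its 3 per-run proportions are ≥ 2%, and in a subject when
   present in any note.
3. **Structured features** — every ICD/CPT code, medication, and note type
   becomes a binary presence feature over the window.
4. **Selection** — features present in > 1% of cases or controls with
   |phi| > 0.05 or odds ratio > 2.0 or < 0.5 are kept.
5. **Silver-standard risk score** — ridge-stabilised logistic regression of
   coded diagnosis status (case = 1) on the selected features; the
   inverse-logit score orders everyone by dementia likelihood, and controls
   with score > θ are flagged as probable undiagnosed dementia.
6. **Chart-review calibration** — 120 controls sampled across ten coarse
   score bins (30 from the lowest) are expert-reviewed as
   Dementia / Unclear / Non-Dementia. Per-bin undiagnosed rates y are fit
   against bin midpoints x as y = b₀ + b₁x; when the intercept is not
   significant, the zero-intercept line y = bx is adopted. Controls are then
   re-binned into ~100-subject fine bins with boundaries
   0 = x₀ < x₁ < … < x_B = 1, the undiagnosed count per bin is
   uᵢ = round(b · x̄ᵢ · Nᵢ), and for every threshold θ = xᵢ

   SEN = Σ_{k>i} u_k / Σ u_k,  SPE = (Σ_{k≤i} N_k − Σ_{k≤i} u_k) / (Σ N_k − Σ u_k),

   giving an ROC curve and trapezoidal AUC. Everything is computed under
   both resolutions of "Unclear" reviews.

Because the motivating clinical data are access-restricted, the package
ships a **synthetic-EHR generator** (`generate_cohort()`,
`plant_undiagnosed()`, `generate_notes()`, `generate_structured_events()`,
`simulate_chart_review()`) that plants a known topic model, a latent
severity per control, and a ground-truth undiagnosed flag drawn with
probability `b_true × severity` — exactly the linear rate model the
calibration stage fits — so every stage is testable offline.

## Worked example: calibrating undiagnosed rates from review counts

The package bundles a per-bin chart-review outcome table
(`example_review_counts()`; 120 reviews across ten risk bins):

```r
library(silverphen)

counts <- example_review_counts()
rates  <- compute_rates(counts)
fit    <- with(subset(rates, policy == "unclear_dementia"),
               fit_rate_line(round(rate, 3), midpoint))
fit
#> <rate_line_fit> y = 0.1565 + 0.7335 x  (p[b0] = 0.084, not significant:
#>   zero-intercept line adopted); zero-intercept slope 0.9689
```

The intercept test (p = 0.084 > 0.05) accepts the origin, so the
zero-intercept slope b = 0.969 is carried into per-bin undiagnosed counts
and the ROC:

```r
scores <- runif(9305, 1e-6, 1 - 1e-6)        # control risk scores
part   <- partition_controls(scores, target_size = 100)
nrow(part)
#> [1] 93
roc <- roc_curve(estimate_undiagnosed(part, min(1, fit$slope_zero)))
pick_thresholds(roc)
```

An end-to-end synthetic study (600 subjects, 20 topics, three LDA runs)
runs with:

```r
res <- run_pipeline(pipeline_config(seed = 1))
res$ground_truth_auc        # score vs planted truth
autoplot(res$roc$unclear_dementia)
```

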