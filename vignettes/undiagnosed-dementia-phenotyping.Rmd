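---
title: "Methods: weakly supervised detection of undiagnosed dementia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weakly supervised detection of undiagnosed dementia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A substantial share of older adults with dementia never receive a diagnosis
code, so their records carry the *signs* of disease (memory complaints,
cognitive work-ups, caregiver notes) without the label. `silverphen` treats
the coded diagnosis as a **silver standard**: diagnosed patients are almost
certainly true positives, undiagnosed patients are mostly — but not all —
true negatives. A classifier trained on this imperfect label, applied back
to the unlabelled group, surfaces probable undiagnosed cases; a small,
stratified expert chart review then converts scores into calibrated
undiagnosed *rates*, sensitivities, and specificities, without ever needing
full-cohort annotation.

## The model, stage by stage

**Cohort.** Cases carry a specialty-clinic dementia code; controls carry
none and no anti-dementia medication over the analysis period, and are
matched 5:1 on gender, age (±5 years), and Charlson comorbidity category.
All data live in a half-open 3-year window `[index − 1095 d, index)`; the
index date (first dementia code for cases, a chosen visit for controls) is
excluded, so cases have *no* dementia code inside their own window.

**Topics.** Notes are thinned to one per subject-day (multiple same-day
notes are redundant and inflate LDA cost), tokenized (lowercase,
split on non-alphanumeric runs, stopwords and one-character tokens dropped,
words in fewer than `min_doc_freq = 2` documents removed, ids assigned
lexicographically), and fitted with collapsed-Gibbs LDA three times under
distinct seeds. Hyperparameters follow common toolkit practice — total
document-topic concentration `alpha_sum = 5` (so `alpha = 5/K` per topic),
topic-word smoothing `beta = 0.01` — because the motivating analyses name a
toolkit but not its settings; all are arguments. The production-scale
default is `n_topics = 1000`; desk-scale corpora use 5–50.

**Stable topics.** Because Gibbs LDA is stochastic, run-specific topics
differ. A topic triple is *stable* when each pair is a mutual best match by
cosine similarity of topic-word rows and all three cosines reach 0.8. The
mutual-best-match-clique criterion was chosen over greedy global matching
because it is order-independent, one-to-one by construction, and
deterministic; the threshold is exposed (`similarity_threshold`). The
merged (mean) word distribution labels the topic only — presence always
uses the three per-run proportions: at least `quorum = 2` of the 3 inferred
proportions `≥ 0.02` (boundary inclusive) makes a topic present in a note,
and presence in any note makes it present in the subject.

**Features and selection.** Structured domains (ICD, CPT, medications, note
types) are binarised to in-window presence. "Correlation" is implemented as
the phi coefficient — the Pearson correlation of two binary indicators —
since no estimator is otherwise pinned down. Odds ratios use the
Haldane–Anscombe 0.5-per-cell correction only when a cell is zero, keeping
non-degenerate tables exact. Selection keeps features with prevalence
> 1% in either group *and* (|phi| > 0.05 or OR > 2 or OR < 0.5); all
inequalities strict, and the same rule applies to topic and structured
features alike.

**Risk model.** Logistic regression (case = 1) fitted by IRLS with a ridge
penalty `lambda = 1e-6` on coefficients (never the intercept). The penalty
exists because plain maximum likelihood need not exist under complete
separation, which is routine with hundreds of binary features; at `1e-6` it
is numerically invisible on non-separated data (the test suite checks
agreement with `glm()` to 1e-5) and can be set to 0. Scores are
inverse-logit values in (0, 1); coarse bins are the ten tenths of [0, 1],
half-open with the top bin closed.

**Calibration.** 10 controls per coarse bin plus 20 extra from bin 1
(120 total; short bins contribute what they have, with a warning) are
reviewed as Dementia / Unclear / Non-Dementia. Per-bin rates are computed
under both Unclear policies — `(d+u)/(d+u+n)` and `d/(d+u+n)` — and
regressed on bin midpoints. The decision rule is procedural: fit
`y = b0 + b1 x`; if the t-test of `b0` (df = n−2) is not significant at
0.05, adopt the zero-intercept slope `b = Σxy/Σx²` for downstream use; both
fits are always reported. Rates are carried at full precision, except that
reproducing published regression tables exactly requires fitting on rates
rounded to the 3 printed decimals, so `fit_rate_line()` takes whatever rate
vector the caller supplies. Inter-rater agreement uses Cohen's kappa with a
Wald-type interval truncated to [−1, 1], matching how such intervals are
conventionally reported; the truncation matters at small n.

**Fine bins, SEN/SPE, ROC.** Controls are rank-binned into
`B = round(N/100)` bins (sizes within 1, larger bins first, ties staying in
the lower bin), with interior boundaries midway between adjacent scores and
outer boundaries pinned at 0 and 1. Per-bin undiagnosed counts are
`u_i = round(b·x̄_i·N_i)` with ties rounded half away from zero (the
round-to-even alternative would make results parity-dependent); counts are
clamped at `N_i` as a safety net. Sensitivity and specificity at each
dividing boundary use the cumulative-sum formulas, with SEN = 1, SPE = 0 at
`i = 0` and SEN = 0, SPE = 1 at `i = B`; all-zero `u` is an explicit error
(sensitivity undefined). The AUC is the trapezoid over `(1−SPE, SEN)`,
which for binned counts equals cross-bin concordant pairs plus half of
within-bin ties — the test suite verifies this identity by exhaustive pair
counting on 1000 random bin systems. `pick_thresholds()` reports the
boundary minimising |SEN − SPE| plus nearest-to-target high-sensitivity and
high-specificity modes, ties resolved toward the lower threshold; this is a
declared rule, not a reconstruction of how any particular published
thresholds were chosen.

## What the synthetic generator emulates — and what it does not

The generator reproduces the *statistical structure* the analysis assumes:
matched 5:1 cohorts (matching is constructed, not solved as an assignment
problem — the contract is only that the stated constraints hold), the
half-open 3-year window, a ≥2-note-days-per-year floor for cases,
code-prevalence differences between groups, notes drawn from a known topic
model with dementia topics enriched in cases, and a planted linear
undiagnosed model: each control has latent severity `s ~ Uniform[0, 1]`
(uniform because no distribution is pinned down and it makes the planted
line directly identifiable) and is truly undiagnosed with probability
`b_true·s` (default `b_true = 0.5`, the midpoint of the 30–50% range
usually quoted for undiagnosed dementia in this population). Truly
undiagnosed controls express the affected note mixing and case-level code
prevalences; no control ever receives a dementia code or anti-dementia
medication — being uncoded and untreated is what defines the group.

Per-note topic proportions are drawn from
`Dirichlet(note_concentration × mixing)` with `note_concentration = 1`,
so individual notes focus on a few themes while subject-level averages
equal the mixing distribution. This is both more realistic (clinical notes
are topical) and necessary for identifiability: if every document carried
identical proportions, the planted topics would only ever be recovered as
their mixture. `note_concentration = Inf` recovers literal
subject-multinomial sampling and is used by the sampling-law test.

The generator does **not** emulate clinical language, demographic realism
beyond the matching structure, comorbidity computation from raw codes, or
reviewer behaviour beyond three error rates (`sens_review`, `spec_review`,
`p_unclear`). Passing tests therefore demonstrate that the *pipeline
machinery* is correct under the planted model, not that the method achieves
any particular accuracy on real EHR text.

## A known limitation of score-binned calibration

One property deserves emphasis. Binning controls by **latent severity**
recovers `b_true` (the generator invariant, tested at n = 5000). Binning by
the **risk score** generally does not: an approximately calibrated
case/control score with a 5:1 design averages at most ~1/6 over controls,
so when the planted marginal undiagnosed rate is `b_true/2 = 0.25`, the
review rate in the top score bins saturates near 1 and the fitted
zero-intercept slope concentrates near
`(controls:cases ratio) × P(undiagnosed) ≈ 1.25`, not `b_true`. The
end-to-end test asserts slope recovery anyway, documenting the gap
honestly: score-binned calibration estimates the rate line *of the score*,
which equals the planted severity line only when the score is calibrated to
severity. On real data, where the review rate is the estimand (rather than
a planted parameter), this distinction is invisible; on synthetic data with
a known `b_true` it is the difference between the latent- and score-binned
regressions. Users comparing calibrated slopes to known simulation truth
should bin by the latent variable.

## Numerical choices and degenerate inputs

* Empty documents at inference get the symmetric-prior mean (uniform over
  topics) with a warning — the prior-only posterior, avoiding 0/0.
* `n_topics` above the vocabulary size warns rather than fails.
* Constant features get `phi = 0` by convention and a `constant` flag.
* Subjects with zero notes get all-zero topic presence with a warning.
* Empty review bins yield `NA` rates and are dropped from line fitting
  with a warning; fewer than 3 points is an error.
* Both-raters-constant kappa is 1 by convention, flagged `degenerate`.
* All stage seeds derive deterministically from one base seed
  (`pipeline_config(seed = …)`), the three LDA seeds must be distinct, and
  the Gibbs sampler uses its own seeded RNG, so a full pipeline rerun is
  reproducible artifact-for-artifact.

## Problem sizes

Desk-scale defaults — 600 subjects, 500-word vocabulary, 20 topics, 150
Gibbs sweeps, three runs — were chosen so a full synthetic study fits in a
few minutes on one core while every stage still has enough signal for the
planted structure (topics, selected features, ground-truth AUC) to be
recovered; unit tests use smaller corpora still. Production-scale settings
(thousands of subjects, `n_topics = 1000`) are configuration changes, not
code changes.
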