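---
title: "Validating patient-reported chronic diseases against administrative records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating patient-reported chronic diseases against administrative records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronicagree)
```

## The measurement problem

Two imperfect instruments observe the same latent quantity: whether a
patient has a given chronic disease at the time of an elective joint
replacement. The pre-operative questionnaire records the patient's own
account ("Have you ever been told by a doctor that you have ...?"); the
administrative admission history records what hospital coders entered, up
to 20 ICD-10 diagnosis codes per admission. Neither is truth. The
convention adopted here — as in the validation literature this package
supports — is to treat the administrative flag as the *reference standard*
and summarise the questionnaire's performance as sensitivity, specificity
and chance-corrected agreement.

For a condition with agreement cells $(a, b, c, d)$ = (both positive,
administrative only, patient-reported only, neither) and $N = a+b+c+d$:

$$\mathrm{sens} = \frac{a}{a+b}, \qquad
  \mathrm{spec} = \frac{d}{d+c}, \qquad
  \kappa = \frac{p_o - p_e}{1 - p_e}$$

with $p_o = (a+d)/N$ and
$p_e = p_\mathrm{adm} p_\mathrm{pat} + (1-p_\mathrm{adm})(1-p_\mathrm{pat})$
from the two marginal prevalences. Kappa is banded qualitatively:
below 0.40 *poor*, 0.40–0.60 *moderate*, 0.61–0.80 *substantial*,
0.81–1.00 *near perfect* agreement. That convention leaves the open
interval (0.60, 0.61) unassigned; this package assigns all of
(0.60, 0.80] to the substantial band, and all negative values to poor.
Out-of-range kappa is an error, not a clamp.

## Confidence intervals

Sensitivity and specificity intervals default to the normal-approximation
(Wald) interval on the binomial proportion, truncated to $[0,1]$. The
choice is deliberate: at the scale of national registries the Wald and
Wilson intervals are indistinguishable to the printed precision, and the
Wald form reproduces the intervals printed in the validation study whose
contingency tables ship with the package (all eleven sensitivity intervals
match to one decimal place; `scripts/acceptance.R` recomputes this).
Wilson intervals are available via `ci_method = "wilson"` for small
cohorts, where Wald under-covers.

The kappa interval uses the Fleiss–Cohen–Everitt large-sample variance
$$\widehat{\mathrm{var}}(\hat\kappa) = \frac{A + B - C}{N (1-p_e)^4},$$
the standard asymptotic form for a single 2×2 rater table. At registry
scale the interval is near-degenerate, so printed intervals cannot
discriminate between asymptotic variants; the formula used is recorded
here and in the function documentation rather than inferred from output.
Degenerate marginals ($p_e = 1$) return `NA` with an explanatory note
rather than an error, as do zero denominators for sensitivity or
specificity — a validation pipeline should report a reason, not crash,
when a condition is absent from one source.

## Cohort construction

`build_cohort()` applies three exclusion rules in a fixed order:

1. **Duplicates** — a procedure linked to more than one questionnaire, or
   a questionnaire linked to more than one index procedure. The default
   removes *every* row of an offending group: when duplicates are
   indistinguishable copies there is no defensible keep-rule, and removing
   all is reproducible and conservative. `dedup = "keep-first"` keeps the
   first row by id for sensitivity analyses.
2. **Subsequent procedures** — each patient's first index admission (by
   admission day, ties by admission id) is kept; questionnaires linked to
   later procedures are excluded.
3. **High-count responders** — rows reporting at least 7 of the listed
   conditions are excluded, on the grounds that such patterns typically
   indicate the response scale was inverted. The count includes arthritis
   (all 12 questionnaire conditions): the exclusion concerns response
   validity, not the analysis set, and arthritis is on the questionnaire.
   Pass `conditions =` to `exclude_high_count()` for the 11-condition
   reading.

The order matters — a row removed as a duplicate is never also counted as
a subsequent procedure — so the order is part of the contract, and the
`exclusion_report()` enforces
`n_final = n_input − (sum of the four exclusion counts)` by construction.
Running `build_cohort()` on its own output removes nothing.

Dates are integer day offsets from an arbitrary cohort start. Calendar
conventions ("12 months", "five years") are fixed as 365 and 1826 days.
This avoids timezone and leap-year ambiguity that day-level admission data
do not support anyway.

## Administrative flags and the look-back window

`derive_admin_flags()` raises a flag when any diagnosis code on an
in-window admission matches the condition's code set. In-window means: the
index admission itself (`include_index = TRUE` by default — the reference
standard is the patient's status *at* surgery), plus any non-index
admission with
$\mathrm{index~day} - \mathrm{window} \le \mathrm{day} \le \mathrm{index~day}$.
The early boundary is closed; non-index admissions on the index day count;
admissions after the index day never count, because post-operative coding
must not inform a pre-operative reference standard. Diagnosis position
(primary vs 20th) is deliberately ignored. Enlarging the window can only
turn flags on, never off — a property the test suite checks.

Code matching uses prefix semantics: a 3-character map entry (`"E11"`)
covers every 4-character child (`"E110"` ... `"E11Z"`) and the bare
category itself; a 4-character entry matches only itself. This mirrors how
comorbidity-index code lists mix category- and subcategory-level entries.

## Backward coding

Seed code lists derived from comorbidity indices miss codes that patients
evidently mean when they tick a box. Backward coding recovers them from
the data in two stages, anchored on *unexplained reporters* — patients who
report a condition but carry no mapped code in their look-back window:

1. **Screen** 3-character categories that appear in the unexplained
   reporters' in-window admissions, lie in the condition's allowed ICD-10
   chapters, occur in strictly more than 1% of *all* condition reporters,
   and are not already mapped at category level.
2. **Evaluate** every observed 4-character code under a screened category:
   accept when reporter prevalence ≥ 2 × non-reporter prevalence.
   A ratio of exactly 2 is accepted ("at least twice"); a code absent among
   non-reporters has infinite ratio and is accepted, with a
   `zero_nonreporter` flag in the audit so reviewers can inspect these.

Two judgement calls in the original procedure are not reproducible from
any printed description and are operationalised as configuration:
"clinically relevant" becomes a per-condition chapter allowlist stored in
the code-map JSON, and the look-back window used for the prevalence
comparisons defaults to 365 days (`backward_lookback`). Prevalence means
"at least one in-window admission carrying the code", with all reporters
and all non-reporters as denominators.

The augmented map is always a superset of the input map, every evaluated
candidate appears exactly once in the audit, and conditions are processed
independently — a code may legitimately serve several conditions.

A caution demonstrated by the package's own simulations: with few
reporters (tens rather than thousands) the ratio test is noisy and will
admit spurious codes — the procedure was designed for registry-scale
cohorts, and small-sample use should review the audit trail rather than
trust the augmented map blindly.

## Subcategory sensitivities

Each mapped code may carry a free-text subcategory label (cause /
manifestation / consequence / other, or condition-specific labels such as
insulin-dependent diabetes); unlabelled codes fall into *other*.
`subcategory_sensitivity()` computes, per (condition, subcategory), the
sensitivity of the patient report among patients flagged through that
subcategory's codes. Subcategories overlap — a patient carrying codes from
two subcategories enters both denominators — so these are not a partition
and their denominators sum to more than the condition's flag count in
general, though each denominator never exceeds it. Only sensitivity is
computed at this level: specificity and kappa against a code *subset* have
no useful interpretation when the complement includes patients flagged by
the condition's other codes. `forest_table()` and `autoplot()` produce
forest-plot-ready output.

## The synthetic cohort generator

`simulate_cohort()` emulates the data-generating situation the pipeline is
built for, with every distortion the cohort builder must handle:

- latent true disease status per patient and condition, Bernoulli with
  configurable prevalence — defaults approximate administrative
  prevalences observed in English arthroplasty patients (e.g. heart
  disease 0.18, high blood pressure 0.50, liver disease 0.006);
- questionnaire answers as a noisy report of truth, with per-condition
  reporting sensitivity and specificity — defaults in the range observed
  for self-report (diabetes 0.875/0.99 down to kidney disease 0.19/0.99);
- one index admission per patient plus a Poisson number (mean 1.5) of
  prior admissions dated uniformly over a 1826-day history; each admission
  carries mapped codes with per-admission coding sensitivity 0.7 and false
  positive rate 0.002, independently across admissions given truth, plus
  1–3 benign filler codes in shuffled positions (capped at 20);
- duplicate questionnaires (1.4% of patients; exact copies with a new row
  id — the simplest adversarial case, since real duplicates' content is
  unobserved), repeat procedures (13%; a second, later index admission
  with its own linked questionnaire), and high-count responders (0.08%;
  exactly 8 conditions ticked, safely above the ≥ 7 exclusion threshold).
  These three rates match the orders of magnitude seen in national
  PROMs–HES linkage.

Everything is deterministic given the configuration seed, byte-for-byte
through `write_cohort()`. Three-character seed codes are refined with a
random final digit when emitted, so generated data exercise prefix
matching.

What the generator does *not* emulate — and hence what green tests do not
show about real data: demographic covariates and their confounding,
severity gradients within conditions, correlated comorbidity (conditions
are independent given nothing), coding practices that vary by hospital or
year, and probabilistic linkage error (keys are exact). Real-data analyses
should treat the pipeline as validated mechanics, not as evidence about
real reporting behaviour.

## Problem sizes and numerical conventions

The test suite exercises the statistics against direct formula evaluation
on 10⁴ random tables (agreement to 10⁻¹²), the data stages against naive
per-patient enumeration on cohorts of up to 500 patients, and interval
coverage on one hundred 20,000-patient single-condition cohorts with the
generator's truth as the administrative reference — sizes chosen so the
whole suite runs in minutes while keeping Monte-Carlo error small relative
to the properties asserted. One caution on the coverage check: a 95%
interval measured on 100 replicates covers in a Binomial(100, ≈ 0.95)
number of them (the exact Wald coverage at those conditions is 0.9501), so
counts of 92–94 are ordinary; the suite's fixed-seed run yields 93 for
sensitivity and 92 for specificity.

Other conventions, fixed and documented rather than configurable:
percentages are displayed to 1 decimal place and kappa to 2 (full
precision is always retained in the tibbles); proportion intervals are
truncated to [0, 1] and kappa intervals to [−1, 1]; ICD-10 codes are
normalised to uppercase, dot-free, at most 4 characters, and anything not
matching `letter digit digit [alnum]` is rejected with the offending text
in the error.

## Known limitations

- The shipped default code map is a labelled reconstruction, not any
  study's authoritative list; analyses of real data should supply their
  own map.
- The administrative reference standard is itself imperfect; sensitivity
  and specificity computed against it measure agreement, not accuracy.
- Backward coding inherits the reference standard's circularity: codes are
  admitted because reporters carry them, so the augmented map must not be
  read as clinical ground truth.
- Only inpatient-style admission records are modelled; outpatient,
  primary-care and death-registry sources are out of scope, as are
  prevalence-adjusted kappa variants and multi-rater statistics.
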