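---
title: "Ensembles of weak label sources for marital-status phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensembles of weak label sources for marital-status phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maritalens)
```

## The problem

A patient's marital status — and especially a *change* in status between
hospital admissions — correlates with depression, substance abuse and other
outcomes. The structured demographics field that records it is unreliable:
it may be empty, it may be stale (carrying a status the patient no longer
has), and it collapses non-cohabiting relationships into "single". Clinical
notes carry better signal in their social-history sections, but individual
extraction models degrade badly on data they were not trained on.

`maritalens` treats every imperfect source — the structured field and two
text extractors — as a *weak annotator* and builds labels in three steps:
harmonize the per-annotator labels, aggregate them with a voting rule, and
train a student classifier on the resulting pseudo-labels to recover the
recall the voting rules sacrifice.

## Label space and harmonization

Marital labels form a closed vocabulary: `MARRIED`, `SINGLE`, `PARTNERED`,
`DATING`, `SEPARATED`, `DIVORCED`, `WIDOWED`, `NOT_GIVEN`. Two points are
deliberate:

* `DATING` is *derived*, never emitted by a base annotator. A `PARTNERED`
  call is only trustworthy when the same note shows the patient living with
  the partner. Without that evidence, stage-1 processing
  (`recode_partnered()`) demotes the call to `SINGLE`; stage-2 processing
  (`derive_dating()`) instead assigns the derived `DATING` category, giving
  a more granular outcome analysis. Both functions are idempotent and touch
  only `PARTNERED` inputs, which the test suite checks over the exhaustive
  8 × 3 input grid.
* An `ENGAGED` category is excluded throughout: it is too rare to analyse,
  and the generator never emits it.

How a missing living-arrangement label should interact with the recoding is
genuinely open; the package takes the conservative reading that *anything*
other than positive cohabitation evidence demotes `PARTNERED`. The
alternative only matters for notes that assert a partner but say nothing
about living arrangement, and can be explored by supplying a custom
cohabitation detector, since any `text -> cohabitation` function can stand
in for the built-in lexicon rule.

## The four aggregation rules

Given the ordered vote triple (structured, model A, model B):

* **Unanimous vote** returns the common label, else abstains (`NOT_GIVEN`).
* **Majority vote** returns any label with ≥ 2 votes, else abstains.
  `NOT_GIVEN` counts as an ordinary vote value: two annotators agreeing that
  nothing is stated *is* a decision. This is the simplest consistent
  reading; the alternative (ignoring `NOT_GIVEN` votes) would let a single
  noisy annotator label a silent note.
* **Precision selection** scores each (annotator, predicted label) pair by
  that annotator's per-class precision on a disjoint tuning split and
  returns the champion cell's label. The per-class interpretation is chosen
  over "single globally best annotator" because the latter collapses the
  ensemble onto one base model, which could then never outperform all three
  sources; the per-model variant remains available via
  `precision_select(..., mode = "per_model")`. Cells never predicted on the
  tuning split have undefined precision; they participate as 0 in the argmax
  (never trust a never-validated prediction) and are flagged in the table.
  Exact ties resolve by a fixed annotator priority (model A > model B >
  structured, the order of the text models' typical headline F1).
* **Random forest** learns which configuration of the 5 categorical vote
  features (3 marital + 2 living votes, one-of-K encoded) to trust. The
  meta-learner can discover, for instance, that model B should be believed
  whenever it disagrees with the other two — something no symmetric voting
  rule can express; a seeded test constructs exactly that situation and
  checks the forest beats the majority vote held out. Defaults are 200
  trees, depth ≤ 8, per-split feature subsampling (the conventional
  choices; the rule is cheap at any of them). Tree-level predictions are
  aggregated in-package by plurality with a fixed class-order tie-break so
  inference is fully deterministic. The fit is delegated to `ranger`.

Abstention is monotone by construction: the unanimous rule abstains on a
superset of the majority rule's abstentions.

## Weak supervision: the student

Each ensemble pseudo-labels the unannotated pool. For the abstaining
strategies an abstention is "no decision", not "no information in the
note", so those records are dropped from the training pool; a `NOT_GIVEN`
*prediction* from the precision or forest strategy is kept as a class
(whether abstentions should train the student at all is configurable via
`include_abstained`, since either convention is defensible).

The student is a bag-of-ngrams (unigrams + adjacent bigrams, lowercase
alphanumeric tokenization) multinomial logistic classifier with an L2
penalty, fit by `glmnet` along a warm-started path down to a fixed penalty
of `1e-3` (fitting the single small penalty directly is numerically
unstable in coordinate descent). A transformer encoder could be slotted in
behind the same `text -> label` interface; the mechanism under study —
pseudo-label, then fit a text model that cannot abstain — does not depend
on the encoder. Vocabulary terms need ≥ 2 occurrences; classes with fewer
than 2 pseudo-labels cannot be fit and are set aside. The model serializes
to JSON at full floating-point precision and round-trips exactly.

The student raises recall for a simple reason: it assigns a definite label
to every note, including the teacher's abstentions, so whenever its
conditional accuracy on abstained notes is positive it recovers recall the
teacher forfeited. The test suite constructs a setting where the majority
teacher abstains on roughly 30% of notes (a frequently missing or stale
structured field plus two 0.70-accurate text models) and asserts the
student's macro recall exceeds the teacher's on held-out gold labels.

## Evaluation conventions

`evaluate_labels()` reports per-class precision/recall/F1/support, macro
averages, support-weighted averages, and micro accuracy. Weighted recall
equals accuracy identically (each gold item contributes its class's recall
numerator exactly once); this identity is fuzz-tested on 1000 random
gold/prediction pairs and anchors the reported tables. Zero-denominator
cells score 0 and carry a flag. Classes with zero gold support are excluded
from macro averaging by default so an empty class cannot distort the macro
score, but `include_zero_support = TRUE` reproduces the alternative
convention (both occur in practice when rare classes are kept in the label
space). `NOT_GIVEN` is scored as an ordinary class: annotated test sets
genuinely contain notes that state nothing.

## Cohort construction and outcome statistics

Timelines are long admission-level tables. Eligibility requires at least two
admissions whose first-to-last span is at most 5 years, measured inclusively
in days (1826). Whether the 5-year rule constrains the full span or each
consecutive gap is ambiguous in the field; full-span is the default and
`mode = "consecutive"` is provided.

Change classification compares the *first and last definite* labels —
intervening admissions, including `NOT_GIVEN` ones, are ignored — into
`SAME`, `GOT_MARRIED` (last label `MARRIED`, different first), or
`OTHER_CHANGE` (a `DATING` ↔ `PARTNERED` move counts as a change). Patients
with fewer than two definite labels are excluded with a logged reason.

Age matching downsamples the larger groups toward the reference group's
5-year age-bin distribution until all group means agree within a tolerance
(default 1 year), seeded and deterministic; an impossible match (no
overlapping bins, or insufficient overlap) is an error with diagnostics
rather than a silent partial match.

Proportions use Clopper–Pearson intervals from Beta quantiles — exact and
conservative (coverage ≥ nominal), which matters at the small event counts
a change cohort produces. The implementation is cross-checked against
`binom.test` and its coverage is verified by simulation at p = 0.07,
n = 139. New diagnosis means off-at-first, on-at-any-later admission;
recovery means on-at-first, off-at-last; both use the group size as
denominator and are disjoint for one condition by construction. Comorbidity
scores are compared by Mann–Whitney rank-sum tests (exact when both groups
have ≤ 8 observations and no ties, tie-corrected normal approximation
otherwise) with Holm step-down adjustment across group comparisons.

## What the synthetic data emulates — and what it does not

`generate_corpus()` renders templated social-history snippets: ≥ 3 cue
sentences per marital class, living-arrangement sentences, and filler about
tobacco/alcohol history. Within a class the templates use only that class's
cue lexicon, so the pattern annotator has a verifiable 100% ceiling on
noise-free text, and corruption tests can degrade it monotonically. The
default class mix follows the composition of a 322-note annotated tuning
set (married 117, single 53, partnered 49, widowed 42, divorced 34, not
given 21, separated 6). The structured field stores the status token except
when missing (default 10%) or stale — a stale field stores a uniformly
chosen *other* status's token, emulating outdated demographics (and the
structured dictionary records dating patients as `SINGLE`).

`generate_cohort()` draws ages from a normal distribution centred at 57
years (SD 15, truncated to 18–95; only the mean is pinned down by published
cohort descriptions, the rest is declared), admission counts as
2 + Poisson(1), inter-admission gaps uniform on 0.5–6 years (declared; the
upper end deliberately exceeds the 5-year filter so eligibility is
exercised), statuses from a sticky first-order transition chain whose
initial distribution follows published static group sizes (married 3774,
divorced 592, partnered 486, single 262, dating 159, widowed 62), and an
integer comorbidity score per status (Poisson; married mean 5, divorced 7,
matching the published medians' ordering).

Condition flags per patient and condition are drawn by case assignment:
new-diagnosis case with probability `new_diagnosis_prob`, recovery case
with `recovery_prob` (both read per change/same group; defaults are the
published rates), otherwise a constant flag at the adjusted prevalence
`(prev − p_rec) / (1 − p_new − p_rec)`. This makes the patient-level event
rates equal the configured probabilities exactly in expectation *and*
keeps the first-admission prevalence at the configured per-status value;
the adjustment clamps at 0 when a group's recovery probability exceeds its
prevalence, in which case first-admission prevalence is mildly inflated.
Prevalence defaults reuse published married/partnered/dating/widowed rates;
the cells no publication pins down (single and divorced prevalences, dating
drug abuse, partnered depression) are declared package defaults chosen at
plausible ICU-population levels, set once and documented here.

What passing tests on this generator show: the aggregation algebra, the
recall mechanism of weak supervision, the metric identities, and the
cohort statistics are implemented correctly, and parameters fed into the
generator are recovered by the estimators. What they do not show: template
text is linearly separable, so student accuracies near 1.0 are a property
of the fixture, not a performance claim about clinical notes; no negation,
temporality, misspelling or cross-institution documentation drift is
simulated, and real extraction metrics cannot be reproduced without the
restricted source data and the original pretrained extractors.

## Reproducibility and numerical choices

Every stochastic function takes an explicit seed; generators save and
restore the caller's RNG state. Pipeline stages derive their seeds from the
master seed by `module_seed(master, stage)` so any stage can be rerun in
isolation. `run_experiment()` writes a manifest (config hash, seed, row
counts, per-artifact MD5) and identical configs produce byte-identical
artifacts; the suite asserts this. The demo configuration (5000 notes, 5000
patients) runs the full pipeline in well under a minute on one CPU; tests
use 600–5000 notes and 60–10000 patients, sizes at which the asserted
frequency properties hold within 4 binomial standard errors. Categorical
frequency checks use 4 SE; deterministic identities use exact or 1e-12
tolerances. The rank-sum test switches from exact enumeration to the
normal approximation exactly at n = 8 per group.

## Known limitations

* The two text annotators are cue-lexicon extractors with injected
  confusion noise, not learned models; rule precedence (widow > divorce >
  separation > marriage > partner > single) is fixed.
* The student is a linear bag-of-ngrams model; it inherits the template
  world's separability.
* Static-group prevalence figures for groups the publications do not print
  are package defaults, not estimates.
* No significance testing between label sources is provided, and
  direction-specific change analyses (e.g. divorce vs widowhood) are out of
  scope at the cohort sizes the change group yields.
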