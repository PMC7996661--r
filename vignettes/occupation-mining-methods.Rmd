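---
title: "Methods: mining occupations from psychiatric free text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining occupations from psychiatric free text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the models, the
conventions we chose where several were defensible, and what the synthetic
evaluation does and does not establish.

## The task

Coded occupation fields in psychiatric records are sparsely completed, but
clinicians describe occupations freely in narrative text, especially in the
*personal history* section of an assessment. The extraction task has two
coupled parts: find the **occupation mention** (a title such as "builder",
a description such as "construction", or a status such as "unemployed"),
and assign its **relation** — whose occupation it is: the patient's, a
family member's, a clinician's, or some other person's. Only
patient-relation extractions feed patient-level analyses. Temporality
(whether the occupation is current or past) is deliberately out of scope:
the text rarely supports it.

## Document model and annotation conventions

Character offsets are 0-based and half-open over Unicode code points; a
span's surface string must equal its text slice exactly, and a mismatch on
read is an error rather than a warning, because it means text and
annotations have drifted apart. Standoff files use a BRAT-style dialect
(`T` span lines, `A` attribute lines for relation, kind and normalised
label) chosen over XML formats for greppability and trivial round-trip
testing. Identical duplicate annotations collapse silently on read;
conflicting annotations on the same span are kept — arbitration belongs to
the evaluator, not the parser. Documents from patients under 16 never enter
a corpus; the reader applies the age gate and reports the excluded count.

## Section extraction

Headers are matched line-anchored and case-insensitively, tolerating a
trailing colon and whitespace; a section runs from the first
non-whitespace character after its header to the start of the next
recognised header line (personal-history or stop header) or end of
document. We require the colon-or-end-of-line after the header phrase so
that narrative sentences beginning "Personal history was..." do not open a
section. When no header matches, downstream stages treat the whole document
as out-of-section text rather than discarding it.

## Mention detection

The detector is the union of two arms.

The **gazetteer** arm matches a lexicon of surface phrases
(case-insensitive, whole tokens, longest-match, left-to-right,
non-overlapping), each carrying a normalised label and a kind
(title/description). Statuses — student, unemployed, retired, carer,
self-employed — are first-class targets because at patient level they
dominate what records actually say about occupation.

The **sequence-model** arm is a linear-chain conditional random field over
BIO tags. Features per token: lowercase form, capitalisation/digit/
punctuation shape flags, gazetteer-hit and gazetteer-begin flags, kinship
and clinician cue flags, and personal-history membership — each for the
token and its neighbours within two positions, plus a bias. Training
maximises the L2-penalised conditional log-likelihood (λ = 0.1, at most 100
L-BFGS iterations) from a zero start, with forward–backward and Viterbi in
compiled code; there is no stochastic element, so retraining with the same
corpus is bit-identical. The regularisation strength and iteration cap are
conventional defaults for CRFs of this size, set once and recorded in the
model metadata along with the corpus hash and tokenizer version; a model
refuses to label text tokenised by a different tokenizer version.

Overlapping candidates resolve by a fixed precedence: the longer span wins;
equal lengths go to the gazetteer span because it carries a normalisation;
remaining ties go leftmost. CRF-only spans whose surface has no gazetteer
entry receive the label `other`. This mirrors a practical reality: a
sequence model can recognise that *something* is an occupation from context
("works as a …") without knowing its canonical form. `other` extractions
are retained in evaluation (matching is by span and relation, not label)
but excluded from patient profiles, where an unnormalisable label is more
noise than signal.

## Relation classification

A linear-kernel SVM (C = 1) with probability outputs is trained on gold
mentions, over deliberately few, fully deterministic features: nearest
preceding pronoun, kinship cue within five tokens left, clinician cue
within five tokens left, non-kin person cue (friend/neighbour/colleague)
within five tokens left, section membership, and token distance from
sentence start. The non-kin person cue is ours: without it the
`other_person` class is indistinguishable from `patient` in cue space. We
use libsvm's native pairwise multiclass scheme with pairwise-coupled
probabilities; the probability calibration consumes R's RNG, so a seed is
part of the training contract.

Rules take precedence over the model, in a fixed order: a clinician cue
forces `clinician`, then a kinship cue forces `family`, then the model
label stands if its probability reaches 0.4, otherwise the fallback is
`patient` inside a personal-history section and `other_person` outside.
Clinician-first ordering is a safety choice: misattributing the care team's
job titles to the patient is the dominant false-positive mode in this
domain, and a rule that fires on "Seen by Dr …" should never be outvoted by
a statistical model. The 0.4 threshold is a coarse abstention level for a
four-class problem (chance is 0.25); performance is insensitive to it on
the synthetic corpus because cue contexts are strong.

The **healthcare occupation filter** then re-labels (never deletes) any
patient-attributed annotation whose normalised label is on the filter list
— variations on psychiatrists and doctors, therapists, nurses and social
workers. Re-labelling rather than deletion keeps the extraction auditable
and makes the invariant simple: after filtering, no patient-attributed
annotation carries a healthcare label, and applying the filter twice equals
applying it once. The shipped list is a starter set and is configurable; a
consequence, mirrored deliberately from the application domain, is that the
pipeline never outputs a patient-held healthcare occupation. The synthetic
generator therefore never emits one either.

## Evaluation

A *strict* true positive requires identical span and identical relation;
`span_only` and `lenient_overlap` (≥1 character overlap plus relation
match) exist for sensitivity analysis, and relaxation is monotone: lenient
scores can never fall below strict ones on the same corpora. Matching is
one-to-one, greedy by start offset with leftmost-first tie-breaking,
implemented with augmenting-path repair so the matching is always of
maximum cardinality — the tests verify equality with an exhaustive
maximum-matching oracle. Precision and recall are micro-averaged pooled
counts; 0/0 ratios are reported as `NA`, never 0, so an empty run cannot
masquerade as perfect or failing.

Cohen's kappa units are a package convention, stated in every report: for
occupation-title agreement, units are per-token binary decisions (inside
any mention vs not); for relation agreement, units are mention pairs
aligned by span overlap, with the relation labels as categories.

## The synthetic corpus

The generator is template-based — sentence templates with slots filled from
the lexicon — because ground truth must be exact and the generator
auditable. It emulates: personal-history sections under the default
headers; patient, family and other-person occupation sentences at
configurable per-sentence rates; clinician "trap" sentences ("Seen by Dr
Patel, consultant psychiatrist") that carry gold `clinician` annotations;
distractor idioms ("working on his anxiety") that contain work-like tokens
but no annotation; a structured field completed for 14% of patients with
13 opaque status codes; and an occupation frequency ranking in which
"student" and "unemployed" dominate, with titles and descriptions on a
Zipf-like tail. A small set of titles is excluded from the shipped
gazetteer but still generated, so a dictionary-only detector has a
measurable recall ceiling and the CRF's contribution is testable. Patients
receive one to four persistent occupations, re-mentioned across their
documents; with roughly three documents per patient this puts the median
distinct-occupation count per extracted patient at 2–3, the right order of
magnitude for register data.

Splitting is by patient, not document, so no patient contributes to both
training and evaluation; split sizes can deviate from requested counts only
by whole-patient rounding (in practice they are hit exactly at the corpus
sizes used).

What the generator does **not** emulate: realistic clinical prose,
spelling errors, negation, coreference, temporal expressions, or the
long-tail vocabulary of real records. Passing the end-to-end performance
floor (strict patient-scope precision and recall ≥ 0.75 on 666 held-out
documents) therefore demonstrates that the pipeline's machinery — feature
extraction, training, decoding, precedence rules, filtering, scoring — is
correct and stable, *not* that these performance levels transfer to real
EHR text, which is substantially harder.

## Association models

The patient-level outcome is binary: at least one occupation from the
structured field or from qualifying text extractions (`other` and
healthcare-filtered labels never qualify). For each categorical predictor
we fit crude, service-adjusted (events and bed-days bands) and fully
adjusted logistic regressions — standard maximum-likelihood `glm` fits, as
this stage is conventional epidemiology; the bespoke content of the package
is everything upstream. Odds ratios carry Wald 95% intervals; each
variable's overall association is a likelihood-ratio test against the
nested model. Reference levels report OR = 1 with an empty interval.
Suspected separation (|log OR| > 10 or SE > 100) is flagged per level and
reported as `NA`; collinearity management — e.g. dropping redundant
service-contact measures — is the caller's responsibility. Every level
keeps an explicit `not known` category rather than dropping missing data.
A calibration simulator (`simulate_profiles()`) generates profiles from a
logistic model with a known odds ratio (default 2.0 for the highest
service-contact band, log-odds interpolated across bands, all other
covariates null), used to verify interval coverage and the uniformity of
null likelihood-ratio p-values.

The distinct-occupation summary reports the median together with both
quartiles *and* the interquartile width, because a bare "IQR = x" is
ambiguous between the width and the upper quartile.

## Problem sizes and reproducibility

The test suite trains on corpora of 120–550 patients; the acceptance
checks use a 550-patient corpus split 257/77/666 personal-history
documents, a 2000-patient corpus for retrieval fractions, and 100–200
replicates of 800–2000-patient profile simulations — sizes chosen so the
whole suite exercises every stage at meaningful scale on a single CPU in a
few minutes. One global seed fans out to per-stage seeds by fixed offsets,
so any stage can be re-run in isolation; every stage, re-run with the same
configuration and seed, is byte-identical, and all I/O formats round-trip
exactly.

## Known limitations

* Relations are resolved from local cues, not coreference; "He …" two
  sentences after a family member was introduced will read as the patient.
* The healthcare filter list is a starter vocabulary; real deployments
  need a site-specific list.
* Patient-held healthcare occupations are unobtainable by construction.
* The CRF feature template is a faithful-in-spirit reconstruction of what
  such pipelines use; it is versioned in the model metadata, and models
  refuse mismatched tokenizations rather than silently degrading.
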