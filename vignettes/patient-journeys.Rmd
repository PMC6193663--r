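---
title: "Mining structured patient journeys from support-group text: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining structured patient journeys from support-group text: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Online support groups (OSG) for prostate cancer hold, scattered across
thousands of threaded discussions, a longitudinal record that clinical
registries rarely capture: how men describe their diagnosis (Gleason grade,
PSA), how they arrive at a treatment decision, what factors weighed on it,
which side effects they live with month by month, and how their emotional
state evolves from diagnosis through recovery. `osgminer` turns a corpus of
such forum posts into per-patient structured journeys and group-level
trajectories. This vignette documents the models and rules it uses, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the design choices made where the design was genuinely open.

## The pipeline

The package processes a corpus in stages, each exposed as a tibble-in /
tibble-out function:

1. **Collocation** (`collocate_by_patient()`): all posts by one author are
   gathered into a single stream, ordered by timestamp with lexicographic
   `post_id` tie-breaks so every downstream result is deterministic.
2. **Clinical extraction** (`extract_gleason()`, `extract_psa()`,
   `extract_age()`): deterministic pattern rules over a documented dialect
   list. Gleason mentions are accepted in component form ("GS3+3",
   "gleason 3+4") and total form ("Gleason 7", "gleason score of 7");
   component grades must lie in 1..5 and totals in 2..10, so the additivity
   invariant `primary + secondary = total` holds for every constructed
   mention. PSA accepts "PSA 4.5" through "PSA rose from 10.2 to 15.1"
   (both values, in order) with a 10,000 ng/mL plausibility cap. Age rules
   require a self-referential context; "my father is 85" is not an age
   disclosure. We use rules rather than trained classifiers because the
   rules are auditable, extensible through a config file, and their recall
   on planted test data is exactly measurable.
3. **Decision templates**: a sentence expresses an *autonomous* decision
   when it contains, in order, a first-person subject, a decide term and a
   treatment term (`<I/We> <words>* <DECIDE> <words>* <TREATMENT>`), and a
   *paternalistic* one when a clinician-role term precedes a recommend term
   and a treatment term. Terms are sets of consumer phrasings ("opted",
   "went for", "made the call"; "urologist", "doc"; "brachytherapy",
   "da vinci", "watch and wait"), multi-word terms matching as contiguous
   token runs within one sentence. Patients with only autonomous matches
   form the Autonomous group, only paternalistic the Paternalistic group,
   both anywhere in their history the Shared group, and none remain
   Unclassified and are excluded from timeline analyses.
4. **Timelines**: the decision anchor t~0~ is the calendar month of the
   earliest matched post; every event is re-indexed to months t~-3~..t~12~
   relative to it. Side-effect mentions are matched greedily,
   longest-first, against a four-category consumer thesaurus (urinary,
   sexual, bowel, other), so "rectal bleeding" is one bowel mention and
   never additionally a generic "bleeding".
5. **Emotion scoring**: each post receives a 16-dimensional non-negative
   vector over eight positive (Happy, Good, Alive, Love, Positive, Open,
   Interested, Strong) and eight negative (Sad, Afraid, Hurt, Angry,
   Depressed, Helpless, Confused, Indifferent) categories,

   $$E_P[e] = \frac{1}{N}\sum_{m \in M_e(P)} w_m,$$

   where $N$ is the post's raw token count, $M_e(P)$ the un-negated
   lexicon matches of category $e$, and $w_m$ starts at 1 and is multiplied
   by 1.5 for every booster ("very") and 0.5 for every dampener ("kind
   of") lying wholly inside the three tokens before the match; any negator
   there zeroes the match. Without modifiers each dimension is bounded by
   1. Positive/negative composites are means over the respective eight
   dimensions.
6. **Reporting**: group trajectories (active patients, posts per active
   patient, advice-post percentage, side-effect prevalence, emotion
   composites, per relative month), decision-factor prevalence, and
   chi-squared / two-sided Student's t-test comparisons between groups.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| modifier window | 3 tokens | context scanned before an emotion term for boosters/dampeners/negators |
| booster / dampener multipliers | 1.5 / 0.5 | per-modifier intensity scaling |
| negation window (templates) | 3 tokens | a decide/recommend term preceded by a negator within it does not fire |
| factor window | 1 post | factor terms count when within this many posts of a decision match |
| timeline window | t~-3~..t~12~ | analysis months relative to the decision anchor |
| PSA cap | 10,000 ng/mL | unit-error guard, logged not fatal |
| age bands | <40, 41–50, 51–60, 61–70, >70 | upper-inclusive edges (41–50 means 41 ≤ age ≤ 50) |
| expansion k | 25 | nearest neighbours retrieved per lexicon seed term |
| embedding | 100-d (200-d at corpus scale), window 5, 5 negatives, 5 epochs | skip-gram with negative sampling |

All lexicons ship as editable TSV files under `inst/extdata/` (decision
templates, decision factors, side-effect thesaurus, 16-category emotion
seeds with provenance, intensity modifiers) so clinicians can extend the
dialects without code changes.

## Lexicon expansion

Seed emotion terms are expanded by cosine nearest-neighbour search in a
skip-gram embedding trained on the corpus (`train_embedding()`,
`expand_lexicon()`). Distributional neighbours frequently carry the
*opposite* emotional sense — a neighbour of a sadness word can be a joy
word — so candidates are never auto-accepted: `apply_review()` requires an
explicit accept/reject decision for every candidate and fails listing any
gap. Accepted terms enter the lexicon with provenance
`expanded-accepted`; the packaged lexicon already distinguishes curated
seeds from reviewed expansion terms.

The trainer is implemented in C++ (single-threaded, own RNG) specifically
so that a fixed seed yields bitwise-identical vectors across runs; no
installed R package provides skip-gram training. Frequent-bigram joining
(`a_b` phrase tokens) is available so multi-word lexicon entries can exist
in the vocabulary; it is off by default, matching standard word2vec
behaviour.

## The synthetic cohort: what it emulates, and what it does not

Real OSG corpora of the relevant scale are proprietary, so the package is
validated by parameter recovery on generated data (`generate_corpus()`).
The default configuration defines the study conditions: 300 patients,
decision-group mix 7% Paternalistic / 42% Autonomous / 28% Shared / 23%
Unclassified (the paternalistic group markedly smaller, the two other
classifiable groups comparable, roughly three quarters of patients
classifiable), treatment mix 55/30/15 surgery/radiation/surveillance,
posting activity peaking in the decision month, urinary side-effect
hazards spiking after treatment and declining while sexual side effects
persist, negative emotion density declining and positive rising across
recovery, and advice behaviour growing over the post-treatment year.

Two realization choices matter for interpreting the tests:

- **Mixtures and hazards are realized as exact counts** (largest remainder
  for the group mix; rounded counts assigned to randomly chosen included
  patients for the per-month side-effect hazards), not as independent
  Bernoulli draws. Recovery checks therefore measure extraction fidelity
  rather than binomial sampling noise; the binomial-CI comparisons are
  still computed and reported.
- **Generation is noiseless by default**: every planted item is realized
  verbatim in a dialect the extractors support, and the filler phrasebook
  is constructed to contain no lexicon terms. A correct pipeline scores
  recall = precision = 1.0, and any regression is immediately visible. An
  optional decoy layer plants negated decision sentences ("i have not
  decided on surgery") to exercise the negation guard.

What passing these tests shows is that the implementation is faithful to
its stated rules; it does **not** show that the rules capture free-form
forum language, with its typos, sarcasm, paraphrase and cross-sentence
anaphora. The generator does not emulate reply networks beyond
opener/reply status, topic drift, carer accounts, or vocabulary outside
the packaged lexicons.

Problem sizes used in the shipped tests were chosen to exercise every code
path at desk scale: the 300-patient cohort (~6,000 posts) for end-to-end
recovery, a 10,000-sentence corpus with five planted synonym pairs for the
embedding check, 10,000 random posts for the emotion-scoring invariants,
and 50 random toy embeddings for the nearest-neighbour oracle comparison.

## Numerical and design choices

- **Sentence scope for templates.** The templates are sentence patterns;
  cross-sentence anaphora is out of scope. The sentence splitter is a
  rule splitter (terminal punctuation with an abbreviation guard); exact
  boundary parity with any particular tokenizer is not required because no
  downstream quantity depends on boundaries beyond sentence-scoped
  matching.
- **"Shared" operationalization.** Both template types anywhere in the
  patient's history — the minimal reading of a mixed decision style.
  Requiring co-occurrence in one post would misclassify patients who
  relate the clinician's advice and their own choice in separate posts.
- **Decision anchor.** t~0~ is the month of the earliest template match —
  a deterministic anchor rule. Parsing explicit in-text dates ("my op was
  March 3rd") is out of scope.
- **Treatment conflicts.** The earliest match's category is used; later
  conflicting categories flag the patient (`treatment_conflict`) rather
  than reclassify, since re-biopsies and genuine treatment changes cannot
  be distinguished from typos in text alone. The same first-mention rule
  applies to conflicting age disclosures.
- **Surveillance lexicon.** The conventional abbreviation "AS" for active
  surveillance is omitted from the default treatment lexicon: after
  lower-casing it collides with the English stop word and would fire in
  nearly every sentence. "surveillance", "active surveillance" and
  "watch and wait" remain.
- **Prevalence denominator.** Side-effect trajectory curves report the
  percentage of the group's patients with at least one mention in the
  month (patient-level), not mention counts — stable under differences in
  posting volume.
- **Mean posts per patient** divides by *active* patients that month, the
  engaged-patient reading of activity curves.
- **Negation zeroes, never transfers.** A negated emotion term contributes
  nothing; the 16 categories define no antonym mapping, so transferring
  intensity to an opposite category would be invention. A known limitation
  follows: idioms like "never felt so alive" score zero.
- **Emotion denominator** is the raw token count before any phrase
  joining, and a phrase match contributes weight 1 regardless of length,
  keeping each dimension bounded and insensitive to phrase-joining
  details.
- **Aggregate emotion scale.** All intensities are non-negative
  proportions, and so are their means; signed "aggregate emotion" values
  sometimes quoted for such trajectories cannot arise from this scoring
  rule without an additional centring transform, which this package does
  not apply. Raw means are reported.
- **Statistics.** Pearson chi-squared without continuity correction (the
  2×2 closed form), pooled-variance Student's t by default with Welch
  behind a flag, raw p-values by default with optional Benjamini–Hochberg
  adjustment. Degenerate t inputs follow an explicit contract: equal-mean
  constant samples give t = 0, p = 1; unequal-mean constant samples are a
  fatal error.
- **Determinism everywhere.** Ties are always broken lexicographically,
  generation and training consume a single seed, and a repeated
  simulate-run-export cycle produces byte-identical CSVs (the metadata
  sidecar records seed, config hash and versions, never wall-clock time).

## Limitations

Rule-based extraction inherits the lexicons' blind spots: unlisted
paraphrases, misspellings and sarcasm are missed, and the advice
classifier is a transparent heuristic (reply + second-person
recommendation pattern + not question-dominated) whose accuracy is
established only on labelled fixtures. Author identity is taken from the
input `patient_id`; resolving carers vs patients, or one person across
forums, is upstream of this package. Hormone therapy and chemotherapy are
not treatment categories, and active surveillance is not distinguished
from watchful waiting.
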