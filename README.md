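# osgminer

Online support groups (OSG) for prostate cancer accumulate years of
free-text discussion in which patients disclose their diagnosis (Gleason
grade, PSA level, age), narrate how they chose a treatment, and report side
effects and emotions month after month. That record is invisible to
clinical registries. `osgminer` turns a corpus of forum posts into
structured per-patient journeys and group-level trajectories, for
researchers in patient-reported outcomes, shared decision-making and
health-services research.

## What it computes

Given posts `(post_id, patient_id, thread_id, forum, timestamp, text)`:

- **Patient collocation** — each author's posts gathered into one
  chronological stream (deterministic timestamp/post_id ordering).
- **Clinical markers** — rule-based extraction of self-disclosed age,
  Gleason score in component ("GS3+4") and total ("Gleason 7") dialects
  with the `primary + secondary = total` invariant enforced, and PSA
  values ("psa was 4.5", "PSA rose from 10.2 to 15.1").
- **Decision behaviour** — sentence templates
  `<I/We> <words>* <DECIDE> <words>* <TREATMENT>` (autonomous) and
  `<DOCTOR> <words>* <RECOMMEND> <words>* <TREATMENT>` (paternalistic),
  with a 3-token negation guard. Only-autonomous patients form the
  Autonomous group, only-paternalistic the Paternalistic group, both the
  Shared group; unmatched patients are excluded by the inclusion filter.
  The decision month t0 is the earliest matched post's month; decision
  factors (doctor experience, side effects, cost, ...) are mined within a
  ±1-post window of decision posts.
- **Side-effect timelines** — mentions in four consumer-language
  categories (urinary, sexual, bowel, other), bucketed monthly over
  t−3..t+12 relative to t0, with out-of-window events counted, never
  silently dropped.
- **Emotion trajectories** — a 16-dimensional vector per post (8 positive,
  8 negative categories): for category *e*,
  `E_P[e] = (Σ un-negated matches of e, weighted) / N`, where `N` is the
  post token count and each match weight is multiplied by 1.5 per booster
  ("very") and 0.5 per dampener ("kind of") in the 3 preceding tokens; a
  negator zeroes it. The lexicon can be expanded by cosine
  nearest-neighbour search in a skip-gram embedding
  (`train_embedding()`, `expand_lexicon()`), with mandatory human review
  (`apply_review()`) because distributional neighbours can carry the
  opposite emotional sense.
- **Aggregates and tests** — per group (decision behaviour, treatment, or
  age band) and relative month: active patients, posts per active patient,
  advice-post percentage, side-effect prevalence, emotion composites;
  chi-squared and two-sided Student's t-test comparisons.
- **Synthetic cohorts** — `generate_corpus()` plants decision groups,
  treatments, t0, disclosures, side-effect schedules, emotion-density
  ramps and advice behaviour with full ground truth, so every stage is
  testable end to end by parameter recovery (`score_recovery()`).

## Worked example

```r
library(osgminer)

sim <- generate_corpus(simulation_config(n_patients = 40, seed = 7))
res <- run_pipeline(sim$posts)
res
#> <osg_pipeline> 823 posts, 40 patients; included 31/40 (77.5%)

dplyr::count(res$assessments, group)
#> # A tibble: 4 × 2
#>   group             n
#> 1 Autonomous       17
#> 2 Paternalistic     3
#> 3 Shared           11
#> 4 Unclassified      9
```

31 of 40 patients disclosed a treatment decision in template form and pass
the inclusion filter (77.5%); the Paternalistic group is the smallest, as
configured. Trajectories read per group and relative month — advice-giving
grows after treatment while urinary side effects appear post-surgery:

```r
dplyr::filter(res$trajectories, rel_month %in% c(0, 6))[,
  c("group", "rel_month", "n_active_patients", "advice_post_pct", "urinary_pct")]
#>   group         rel_month n_active_patients advice_post_pct urinary_pct
#> 1 Autonomous            0                17           13.2         5.88
#> 2 Autonomous            6                13           31.2        17.6
#> 3 Paternalistic         0                 3            0           0
#> 4 Paternalistic         6                 2           66.7         0
#> 5 Shared                0                11            9.09        9.09
#> 6 Shared                6                 9           50          18.2
```

Recovery against the planted ground truth is exact on the noiseless
generator (`tidy(score_recovery(sim, res))` reports accuracy 1.0 for
groups, treatments, t0, clinical values, factors and advice labels, with
monthly emotion composites rank-correlating 0.96/0.91 with the planted
density ramps at this cohort size). Individual extractors work on plain
strings too:

```r
extract_gleason("the biopsy came back GS3+4")
#>   primary secondary total
#> 1       3         4     7

compute_emotion_vector(tokenize("very happy but not happy")$tokens)[1:4]
#> Happy  Good Alive  Love
#>   0.3   0.0   0.0   0.0   # boosted first match (1.5), negated second (0), N = 5
```

A thin CLI over the same functions lives at `inst/cli/osgminer.R`
(`simulate`, `ingest`, `run`).

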