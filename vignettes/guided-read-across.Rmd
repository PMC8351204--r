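---
title: "Guided read-across, study reliability and the TTC decision tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guided read-across, study reliability and the TTC decision tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxra)
```

## The problem

Read-across fills a data gap for a target chemical with experimental
results from analogues. Its credibility rests on two questions that this
package quantifies separately and then combines: *how good is the
analogue* (structural and physicochemical similarity) and *how good is
the study* being read across (design completeness and expert
interpretability). The package implements the full chain — candidate
search, similarity scoring, alert profiling, study grading, probabilistic
evidence combination, endpoint bounding — plus an independent non-cancer
TTC screen for exposure-driven waiving.

## Similarity model

Structure-based similarity is the Tanimoto coefficient over fingerprint
bit sets. Two bundled fingerprints (a 1024-bit path-based topological
fingerprint and the 166 structural keys, both via OpenBabel) cover the
common use; a SMARTS-library fingerprint turns any alert collection into
an interpretable chemotype fingerprint. Similarity search enforces a
floor of 0.65 on the threshold (below that, fingerprint similarity stops
being meaningful as an analogue criterion) and defaults to 0.7, the
conventional working threshold.

Property-based similarity operates on z-scores: each property is
standardised against the mean and standard deviation of a reference
population before comparison, so that heterogeneous units (g/mol, Å²,
log units, counts) contribute comparably. Two measures are provided:

- Pearson similarity `(1 + r) / 2`, sensitive to the *pattern* of the
  property vector;
- Euclidean similarity `1 / (1 + d)`, sensitive to its *magnitude*.

They answer different questions and the workflow carries both; the
Euclidean variant is the default input to evidence combination because it
is the stricter of the two (a candidate can correlate almost perfectly
with the target while sitting far away in property space — the hair-dye
example below shows exactly this, Pearson 0.90–0.999 against Euclidean
0.48–0.88).

Analogue Quality is the geometric mean of the chosen measures
(`analogue_quality()`). The geometric mean is deliberate: the measures
are jointly necessary lines of evidence about one pairing, so a single
near-zero measure should collapse the score, which an arithmetic mean
would not do. It follows that min ≤ AQ ≤ max of the inputs, that AQ is
monotone in each input, and that AQ of N equal values is that value —
all of which are tested as properties.

Reported values are rounded half away from zero to two decimals
(`round_half_up()`); internal arithmetic is full precision. The
distinction matters: a candidate with AQ 0.6256 and study reliability
0.9 has read-across reliability 0.5631, which reports as 0.56 — rounding
the AQ first would give 0.63 × 0.9 = 0.567 → 0.57, a different reported
value.

## Descriptors and the reference statistics

Descriptors (`compute_descriptors()`) come from OpenBabel: molecular
weight, TPSA, logP, H-bond donors/acceptors, molar refractivity, plus a
SMARTS-counted rotatable-bond number and a simple graph-complexity index
(`bonds · log2(atoms) + 2·rings + heteroatoms`). Published descriptor
tables often come from other engines whose logP or complexity models
differ; `attach_property_table()` therefore lets externally supplied
values override computed ones per compound, with provenance flags, so
that literature tables can be reproduced exactly without re-implementing
proprietary models. Dot-disconnected SMILES (salts, mixtures) are reduced
to the largest organic fragment for all structure-derived computation.

The bundled reference statistics (`default_reference_statistics()`) are
*example-calibrated*: they are back-solved by least squares from the raw
and standardised property values of the bundled paraben example (the
degenerate TPSA column, constant across the four parabens, is pinned by
one chosen pair: mean 62.7, sd 60). They make the worked example
self-contained; for real analyses users must supply reference statistics
derived from a relevant structure collection via
`reference_statistics()`.

## Study reliability

`minis_grade()` maps the outcomes of sixteen minimum-inclusion-criteria
rules to a 1–5 grade by failure count (0 → 5, 1–2 → 4, 3–4 → 3, >4 → 2),
with summary-only studies pinned at grade 1. The rule *texts* are
organisation-specific and are inputs, not code: the package consumes
pass/fail outcomes (16-character `P`/`F` strings in study records).
Opinion Scores (1 = conclusion barely interpretable … 5 = fully
interpretable) are expert judgement and are never computed. The default
grade × opinion likelihood grid spans 0.5–1.0 and is monotone in both
coordinates; custom grids are allowed but validated
(`validate_reliability_table()`).

## Evidence combination

The point estimate of read-across reliability is the joint probability
AQ × SRL — appropriate because analogue quality and study quality are
independent sources of evidence. Qualification applies two floors:
both quantities must reach 0.7 for the candidate to act as an analogue,
and SRL below 0.5 marks the data as unusable outright (checked first).

For an uncertainty interval the package uses Dempster–Shafer theory over
the frame {reliable, not reliable}: each score becomes a discounted mass
function (`build_mass()`: mass d·s on "reliable", d·(1−s) on "not
reliable", 1−d of ignorance, discount d defaulting to 0.9), combined by
Dempster's rule (`dst_combine()`), read out as belief/plausibility. The
mass-assignment model is a design choice of this package — published
applications of DST to read-across parameterise it differently — so the
DST layer is validated by its algebraic properties (commutativity,
vacuous-mass identity, normalisation, belief ≤ plausibility, interval
width shrinking as d → 1) rather than against any single published
interval.

## NOAEL bounds

`noael_bounds()` treats the nearest-neighbour NOAELs as a normal sample.
Three interval conventions are provided because the literature is not
specific about which is meant by a "95 % confidence interval" on such a
set: `normal_sd` (mean ± z·sd, the default and the literal reading of
"assuming a normal distribution of NOAEL values"), `normal_mean_ci`
(mean ± z·sd/√n), and `lognormal_sd` (the first form on the log scale,
arguably the most defensible for dose data but not the default, to keep
the default the literal convention). Lower bounds clip at zero. A single
neighbour is an error instructing the caller to report that NOAEL with no
interval — fabricating an interval from one value would be worse than
honest absence. Neighbour selection (`nearest_neighbor_noaels()`) uses
fingerprint similarity at 0.7 and can exclude neighbours hitting a
structural alert (e.g. removing reproductive-toxicant profiles when the
target lacks them).

## Alert profiling and enrichment

`match_alerts()`/`screen_library()` run SMARTS libraries against
compounds. The bundled library is a small curated illustration (pro-
quinoid liver alerts, aromatic nitro/amine/azo DNA binders, a
nitroaromatic-ether reproductive alert); any public chemotype collection
loads through the same CSV/JSON format. Endpoint enrichment per chemotype
(`enrichment_z()`) is a pooled two-proportion z statistic comparing the
endpoint rate inside the chemotype subset against its complement — the
exact statistic behind published chemotype heat maps is not always
stated, and this choice is documented rather than claimed canonical. The
z bins are `strong_neg` (z ≤ −2), `neg` (−2, −1], `neutral` (−1, 1],
`pos` (1, 2), `strong_pos` (z ≥ 2); the boundary z = 1 goes to neutral
because the neutral interval is closed above, and the five bins
partition the line.

## TTC decision tree

`ttc_evaluate()` implements the non-cancer path: cohort-of-concern fail
(metals or metal-containing compounds — evaluated on the largest organic
fragment, so simple counterions do not trigger it — and polyhalogenated
dibenzo-p-dioxin/dibenzofuran/biphenyl cores with ≥ 2 aromatic
halogens), then the organophosphate branch (18 µg/person/day), then the
Cramer-class threshold (1800/540/90 µg/person/day). Only the Class III
value is anchored in the worked example this package reproduces; Class
I/II and the organophosphate threshold are editable configuration
defaults from the standard published TTC scheme. Threshold comparisons
are strict (exposure equal to the threshold fails, conservatively), and
the verdict carries the full question/answer trace. Cramer
classification itself is an input — external classifiers disagree for
some compound classes, and the verdict carries a `cramer_warning` flag to
surface that. Genotoxicity/carcinogenicity branches of extended TTC
schemes are out of scope.

## The fixture bundles: what they show and what they do not

`generate_fixture_library()` provides the study conditions for tests and
examples:

- **parabens** — four alkyl 4-hydroxybenzoates with published property
  values, standardised vectors and fingerprint Tanimotos attached as
  external tables. Because those components are supplied, the bundle
  tests the package's *arithmetic* (distances, similarities, geometric
  means, rounding) independent of descriptor-toolkit versions; computed-
  descriptor agreement is asserted separately with toolkit tolerances
  (MW ± 0.1 g/mol, TPSA ± 0.5 Å²).
- **hair_dyes** — a target and three candidates with published
  similarity components and three grade-4/opinion-4 90-day studies
  (NOAELs 17/50/80 mg/kg-bw/day). The SMILES are *synthetic surrogates*:
  nitroaromatic amines constructed so the bundled alert library
  reproduces the documented category pattern (all four pro-quinoid
  liver + nitro/amine DNA binders; the reproductive alert only on the
  two non-qualifying candidates). Nothing numeric is derived from the
  surrogate structures.
- **random_homologues** — a seed-deterministic library (default n = 20,
  alkyl chain lengths 1–8 over three scaffolds, half of them parabens,
  lognormal NOAELs with median 50 mg/kg-bw/day and log-sd 0.6, roughly
  the spread of 90-day oral NOAELs) used to stress-test similarity
  search and neighbour recovery against brute-force enumeration.

Passing these fixtures demonstrates that the pipeline reproduces the
published worked-example arithmetic and that the search/combination
machinery is exact on enumerable problems. It does not validate the
bundled alert SMARTS as toxicological alerts, the surrogate structures
as real dyes, or the example-calibrated reference statistics beyond the
paraben set — all three are explicitly illustrative and replaceable
through the same interfaces.

## Numerical and degenerate-input choices

- Tanimoto of two empty bitsets is defined as 1 (featureless structures
  are indistinguishable to the fingerprint); the convention is
  documented at the function.
- Pearson similarity on a zero-variance vector is an explicit error, not
  a silent 0.5: an undefined correlation must surface to the user.
- Similarity search breaks ties by compound id, ascending, so rankings
  are deterministic.
- Candidate-level failures inside `pairwise_profile()` (a missing
  property, a missing supplied Tanimoto) produce a per-candidate error
  entry with `NA` values, never a silently shorter table.
- Workflow steps are fail-safe: any step error yields a partial report
  with all completed prior steps intact and a note in `$messages`.
- The only stochastic component anywhere is the `random_homologues`
  generator; the scientific pipeline is deterministic, and repeated runs
  export byte-identical reports.

## Worked example

```{r}
report <- read_across(generate_fixture_library("hair_dyes"))
report
```

```{r}
ttc_evaluate("[Na+].[O-]S(=O)(=O)c1cccc2ccccc12", "III",
             exposure = 0.35, exposure_unit = "ug_per_kg_bw_day",
             cramer_warning = TRUE)
```

## Known limitations

- Fingerprint bit patterns are OpenBabel-version-dependent; published
  Tanimoto tables from other toolkits are reproduced by supplying them
  as inputs, not by recomputation.
- The DST interval depends on the discount parameter; it is a
  sensitivity band, not a calibrated frequentist interval.
- The TTC tree implements exactly the cohort-of-concern →
  organophosphate → Cramer-threshold path; intermediate questions of
  extended published trees that this path does not touch are not
  modelled, and their node numbering is kept only as labels (Q1, Q6,
  Q9).
- NOAEL bounds assume the neighbour NOAELs are a meaningful sample for
  the target; with few or heterogeneous neighbours the interval can be
  wide or clip at zero, and the single-neighbour case deliberately
  refuses to produce an interval.
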