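---
title: "Patient similarity knowledge bases with formal concept analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient similarity knowledge bases with formal concept analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcakb)
```

## The model

`fcakb` treats a cohort of patients as a *formal context* K = (G, M, I):
objects G are patients, attributes M are binarized clinical features, and I
records which patient has which feature. The two derivation operators
A′ (features shared by all patients in A) and B′ (patients having all
features in B) form a Galois connection; their fixed points — pairs (A, B)
with A′ = B and B′ = A — are the *formal concepts*. A concept is a maximal
patient group together with exactly the features that define it, and the set
of all concepts ordered by extent inclusion is a complete lattice: the
knowledge base. The hypothesis underlying its clinical use is that patients
sharing a concept are candidates for similar management, and that the
lattice's hierarchy (sub-concepts = smaller groups with more specific
features) organizes those groups for browsing and retrieval.

Retrieval scores every concept against a query concept with the weighted
set-overlap

$$\mathrm{Sim} = \alpha\,\frac{|A_1\cap A_2|}{\max(|A_1|,|A_2|)}
              + \beta\,\frac{|B_1\cap B_2|}{\max(|B_1|,|B_2|)},$$

α = β = 0.5 weighting patients and features equally. A new patient has no
extent yet, so case retrieval defaults to α = 0, β = 1 (pure intent
overlap); a concept whose intent equals the query scores exactly 1.

## Clinical coding

Raw colorectal-cancer records are coded into 32 binary attributes in 11
mutually exclusive, exhaustive groups (`crc_coding_scheme()`):

| group | attributes | rule |
|---|---|---|
| age (years) | Age_L / Age_M / Age_H | < 60 / [60, 70) / ≥ 70 |
| differentiation | Degre_L / Degre_M / Degre_H | poor / moderate / well |
| histology | MAd / Ad | mucinous adenocarcinoma / adenocarcinoma |
| T stage | T1–T4 | as recorded |
| N stage | N0–N2 | as recorded |
| examined nodes | Lym_L / Lym_H | < 10 / ≥ 10 |
| CEA (μg/ml) | CEA_L / CEA_H | < 5 / ≥ 5 |
| CA19-9 (U/ml) | Ca199_L / Ca199_H | < 37 / ≥ 37 |
| LVI | Lv_N / Lv_Y | absent / present |
| LNR | LNR_L / LNR_H | < 0.13 / ≥ 0.13 |
| stage group | I, IIA, IIB, IIC, IIIA, IIIB, IIIC | as recorded |

Design choices here: low bins are half-open below the cutoff and the cutoff
itself falls in the upper bin (age 60 → Age_M, CEA 5 → CEA_H, LNR 0.13 →
LNR_H), matching the "< x" / "≥ x" convention of clinical baseline tables.
Stage group is coded as supplied, not recomputed from T/N, because source
registries record it independently; metastasis (M stage) is absent from the
attribute space. Missing values are rejected rather than imputed — the
method assumes complete one-hot rows, and silently imputed bits would
fabricate concept memberships. Spelling variants of attribute names seen in
published tables (`Ly_N`/`Lv_N`, `LymH`, lowercase forms) are normalized on
input and treated as one token each.

## Enumeration and the Hasse diagram

`concept_lattice()` enumerates closed attribute sets with Ganter's
NextClosure algorithm in the lectic order induced by the canonical attribute
order — deterministic, memory-light, and emitting each closed intent exactly
once. Closures are evaluated as two dense matrix products against the
incidence matrix, which in plain R carries a 2442-patient, 32-attribute
context (about 10^5 concepts) in a couple of minutes. Concepts are then
sorted by (extent size descending, intent bit-pattern) and ids C1, C2, ...
assigned, so ids are reproducible across runs; enumeration order itself is
an implementation detail. The covering relation (Hasse diagram) is computed
from packed intent bitmasks: for each concept, its upper neighbours are the
maximal strict sub-intents, found by subset tests over 16-bit words. Both
the top concept (all patients) and the bottom (all attributes) are retained;
`proper_concept_count()` reports the count excluding empty-sided concepts,
which is the number quoted for small worked examples.

An independent oracle, `brute_force_concepts()`, closes every subset of the
attribute powerset (guarded at 20 attributes) and is used by the test suite
to verify NextClosure exactly on hundreds of random contexts up to 8 × 8.

## Retrieval choices

Two degenerate cases need decisions the similarity formula does not make:

- **0/0 terms.** If both operand sets of a term are empty the term
  contributes 0 (relevant when scoring an extent-less query with α > 0).
- **The bottom concept.** When no patient has all 32 attributes the bottom
  concept has an empty extent and the full attribute set as intent; under
  β = 1 it would score |B_query|/|M| against any query while describing no
  patients. Retrieval therefore excludes empty-extent concepts by default
  (`include_empty_extent = TRUE` restores them).
- **Ties.** Equal scores are ordered by extent size (larger, more general
  patient groups first) then concept id — deterministic, but not a claim
  that published tables used the same rule, so tests pin score multisets
  and the rank-1 result rather than intra-tie order.
- **Rounding.** Scores are computed exactly and displayed rounded half-up
  to 3 decimals (`round_half_up()`), the convention of clinical tables;
  base R's bankers' rounding would print 0.5-boundary scores differently.

## The synthetic cohort generator

The reference 2442-patient hospital cohort is not publicly deposited, so
`generate_cohort()` emulates it from its published baseline table: each of
the 11 attribute groups is sampled from the table's marginal frequencies
(taken as counts/2442, so each group sums to 1 exactly), and continuous
values are drawn uniformly inside the selected bin (age 18–95, CEA 0–100,
CA19-9 0–500, LNR 0–1, nodes 1–60). Uniform in-bin draws are arbitrary but
harmless: the coding step only ever sees the bin. Groups are sampled
independently because only marginals are published; real cohorts couple
stage with T and N, so `mode = "tnm_consistent"` optionally derives stage
group from the drawn T/N via a fixed AJCC-like lookup (T1–2/N0 → I, T3/N0 →
IIA, T4/N0 → IIB or IIC at the marginal IIB:IIC odds, N1 → IIIA for T1–2
else IIIB, N2 → IIIC) — an approximation documented as such, not a property
of the reference data.

What passing tests on synthetic cohorts do and do not show: marginal
recovery and lattice correctness are fully exercised, but the *joint*
attribute distribution of the real cohort is unknown, so synthetic lattices
differ in size and shape from the real one. Under independent marginals the
2442-patient lattice has roughly 10^5 concepts — more than the ~3 × 10^4
reported for the real, correlated cohort, as independence maximizes
attribute-combination diversity. Conclusions about lattice size on real
data should not be read off the synthetic cohort.

## Problem sizes and tolerances

The test suite verifies: the 3 × 7 worked example (7 concepts, 5 proper,
9 covering edges, oracle-verified); exact reproduction of the published
top-10 retrieval score sequence at 3 decimals; NextClosure ≡ brute force on
200 seeded random contexts up to 8 × 8; one-hot conservation over 1000
random records; Galois/closure axioms on randomized contexts; and marginal
recovery within 4 binomial standard errors at n = 10,000 over 5 seeds
(the 4-SE band makes a spurious failure across the ~155 checks about a 1%
event). The full-size run in the test suite enumerates the n = 2442
synthetic lattice without covering edges and verifies every concept is a
Galois fixed point; the covering computation is verified separately on
small lattices where a hand-derived edge count exists.

## Limitations

- Attribute implications (the second classical FCA output) are not
  computed; the knowledge base here is the lattice plus retrieval.
- No iceberg/pruned lattices: enumeration is complete, which is practical
  to ~10^5 concepts but not for contexts with hundreds of attributes.
- Similarity is the weighted overlap above only; alternative measures
  (Euclidean, ontology-based) are out of scope, as are concept clustering
  and treatment recommendation.
- `plot()` draws a simple layered Hasse diagram for small lattices; use the
  DOT export and Graphviz for anything larger.
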