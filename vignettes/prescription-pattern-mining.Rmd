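---
title: "Mining co-prescription patterns in herbal claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining co-prescription patterns in herbal claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbmine)
```

## The problem

Taiwan's national health insurance reimburses traditional Chinese medicine
alongside western medicine, and its claims records capture every ambulatory
prescription of Chinese herbal medicine (CHM). Two product classes exist:
**herbal formulas** (HF) — fixed multi-herb preparations such as
Jia-Wei-Xiao-Yao-San (JWXYS) — and **single herbs** (SH) such as *Cyperus
rotundus*. A typical prescription combines one or two formulas with several
adjuvant herbs, and the clinically interesting question is which CHM forms
the *core treatment* for a condition and which are co-prescribed around it.

`herbmine` implements that analysis for premenstrual syndrome (PMS, ICD-9
625.4) as a reusable pipeline: cohort selection from visit-level claims,
prevalence and dosing summaries, Apriori association-rule mining, and a
weighted co-prescription network whose hub is the core treatment. Because
the underlying national claims extract cannot be redistributed, the package
ships (a) the published summary counts as reference tables for worked-
example arithmetic, and (b) a synthetic claims generator with analytic
ground truth, which is what the test suite exercises end to end.

## Cohort definition

A visit enters the analysis when:

1. its diagnosis list is exactly the target code (default `625.4`). The
   sole-diagnosis rule — rather than "target anywhere among the three
   codes" — removes visits confounded by co-morbidities, at the cost of
   undercounting. `cohort_config(require_sole_diagnosis = FALSE)` gives the
   looser reading; the retained-visit set can only grow under it.
2. it carries a CHM prescription (non-empty item list), and
3. it records neither acupuncture nor massage, because those modalities can
   shift what is prescribed.

Two denominators are deliberately carried on the cohort object:
`n_all_target_visits` (diagnosis rules only — the denominator of the CHM
modality share) and `n_chm_prescriptions` (the final N that every
prevalence below is divided by). On the published counts these are 14,312
and 13,820, a 96.6% share, and the same arithmetic is reproduced by
`cohort_summary()` on any dataset.

## Statistics

**Prevalence.** "Instances" of a CHM is the number of prescriptions
containing it; prevalence is `100 * instances / N`, rounded *half-up* to
one decimal (`round_half_up()`), matching the convention of claims-study
tables; base R's `round()` would round half to even. The same definition
applies to unordered pairs. Mean dose (g/day) and duration (days) are
averaged over the prescriptions containing the CHM — the only denominator
available per item.

**Association rules.** A prescription is a transaction; for itemsets,
support is `count / N`. For a directed rule A→B, confidence is
`support(A,B) / support(A)`. Mining uses a hand-rolled level-wise Apriori
(`frequent_itemsets()`): frequent singletons, then candidate k-itemsets
joined from (k-1)-itemsets sharing a prefix, pruned by downward closure
before counting via transaction-id-list intersection. Default thresholds
are the conventional 1% support and 30% confidence; comparisons are
**inclusive** (`>=`), because a strict inequality on floating-point support
values makes the boundary untestable. The default `max_size` is 3 — pairs
are the reporting unit, triples are cheap. Reported combinations are
unordered, so `undirected_pairs()` collapses the two directions and keeps
both confidences; a pair is significant if either direction passes. With
the published counts for the top pair, Cyperus→JWXYS has confidence
1059/2485 = 42.6% (passes), JWXYS→Cyperus 1059/5185 = 20.4% (pruned) — the
pair is significant with an asymmetric direction profile.

**Network.** `build_network()` takes the top-k pairs (k = 10 by default,
matching the conventional figure; `network_from = "rules"` switches to
rule-filtered pairs), nodes annotated with item prevalence. The *core* is
operationalized as the node maximizing **weighted degree** (sum of incident
co-occurrence counts), with ties broken by prevalence then id. Published
figures identify the core visually; a reproducible criterion is needed
here, and this one recovers JWXYS on the published top-10 table (weighted
degree 3,796 across 7 of the 10 edges). Any richer centrality would be an
extension, not a reproduction.

```{r network}
ref <- pms_reference_tables()
net <- build_network(ref$items, ref$pairs, top_k_pairs = 10)
net
identify_core(net)
sort(weighted_degree(net), decreasing = TRUE)
```

One wrinkle: *Curcuma longa* appears only in the published pair table, so
its single-item count is unknown; the reference item table carries it with
`NA` prevalence and the network accepts that (the edge-count consistency
check is skipped for `NA`).

The published text reports an 80%/20% split of "HF with SH" vs "SH with
SH" among top combinations; classifying the ten printed pairs by their
members' types actually yields 6 HF–SH, 3 SH–SH and 1 HF–HF. The
denominator behind the printed 80/20 is unclear, so `combo_type_share()`
reports the three-way split of whatever pair table it is given and the
package asserts nothing about the 80/20 figure.

## The synthetic generator

`generate_claims()` emulates the claims extract's structure, not its
demography: patients with `1 + Poisson(mean - 1)` visits (the published
totals imply ~2.5 visits per patient, the default mean), a primary
diagnosis that is the target code with probability 0.8, a 10% chance of a
secondary code on target visits (making them ineligible), and a 3.4%
chance that a qualifying CHM visit also records acupuncture or massage
(reproducing the ~96.6% modality share).

Item inclusion is a two-stage scheme chosen so that every planted quantity
has a closed form:

- every catalogued item is included independently with its base
  probability (`core_items` + `baseline_items`);
- each adjuvant rule `(A, B, p)` whose antecedent A is present *in the
  base set* then adds B with probability p. Rules are applied in one pass
  with no chaining, and an item may not be both an antecedent and an
  adjuvant — both restrictions exist so that implied probabilities stay
  analytic: `P(B | A) = 1 - (1 - b_B)(1 - p) * prod(1 - b_a' p')` over
  other rules targeting B, and `P(A & B) = P(A) P(B | A)`.

A visit whose draws produce zero items carries no prescription and is
recorded as acupuncture-only; ground truth therefore reports marginals and
pair supports conditional on a non-empty prescription (division by
`p_nonempty = 1 - prod(1 - base)`), which leaves conditional probabilities
untouched. Under the default configuration `p_nonempty` ≈ 0.996, so the
correction is cosmetic; for small test catalogs it matters.

The default configuration (`default_pms_config()`) plants JWXYS at 0.375
marginal prevalence with adjuvant rules toward Cyperus, Leonurus, Corydalis
and Salvia, four further core formulas at their published marginal
prevalences, and a 30-item background tail sized so the analytic expected
prescription size is ≈ 5.4 items; dose means are ~4 g/day for formulas vs
~1.3 g/day for single herbs (truncated normal at zero, sampled by inverse
CDF), durations average ≈ 6.5 days, and administrations per day put 89% of
mass on 3. `admin_per_day` is drawn per visit and shared by the visit's
items, because dosing frequency is a prescription-level fact; real extracts
with per-item disagreement are resolved by the prescription's modal value
(ties to the lower frequency), with a message counting the affected rows.

What the generator does **not** emulate: age/sex structure, seasonality,
longitudinal treatment episodes, dose-diagnosis interactions, and any
correlation between items beyond the planted one-pass rules. Tests passing
on synthetic data therefore demonstrate that the *pipeline* recovers known
structure, not that real prescribing obeys this generative model.

## Numerical and scale choices

- Percent values are rounded half-up to one decimal everywhere they are
  emitted; internal computation keeps full precision.
- Support/confidence threshold comparisons carry an epsilon (`1e-9` counts,
  `1e-12` ratios) so boundary cases resolve deterministically.
- Sorted outputs break ties lexicographically on canonical itemset strings,
  making every table and the mined output order-stable across runs.
- ICD-9 codes are stored in dotted canonical form; `"6254"` and `"625.4"`
  are the same code on read, and normalization is idempotent.
- Duplicate `chm_id` within one prescription is rejected at read time: no
  aggregation rule (sum doses? max?) is defensible without knowing why the
  duplicate exists, so the reader refuses rather than guesses.
- Statistical recovery tests run at ~20,000 qualifying prescriptions
  (11,500 synthetic patients), the scale of the published cohort; the
  oracle-agreement property tests use 100 random instances of up to 12
  items and 200 transactions, where exhaustive subset enumeration is
  feasible as an independent check of the Apriori path.
- Pipeline manifests record an MD5 checksum per artifact (base R's
  `tools::md5sum`), enough to verify byte-identical reproduction of a run
  from the same config and seed.

## Known limitations

- The cohort carries no date-window or demographic filtering; the published
  procedure applies none beyond diagnosis and modality, but real studies
  may need both.
- Confidence intervals are not attached to prevalences or confidences; the
  package reports point estimates, as the source tables do.
- `identify_core()` reflects weighted degree only. A network with two
  comparable hubs would report just one; inspect `weighted_degree()` when
  in doubt.
- The reference tables contain only published top-k rows, so analyses that
  need the full item universe (e.g. re-mining the real cohort) cannot be
  run from them; they support worked-example arithmetic and the reference
  network only.
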