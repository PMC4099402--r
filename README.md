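# herbmine

Prescription-pattern mining of Chinese herbal medicine (CHM) claims:
who gets what, in which combinations, and around which core treatment.

## The problem

Claims databases that reimburse traditional Chinese medicine record, for
every ambulatory visit, up to three ICD-9 diagnosis codes and the herbal
products dispensed — fixed multi-herb **herbal formulas** (HF) and
**single herbs** (SH). For a condition such as premenstrual syndrome
(PMS, ICD-9 625.4), the analytic questions are:

- which CHM are most prescribed (prevalence = instances / N
  prescriptions),
- which *pairs* travel together, judged by association-rule mining — for
  a rule A→B, support = P(A ∩ B) and confidence = P(A ∩ B)/P(A), with
  conventional thresholds of 1% and 30%, and
- which CHM is the **core treatment**: the hub of the co-prescription
  network, i.e. the node maximizing weighted degree (the summed
  co-occurrence counts of its incident edges).

`herbmine` implements the full pipeline: typed claims readers/writers,
cohort selection (sole-diagnosis target visits, CHM only, acupuncture/
massage excluded), prevalence/dose/dosing-frequency tables, a level-wise
Apriori miner with support/confidence rules, weighted co-prescription
networks with GraphML export, and a pipeline runner with a reproducible
manifest. Because the source claims extract is not redistributable, the
package bundles the published summary counts as reference tables
(`pms_reference_tables()`) and provides a synthetic claims generator with
closed-form ground truth (`default_pms_config()`, `generate_claims()`)
for end-to-end validation.

## Worked example

```r
library(herbmine)

# published-count arithmetic: top formula 5,185 of N = 13,820
prevalence_pct(5185, 13820)
#> [1] 37.5

# a synthetic cohort with planted structure
cfg <- default_pms_config(seed = 1, n_patients = 1000)
syn <- generate_claims(cfg)
coh <- select_cohort(syn$dataset)
coh
#> <chm_cohort> 903 patients, 1785 target-diagnosis visits,
#>   1718 CHM prescriptions (96.2%)

head(item_prevalence(coh), 3)
#>   chm_id   chm_name chm_type instances dose_g_per_day duration_days prevalence_pct
#> 1 jwxys    Jia-Wei…       HF       678           4.01          6.96           39.5
#> 2 cyperus  Cyperus…       SH       367           1.31          6.98           21.4
#> 3 leonurus Leonuru…       SH       283           1.29          7.12           16.5

tx <- transactions_from_cohort(coh)
fi <- frequent_itemsets(tx, min_support = 0.01, max_size = 3)
head(association_rules(fi, tx$n_transactions, 0.01, 0.30), 3)
#>   antecedent consequent count support confidence
#> 1 cyperus    jwxys        250   0.146      0.681
#> 2 jwxys      cyperus      250   0.146      0.369
#> 3 leonurus   jwxys        181   0.105      0.640

net <- build_network(item_prevalence(coh), pair_prevalence(coh), 10)
identify_core(net)
#> [1] "jwxys"
```

The cohort print shows the two denominators the analysis keeps distinct:
all target-diagnosis visits (1,785 here) and the retained CHM
prescriptions (1,718, a 96.2% share — the modality-share statistic). The
prevalence table gives per-item instance counts, mean dose (formulas
~4 g/day vs single herbs ~1.3 g/day) and mean duration; the rule table
shows the planted co-prescription structure recovered in both directions
(Cyperus→JWXYS at 68% confidence, the reverse at 37%); and the network hub
is the planted core formula JWXYS.

A complete run — simulate (or read CSVs), filter, tabulate, mine, build
the network, and write a manifest with per-file checksums — is one call:

```r
run_pipeline(run_config(out_dir = "out",
                        generator = default_pms_config(n_patients = 1000),
                        seed = 7))
```

or from a shell, `Rscript inst/cli/chm-pipeline.R --out-dir out --seed 7`.

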