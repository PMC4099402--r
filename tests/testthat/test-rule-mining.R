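test_that("transactions are the deduplicated item sets of each prescription", {
  coh <- select_cohort(make_tiny_dataset())
  tx <- transactions_from_cohort(coh)
  expect_equal(tx$n_transactions, coh$n_chm_prescriptions)
  expect_equal(tx$items[["V1"]], c("cyperus", "jwxys"))
  expect_equal(tx$items[["V4"]], c("cyperus", "leonurus"))

  # transaction sizes agree with the prescription-size histogram
  syn <- generate_claims(default_pms_config(seed = 71, n_patients = 120))
  coh2 <- select_cohort(syn$dataset)
  tx2 <- transactions_from_cohort(coh2)
  hist <- prescription_size_stats(coh2)$histogram
  expect_equal(as.integer(table(lengths(tx2$items))), hist$n_prescriptions)
})

test_that("the textbook four-transaction example mines exactly", {
  tx <- as_transactions(list(c("A", "B"), c("A", "B"), c("A", "C"), "B"))
  fi <- frequent_itemsets(tx, min_support = 0.5, max_size = 3)
  expect_equal(fi$itemset, c("A", "B", "A + B"))
  expect_equal(fi$support, c(0.75, 0.75, 0.5))

  # min_support 1 keeps only itemsets present in every transaction
  tx2 <- as_transactions(list(c("A", "B"), c("A", "B")))
  fi2 <- frequent_itemsets(tx2, min_support = 1)
  expect_setequal(fi2$itemset, c("A", "B", "A + B"))
  expect_equal(fi2$support, rep(1, 3))
})

test_that("a zero support floor is rejected with guidance", {
  tx <- as_transactions(list("A"))
  expect_error(frequent_itemsets(tx, min_support = 0), "positive")
})

test_that("mining agrees exactly with brute-force enumeration", {
  withr::local_seed(123)
  for (rep in 1:10) {
    sets <- random_instance(n_items = sample(4:10, 1),
                            n_tx = sample(20:100, 1))
    ms <- sample(c(0.02, 0.05, 0.1, 0.2), 1)
    fi <- frequent_itemsets(as_transactions(sets), ms, max_size = 3)
    oracle <- oracle_itemsets(sets, ms, max_size = 3)
    expect_equal(fi$itemset, oracle$itemset)
    expect_equal(fi$count, oracle$count)
    expect_equal(fi$support, oracle$support)
  }
})

test_that("rules match brute-force rule generation on random instances", {
  withr::local_seed(321)
  for (rep in 1:6) {
    sets <- random_instance(n_items = 8, n_tx = 60)
    fi <- frequent_itemsets(as_transactions(sets), 0.05, max_size = 3)
    rules <- association_rules(fi, length(sets), 0.05, 0.4)
    oracle <- oracle_rules(sets, 0.05, 0.4, max_size = 3)
    expect_equal(rules$antecedent, oracle$antecedent)
    expect_equal(rules$consequent, oracle$consequent)
    expect_equal(rules$confidence, oracle$confidence)
  }
})

test_that("published pair arithmetic: direction decides retention", {
  # counts as printed: pair 1,059; Cyperus 2,485; JWXYS 5,185; N 13,820
  itemsets <- tibble::tibble(
    items = list("cyperus", "jwxys", c("cyperus", "jwxys")),
    itemset = c("cyperus", "jwxys", "cyperus + jwxys"),
    size = c(1L, 1L, 2L),
    count = c(2485L, 5185L, 1059L),
    support = c(2485, 5185, 1059) / 13820
  )
  rules <- association_rules(itemsets, 13820, 0.01, 0.30)
  # Cyperus -> JWXYS passes: support 7.66%, confidence 42.6%
  expect_equal(nrow(rules), 1)
  expect_equal(rules$antecedent, "cyperus")
  expect_equal(rules$consequent, "jwxys")
  expect_equal(round(rules$support, 4), 0.0766)
  expect_equal(round(rules$confidence, 3), 0.426)
  # JWXYS -> Cyperus is pruned: confidence 1059/5185 = 0.204 < 0.30
  expect_equal(round(1059 / 5185, 3), 0.204)

  pairs <- undirected_pairs(rules, itemsets)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$chm_a, "cyperus")
  expect_equal(round(pairs$confidence_a_to_b, 3), 0.426)
  expect_equal(round(pairs$confidence_b_to_a, 3), 0.204)
})

test_that("independent items give confidence equal to consequent support", {
  # A and B independent, each in half the transactions
  sets <- list(c("A", "B"), "A", "B", "Z")
  fi <- frequent_itemsets(as_transactions(sets), 0.25, 2)
  rules <- association_rules(fi, 4, 0.25, 0)
  ab <- rules[rules$antecedent == "A" & rules$consequent == "B", ]
  expect_equal(ab$confidence, 0.5)
})

test_that("no passing rule yields an empty pair table", {
  sets <- list(c("A", "B"), "A", "B", "A")
  fi <- frequent_itemsets(as_transactions(sets), 0.25, 2)
  rules <- association_rules(fi, 4, 0.25, 0.99)
  expect_equal(nrow(rules), 0)
  expect_equal(nrow(undirected_pairs(rules)), 0)
})

test_that("downward closure holds on mined output", {
  withr::local_seed(99)
  sets <- random_instance(n_items = 9, n_tx = 80)
  fi <- frequent_itemsets(as_transactions(sets), 0.05, 3)
  keys <- fi$itemset
  for (i in which(fi$size > 1)) {
    members <- fi$items[[i]]
    for (d in seq_along(members)) {
      expect_true(paste(members[-d], collapse = " + ") %in% keys)
    }
  }
  # support never exceeds confidence on any emitted rule
  rules <- association_rules(fi, length(sets), 0.05, 0)
  expect_true(all(rules$support <= rules$confidence + 1e-12))
  expect_true(all(rules$confidence <= 1 + 1e-12))
})

test_that("raising thresholds never adds itemsets or rules", {
  withr::local_seed(77)
  sets <- random_instance(n_items = 8, n_tx = 60)
  tx <- as_transactions(sets)
  lo <- frequent_itemsets(tx, 0.05, 3)
  hi <- frequent_itemsets(tx, 0.15, 3)
  expect_true(all(hi$itemset %in% lo$itemset))

  r_lo <- association_rules(lo, length(sets), 0.05, 0.2)
  r_hi <- association_rules(lo, length(sets), 0.05, 0.6)
  key <- function(r) paste(r$antecedent, "->", r$consequent)
  expect_true(all(key(r_hi) %in% key(r_lo)))
})

test_that("planted conditional probabilities are recovered as confidences", {
  catalog <- tibble::tibble(chm_id = c("J", "C", "L"),
                            chm_name = c("j", "c", "l"),
                            chm_type = c("HF", "SH", "SH"))
  cfg <- generator_config(
    n_patients = 3500, mean_visits_per_patient = 2,
    p_target_dx = 1, p_extra_dx = 0, p_acu_massage = 0,
    core_items = c(J = 0.4),
    adjuvant_rules = tibble::tibble(given = "J", adjuvant = "C",
                                    prob = 0.30),
    baseline_items = c(C = 0.05, L = 1.0), catalog = catalog, seed = 13)
  # C gets a small baseline too, so P(C | J) = 1 - 0.95 * 0.70 = 0.335
  syn <- generate_claims(cfg)
  truth <- syn$truth$rules
  expect_equal(truth$cond_prob, 1 - 0.95 * 0.70)

  coh <- select_cohort(syn$dataset)
  tx <- transactions_from_cohort(coh)
  fi <- frequent_itemsets(tx, 0.01, 2)
  rules <- association_rules(fi, tx$n_transactions, 0.01, 0.30)
  jc <- rules[rules$antecedent == "J" & rules$consequent == "C", ]
  expect_equal(nrow(jc), 1) # recovered as significant at the 1%/30% bar
  n_j <- fi$count[fi$itemset == "J"]
  se <- sqrt(truth$cond_prob * (1 - truth$cond_prob) / n_j)
  expect_lt(abs(jc$confidence - truth$cond_prob), 3 * se)
})
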