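small_catalog <- tibble::tibble(
  chm_id = c("J", "C", "L"),
  chm_name = c("Formula J", "Herb C", "Herb L"),
  chm_type = c("HF", "SH", "SH")
)

test_that("invalid probabilities and dangling references are rejected", {
  expect_error(
    generator_config(n_patients = 10, core_items = c(J = 1.2),
                     catalog = small_catalog),
    "probabilities")
  expect_error(
    generator_config(n_patients = 10, core_items = c(Z = 0.5),
                     catalog = small_catalog),
    "uncatalogued")
  expect_error(
    generator_config(
      n_patients = 10, core_items = c(J = 0.5),
      adjuvant_rules = tibble::tibble(given = "J", adjuvant = "Z",
                                      prob = 0.5),
      catalog = small_catalog),
    "uncatalogued")
})

test_that("fixed seed gives identical output, different seeds differ", {
  a <- generate_claims(default_pms_config(seed = 1, n_patients = 80))
  b <- generate_claims(default_pms_config(seed = 1, n_patients = 80))
  c <- generate_claims(default_pms_config(seed = 2, n_patients = 80))
  expect_equal(a$dataset$visits, b$dataset$visits)
  expect_equal(a$dataset$items, b$dataset$items)
  expect_false(identical(a$dataset$items, c$dataset$items))

  # and the CSV serialization is byte-identical
  pa <- withr::local_tempfile(); pb <- withr::local_tempfile()
  ia <- withr::local_tempfile(); ib <- withr::local_tempfile()
  write_claims(a$dataset, pa, ia)
  write_claims(b$dataset, pb, ib)
  expect_identical(readLines(pa), readLines(pb))
  expect_identical(readLines(ia), readLines(ib))
})

test_that("p_target_dx = 0 yields a dataset with zero qualifying visits", {
  cfg <- generator_config(n_patients = 40, p_target_dx = 0,
                          core_items = c(J = 0.9, C = 0.5),
                          catalog = small_catalog, seed = 3)
  syn <- generate_claims(cfg)
  coh <- select_cohort(syn$dataset)
  expect_equal(coh$n_all_target_visits, 0)
  expect_equal(coh$n_chm_prescriptions, 0)
})

test_that("degenerate probabilities force exactly the planted item set", {
  cfg <- generator_config(
    n_patients = 30, p_target_dx = 1, p_extra_dx = 0, p_acu_massage = 0,
    core_items = c(J = 1.0),
    adjuvant_rules = tibble::tibble(given = "J", adjuvant = "C", prob = 1.0),
    catalog = small_catalog, seed = 5)
  syn <- generate_claims(cfg)
  sets <- split(syn$dataset$items$chm_id, syn$dataset$items$visit_id)
  expect_true(all(vapply(sets, function(s)
    setequal(s, c("J", "C")), logical(1))))
})

test_that("planted marginal and pair probabilities are recovered within 3 SE", {
  cfg <- generator_config(
    n_patients = 4000, mean_visits_per_patient = 2,
    p_target_dx = 1, p_extra_dx = 0, p_acu_massage = 0,
    core_items = c(J = 0.4),
    adjuvant_rules = tibble::tibble(given = "J", adjuvant = "C", prob = 0.3),
    baseline_items = c(L = 1.0), # guaranteed base herb: no empty draws
    catalog = small_catalog, seed = 9)
  syn <- generate_claims(cfg)
  coh <- select_cohort(syn$dataset)
  sets <- split(coh$items$chm_id, coh$items$visit_id)
  n <- length(sets)

  # pair probability P(J & C) = 0.4 * 0.3 = 0.12 (C has no baseline mass)
  p_jc <- mean(vapply(sets, function(s) all(c("J", "C") %in% s), logical(1)))
  se <- sqrt(0.12 * 0.88 / n)
  expect_lt(abs(p_jc - 0.12), 3 * se)

  # and each configured marginal, against the analytic ground truth
  truth <- syn$truth$item_marginals
  for (id in names(truth)) {
    if (truth[[id]] == 0) next
    emp <- mean(vapply(sets, function(s) id %in% s, logical(1)))
    if (truth[[id]] == 1) {
      expect_equal(emp, 1) # degenerate: guaranteed item, zero variance
    } else {
      se <- sqrt(truth[[id]] * (1 - truth[[id]]) / n)
      expect_lt(abs(emp - truth[[id]]), 3 * se)
    }
  }
})

test_that("default study configuration matches its calibration targets", {
  cfg <- default_pms_config(seed = 1)
  # analytic expected prescription size sits in the realistic band
  exp_items <- expected_items_per_prescription(cfg)
  expect_gte(exp_items, 4)
  expect_lte(exp_items, 6)
  # dosing weights put dominant mass on three administrations a day
  w <- cfg$admin_choices
  expect_equal(w$admin[which.max(w$weight)], 3L)
  expect_gt(w$weight[w$admin == 3] / sum(w$weight), 0.8)
  # ground truth pair probabilities satisfy P(A&B) = P(A) P(B|A)
  tr <- generate_claims(default_pms_config(seed = 2, n_patients = 50))$truth
  expect_equal(tr$rules$pair_prob, tr$rules$given_prob * tr$rules$cond_prob)
})

test_that("generator config and ground truth serialize and restore", {
  cfg <- default_pms_config(seed = 4, n_patients = 77)
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, yml)
  cfg2 <- read_generator_config(yml)
  expect_equal(cfg2$core_items, cfg$core_items)
  expect_equal(cfg2$adjuvant_rules, cfg$adjuvant_rules)
  expect_equal(cfg2$seed, cfg$seed)
  # restored config generates the identical dataset
  expect_equal(generate_claims(cfg2)$dataset$items,
               generate_claims(cfg)$dataset$items)

  js <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(generate_claims(cfg)$truth, js)
  back <- jsonlite::read_json(js)
  expect_equal(back$expected_items_per_prescription,
               expected_items_per_prescription(cfg))
})
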