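tiny_cohort <- function() {
  select_cohort(make_tiny_dataset(), cohort_config())
}

test_that("published worked examples reproduce from their printed counts", {
  # the top formula: 5,185 of 13,820 prescriptions -> 37.5%
  expect_equal(prevalence_pct(5185, 13820), 37.5)
  # the top pair: 1,059 of 13,820 -> 7.7%
  expect_equal(prevalence_pct(1059, 13820), 7.7)
  # and every printed prevalence in the bundled reference tables is the
  # rounded ratio of its printed numerator over N
  ref <- pms_reference_tables()
  for (tab in list(ref$hf, ref$sh)) {
    expect_equal(prevalence_pct(tab$instances, ref$n_prescriptions),
                 tab$prevalence_pct)
  }
  expect_equal(prevalence_pct(ref$pairs$instances, ref$n_prescriptions),
               ref$pairs$prevalence_pct)
})

test_that("item prevalence on a tiny cohort is exact", {
  coh <- tiny_cohort() # V1 {jwxys, cyperus}, V4 {cyperus, leonurus}
  tab <- item_prevalence(coh)
  expect_equal(tab$chm_id, c("cyperus", "jwxys", "leonurus"))
  expect_equal(tab$instances, c(2L, 1L, 1L))
  expect_equal(tab$prevalence_pct, c(100.0, 50.0, 50.0))
  # dose/duration averaged over the containing prescriptions
  expect_equal(tab$dose_g_per_day[tab$chm_id == "cyperus"], (1.4 + 1.2) / 2)
})

test_that("a one-item cohort reports that item at 100%", {
  ds <- make_tiny_dataset()
  one <- claims_dataset(ds$visits[1, ], ds$items[1:2, ])
  coh <- select_cohort(one)
  tab <- item_prevalence(coh)
  expect_equal(tab$prevalence_pct, c(100, 100))
})

test_that("empty cohorts raise an error naming the denominator", {
  empty <- structure(list(visits = NULL, items = NULL,
                          n_all_target_visits = 0L,
                          n_chm_prescriptions = 0L, n_patients = 0L),
                     class = "chm_cohort")
  expect_error(item_prevalence(empty), "n_chm_prescriptions")
  expect_error(pair_prevalence(empty), "n_chm_prescriptions")
})

test_that("one prescription of {A,B,C} enumerates its three pairs once", {
  visits <- tibble::tibble(
    visit_id = "V1", patient_id = "P1", visit_date = as.Date("2005-01-01"),
    dx1 = "625.4", dx2 = NA_character_, dx3 = NA_character_,
    modality = "CHM")
  items <- tibble::tibble(
    visit_id = "V1", chm_id = c("A", "B", "C"),
    chm_name = c("a", "b", "c"), chm_type = c("HF", "SH", "SH"),
    dose_g_per_day = 1, duration_days = 7L, admin_per_day = 3L)
  coh <- select_cohort(claims_dataset(visits, items))
  pp <- pair_prevalence(coh)
  expect_equal(nrow(pp), 3)
  expect_equal(pp$instances, rep(1L, 3))
  expect_setequal(paste(pp$chm_a, pp$chm_b), c("A B", "A C", "B C"))
})

test_that("item and pair counts match the brute-force oracle", {
  syn <- generate_claims(default_pms_config(seed = 41, n_patients = 80))
  coh <- select_cohort(syn$dataset)
  sets <- split(coh$items$chm_id, coh$items$visit_id)

  tab <- item_prevalence(coh)
  oracle <- oracle_item_counts(sets)
  expect_equal(stats::setNames(tab$instances, tab$chm_id)[names(oracle)],
               oracle)

  pp <- pair_prevalence(coh)
  okey <- oracle_pair_counts(sets)
  got <- stats::setNames(pp$instances,
                         paste(pmin(pp$chm_a, pp$chm_b),
                               pmax(pp$chm_a, pp$chm_b), sep = "|"))
  expect_equal(sort(names(got)), sort(names(okey)))
  expect_equal(got[names(okey)], okey)

  # anti-monotonicity: a pair can never beat either of its members
  singles <- stats::setNames(tab$instances, tab$chm_id)
  expect_true(all(pp$instances <= pmin(singles[pp$chm_a],
                                       singles[pp$chm_b])))
})

test_that("pair rows are canonically ordered by member frequency", {
  coh <- tiny_cohort()
  pp <- pair_prevalence(coh)
  # cyperus (2 instances) leads jwxys and leonurus (1 each)
  expect_equal(pp$chm_a, c("cyperus", "cyperus"))
  expect_setequal(pp$chm_b, c("jwxys", "leonurus"))
})

test_that("combination type shares classify the reference top-10 pairs", {
  ref <- pms_reference_tables()
  share <- combo_type_share(ref$pairs, ref$items)
  expect_equal(sum(share), 100)
  # 6 formula-herb, 3 herb-herb and 1 formula-formula pair among the ten
  expect_equal(unname(share), c(10, 60, 30))
  expect_equal(names(share), c("HF-HF", "HF-SH", "SH-SH"))

  # degenerate single-class cases
  one <- tibble::tibble(chm_a = "jwxys", chm_b = "gzflw")
  expect_equal(combo_type_share(one, ref$items)[["HF-HF"]], 100)
  expect_error(
    combo_type_share(tibble::tibble(chm_a = "jwxys", chm_b = "nope"),
                     ref$items),
    "missing from catalog")
})

test_that("prescription-size stats: exact means and a complete histogram", {
  coh <- tiny_cohort() # sizes 2 and 2
  st <- prescription_size_stats(coh)
  expect_equal(st$mean_items, 2.0)
  expect_equal(sum(st$histogram$n_prescriptions), coh$n_chm_prescriptions)

  # two prescriptions of sizes 4 and 6 average 5.0
  visits <- tibble::tibble(
    visit_id = c("V1", "V2"), patient_id = c("P1", "P2"),
    visit_date = as.Date("2005-01-01"), dx1 = "625.4",
    dx2 = NA_character_, dx3 = NA_character_, modality = "CHM")
  items <- tibble::tibble(
    visit_id = rep(c("V1", "V2"), c(4, 6)),
    chm_id = c(paste0("a", 1:4), paste0("b", 1:6)),
    chm_name = "x", chm_type = "SH",
    dose_g_per_day = 1, duration_days = 7L, admin_per_day = 3L)
  st2 <- prescription_size_stats(select_cohort(claims_dataset(visits, items)))
  expect_equal(st2$mean_items, 5.0)
})

test_that("synthetic mean prescription size tracks the analytic expectation", {
  cfg <- default_pms_config(seed = 51, n_patients = 1500)
  syn <- generate_claims(cfg)
  coh <- select_cohort(syn$dataset)
  st <- prescription_size_stats(coh)
  mu <- syn$truth$expected_items_per_prescription
  # item count is a sum of independent Bernoullis; its variance is bounded
  # by the mean, so 3*sqrt(mu/n) is a conservative 3-SE band
  se <- sqrt(mu / coh$n_chm_prescriptions)
  expect_lt(abs(st$mean_items_raw - mu), 3 * se)
})

test_that("dosing frequency sums to 100% and respects configured weights", {
  coh <- tiny_cohort()
  d <- dosing_frequency_distribution(coh)
  expect_equal(d$admin_per_day, c(3L, 4L))
  expect_equal(d$pct, c(50, 50))
  expect_equal(sum(d$n_prescriptions), coh$n_chm_prescriptions)

  syn <- generate_claims(default_pms_config(seed = 61, n_patients = 1200))
  coh2 <- select_cohort(syn$dataset)
  d2 <- dosing_frequency_distribution(coh2)
  expect_equal(sum(d2$n_prescriptions), coh2$n_chm_prescriptions)
  p3 <- d2$n_prescriptions[d2$admin_per_day == 3] / sum(d2$n_prescriptions)
  se <- sqrt(0.890 * 0.110 / sum(d2$n_prescriptions))
  expect_lt(abs(p3 - 0.890), 3 * se)
})

test_that("mixed admin_per_day prescriptions resolve to the modal value", {
  ds <- make_tiny_dataset()
  ds$items$admin_per_day[ds$items$visit_id == "V1"] <- c(3, 4)
  coh <- select_cohort(claims_dataset(ds$visits, ds$items))
  expect_message(d <- dosing_frequency_distribution(coh), "mixed")
  # tie between 3 and 4 resolves to the lower value
  expect_equal(sum(d$n_prescriptions), 2)
  expect_true(3L %in% d$admin_per_day)
})
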