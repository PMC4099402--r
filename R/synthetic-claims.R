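#' Configure the synthetic claims generator
#'
#' The generator emulates the structure of a national-insurance ambulatory
#' claims extract for a premenstrual-syndrome (PMS, ICD-9 625.4) herbal
#' cohort: multi-visit patients, up to three ordered diagnosis codes with
#' the primary in first position, CHM/acupuncture/massage modalities, and
#' multi-item prescriptions built from a dominant core formula plus
#' conditionally co-prescribed adjuvants.
#'
#' Item inclusion per CHM visit follows a two-stage scheme with closed-form
#' ground truth: every catalogued item is first included independently with
#' its marginal probability (`core_items` and `baseline_items` together);
#' then each adjuvant rule `(given, adjuvant, prob)` whose antecedent is in
#' that base set adds the adjuvant with the stated conditional probability.
#' Rules are applied in one pass against the base set only (an adjuvant
#' added by a rule never triggers further rules), which keeps every implied
#' pair probability available analytically.
#'
#' @param n_patients Number of patients.
#' @param mean_visits_per_patient Mean visits per patient; visits are drawn
#'   as 1 + Poisson(mean - 1) so every patient has at least one visit.
#' @param p_target_dx Probability a visit's primary diagnosis is the target
#'   code 625.4.
#' @param p_extra_dx Probability a 625.4 visit carries a secondary
#'   diagnosis (making it ineligible for a sole-diagnosis cohort).
#' @param p_acu_massage Probability a 625.4 CHM visit also records
#'   acupuncture or massage (excluded downstream).
#' @param core_items Named numeric vector: chm_id -> marginal inclusion
#'   probability for core items.
#' @param adjuvant_rules Tibble/data frame with columns `given`, `adjuvant`,
#'   `prob`: conditional co-prescription rules.
#' @param baseline_items Named numeric vector: chm_id -> small inclusion
#'   probability for background items.
#' @param dose_params Tibble with columns `chm_id`, `mean`, `sd`: per-item
#'   dose distribution in g/day (normal truncated at 0).
#' @param duration_choices Tibble with columns `days` (positive integers)
#'   and `weight`.
#' @param admin_choices Tibble with columns `admin` (administrations/day)
#'   and `weight`; admin_per_day is a prescription-level attribute shared by
#'   all items of a visit.
#' @param catalog Tibble `chm_id`, `chm_name`, `chm_type` covering every
#'   item referenced above.
#' @param seed Integer seed; a fixed seed makes [generate_claims()] output
#'   byte-identical.
#' @return A validated object of class `generator_config`.
#' @seealso [default_pms_config()], [generate_claims()]
#' @export
generator_config <- function(n_patients,
                             mean_visits_per_patient = 2.5,
                             p_target_dx = 0.8,
                             p_extra_dx = 0.1,
                             p_acu_massage = 0.034,
                             core_items,
                             adjuvant_rules = NULL,
                             baseline_items = numeric(0),
                             dose_params = NULL,
                             duration_choices = NULL,
                             admin_choices = NULL,
                             catalog,
                             seed = 1L) {
  if (is.null(adjuvant_rules)) {
    adjuvant_rules <- tibble::tibble(given = character(),
                                     adjuvant = character(),
                                     prob = numeric())
  }
  adjuvant_rules <- tibble::as_tibble(adjuvant_rules)
  catalog <- tibble::as_tibble(catalog)
  if (is.null(dose_params)) {
    dose_params <- tibble::tibble(
      chm_id = catalog$chm_id,
      mean = ifelse(catalog$chm_type == "HF", 4.0, 1.3),
      sd = ifelse(catalog$chm_type == "HF", 1.0, 0.3)
    )
  }
  if (is.null(duration_choices)) {
    duration_choices <- tibble::tibble(days = c(3L, 5L, 7L, 10L, 14L),
                                       weight = c(0.10, 0.25, 0.45, 0.12, 0.08))
  }
  if (is.null(admin_choices)) {
    admin_choices <- tibble::tibble(admin = c(2L, 3L, 4L),
                                    weight = c(0.026, 0.890, 0.084))
  }
  cfg <- structure(
    list(n_patients = as.integer(n_patients),
         mean_visits_per_patient = mean_visits_per_patient,
         p_target_dx = p_target_dx,
         p_extra_dx = p_extra_dx,
         p_acu_massage = p_acu_massage,
         core_items = core_items,
         adjuvant_rules = adjuvant_rules,
         baseline_items = baseline_items,
         dose_params = tibble::as_tibble(dose_params),
         duration_choices = tibble::as_tibble(duration_choices),
         admin_choices = tibble::as_tibble(admin_choices),
         catalog = catalog,
         seed = as.integer(seed)),
    class = "generator_config"
  )
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  probs <- c(cfg$p_target_dx, cfg$p_extra_dx, cfg$p_acu_massage,
             cfg$core_items, cfg$baseline_items, cfg$adjuvant_rules$prob)
  if (any(probs < 0 | probs > 1)) {
    stop("config error: all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_patients < 1) {
    stop("config error: n_patients must be positive", call. = FALSE)
  }
  if (cfg$mean_visits_per_patient < 1) {
    stop("config error: mean_visits_per_patient must be >= 1", call. = FALSE)
  }
  ids <- cfg$catalog$chm_id
  referenced <- c(names(cfg$core_items), names(cfg$baseline_items),
                  cfg$adjuvant_rules$given, cfg$adjuvant_rules$adjuvant)
  unknown <- setdiff(referenced, ids)
  if (length(unknown)) {
    stop(sprintf("config error: uncatalogued chm_id %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  overlap <- intersect(names(cfg$core_items), names(cfg$baseline_items))
  if (length(overlap)) {
    stop(sprintf("config error: %s present in both core and baseline items",
                 paste(overlap, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(cfg$adjuvant_rules[c("given", "adjuvant")])) {
    stop("config error: duplicate (given, adjuvant) rule", call. = FALSE)
  }
  if (any(cfg$adjuvant_rules$given == cfg$adjuvant_rules$adjuvant)) {
    stop("config error: adjuvant rule with given == adjuvant", call. = FALSE)
  }
  # antecedents must be base items only: one-pass application evaluates
  # antecedent presence against the base inclusion set, so an item that is
  # both antecedent and adjuvant would break the closed-form ground truth
  both <- intersect(cfg$adjuvant_rules$given, cfg$adjuvant_rules$adjuvant)
  if (length(both)) {
    stop(sprintf("config error: %s appears as both rule antecedent and adjuvant",
                 paste(both, collapse = ", ")), call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config> %d patients, ~%.1f visits each, %d catalogued CHM, %d adjuvant rules, seed %d\n",
    x$n_patients, x$mean_visits_per_patient, nrow(x$catalog),
    nrow(x$adjuvant_rules), x$seed))
  cat(sprintf("  expected items/prescription (analytic): %.2f\n",
              expected_items_per_prescription(x)))
  invisible(x)
}

# base (pre-rule) inclusion probability for every catalogued item
base_inclusion_probs <- function(cfg) {
  p <- stats::setNames(numeric(nrow(cfg$catalog)), cfg$catalog$chm_id)
  p[names(cfg$core_items)] <- cfg$core_items
  p[names(cfg$baseline_items)] <- cfg$baseline_items
  p
}

# marginal inclusion probability after one-pass rule application:
# item j is absent iff its base draw misses AND every rule targeting j
# fails (each fires with prob P(base antecedent) * prob)
marginal_inclusion_probs <- function(cfg) {
  base <- base_inclusion_probs(cfg)
  marg <- base
  if (nrow(cfg$adjuvant_rules)) {
    for (i in seq_len(nrow(cfg$adjuvant_rules))) {
      r <- cfg$adjuvant_rules[i, ]
      marg[r$adjuvant] <- 1 - (1 - marg[r$adjuvant]) *
        (1 - base[r$given] * r$prob)
    }
  }
  marg
}

#' Analytic expected prescription size for a generator configuration
#'
#' Sum over catalogued items of their marginal inclusion probabilities
#' (base probabilities plus one-pass adjuvant-rule contributions),
#' conditional on the prescription being non-empty.
#'
#' @param cfg A `generator_config`.
#' @return Expected number of items per CHM prescription.
#' @export
expected_items_per_prescription <- function(cfg) {
  base <- base_inclusion_probs(cfg)
  sum(marginal_inclusion_probs(cfg)) / (1 - prod(1 - base))
}

#' Default PMS study configuration
#'
#' A documented configuration whose qualifying cohort resembles the
#' published national claims analysis of herbal prescriptions for
#' premenstrual syndrome: the herbal formula JWXYS (Jia-Wei-Xiao-Yao-San)
#' dominates (~37.5% marginal prevalence), single herbs such as Cyperus
#' rotundus and Leonurus heterophyllus are conditionally co-prescribed with
#' it, a long tail of background items brings the expected prescription
#' size to about 5.4 items, dosing is overwhelmingly three times a day, and
#' ~3.4% of qualifying CHM visits carry acupuncture or massage.
#'
#' @param seed Integer seed.
#' @param n_patients Number of patients (default 5668, the cohort size the
#'   configuration is modelled on).
#' @return A `generator_config`.
#' @examples
#' cfg <- default_pms_config(seed = 1)
#' expected_items_per_prescription(cfg)
#' @export
default_pms_config <- function(seed = 1L, n_patients = 5668L) {
  core <- c(jwxys = 0.375, dgsys = 0.149, gzflw = 0.090,
            wjt = 0.081, sfzyt = 0.072)
  baseline_named <- c(
    cyperus = 0.076, leonurus = 0.100, corydalis = 0.070, salvia = 0.060,
    eucommia = 0.074, scutellaria = 0.062, dipsacus = 0.047, cuscuta = 0.046,
    pueraria = 0.045, moutan = 0.044, curcuma = 0.030
  )
  other_hf <- stats::setNames(rep(0.08, 5), sprintf("hf_other%02d", 1:5))
  other_sh <- stats::setNames(rep(0.13, 25), sprintf("sh_other%02d", 1:25))
  rules <- tibble::tribble(
    ~given,    ~adjuvant,   ~prob,
    "jwxys",   "cyperus",   0.30,
    "jwxys",   "leonurus",  0.17,
    "jwxys",   "corydalis", 0.12,
    "jwxys",   "salvia",    0.10,
    "dgsys",   "cyperus",   0.20,
    "gzflw",   "moutan",    0.15
  )
  catalog <- tibble::tibble(
    chm_id = c(names(core), names(other_hf),
               names(baseline_named), names(other_sh)),
    chm_name = c("Jia-Wei-Xiao-Yao-San", "Dang-Gui-Shao-Yao-San",
                 "Gui-Zhi-Fu-Ling-Wan", "Wen-Jing-Tang", "Shao-Fu-Zhu-Yu-Tang",
                 sprintf("Background formula %02d", 1:5),
                 "Cyperus rotundus L.", "Leonurus heterophyllus Sweet",
                 "Corydalis yanhusuo W. T. Wang", "Salvia miltiorrhiza Bge.",
                 "Eucommia ulmoides Oliv.", "Scutellaria baicalensis Georgi",
                 "Dipsacus asperoides C. Y. Cheng", "Cuscuta chinensis Lam.",
                 "Pueraria lobata (Willd.) Ohwi", "Paeonia suffruticosa Andr.",
                 "Curcuma longa L.",
                 sprintf("Background herb %02d", 1:25)),
    chm_type = c(rep("HF", length(core) + length(other_hf)),
                 rep("SH", length(baseline_named) + length(other_sh)))
  )
  generator_config(
    n_patients = n_patients,
    mean_visits_per_patient = 2.5,
    p_target_dx = 0.8,
    p_extra_dx = 0.1,
    p_acu_massage = 0.034,
    core_items = core,
    adjuvant_rules = rules,
    baseline_items = c(baseline_named, other_hf, other_sh),
    catalog = catalog,
    seed = seed
  )
}

DISTRACTOR_DX <- c("625.3", "626.2", "306.4", "780.79", "799.9", "564.1")

# exact truncated-normal sampler (truncation at 0), vectorized
rtruncnorm0 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
}

sample_weighted <- function(n, values, weights) {
  values[sample.int(length(values), n, replace = TRUE,
                    prob = weights / sum(weights))]
}

#' Generate a synthetic claims dataset with ground truth
#'
#' Draws patients, visits, diagnoses, modalities and prescription items
#' according to a [generator_config()]. Output is deterministic under a
#' fixed seed (identical configs give byte-identical CSVs through
#' [write_claims()]).
#'
#' A visit whose independent inclusion draws yield zero items (rare under
#' realistic configurations) carries no CHM prescription and is recorded
#' as an acupuncture-only visit; ground-truth marginals and pair supports
#' are therefore reported conditional on a prescription existing (division
#' by `p_nonempty`), which leaves conditional probabilities untouched.
#'
#' @param cfg A `generator_config`.
#' @return A list of class `synthetic_claims` with elements `dataset` (a
#'   [claims_dataset()]) and `truth` (class `claims_ground_truth`: the
#'   realized config, analytic item marginals, and for every adjuvant rule
#'   the implied conditional probability `P(adjuvant | given)` and pair
#'   probability `P(given & adjuvant)`).
#' @examples
#' cfg <- default_pms_config(seed = 1, n_patients = 200)
#' syn <- generate_claims(cfg)
#' syn$dataset
#' @export
generate_claims <- function(cfg) {
  validate_generator_config(cfg)
  set.seed(cfg$seed)

  n_visits_per_patient <- 1L + stats::rpois(cfg$n_patients,
                                            cfg$mean_visits_per_patient - 1)
  n <- sum(n_visits_per_patient)
  patient_id <- rep(sprintf("P%05d", seq_len(cfg$n_patients)),
                    n_visits_per_patient)
  visit_id <- sprintf("V%06d", seq_len(n))
  visit_date <- as.Date("1998-01-01") +
    sample.int(as.integer(as.Date("2011-12-31") - as.Date("1998-01-01")) + 1L,
               n, replace = TRUE) - 1L

  is_target <- stats::runif(n) < cfg$p_target_dx
  dx1 <- ifelse(is_target, "625.4",
                sample(DISTRACTOR_DX, n, replace = TRUE))
  dx2 <- rep(NA_character_, n)
  extra <- is_target & stats::runif(n) < cfg$p_extra_dx
  dx2[extra] <- sample(DISTRACTOR_DX, sum(extra), replace = TRUE)
  # non-target visits occasionally carry a second code too
  extra2 <- !is_target & stats::runif(n) < 0.3
  dx2[extra2] <- sample(DISTRACTOR_DX, sum(extra2), replace = TRUE)
  dx3 <- rep(NA_character_, n)

  acu <- is_target & stats::runif(n) < cfg$p_acu_massage
  acu_kind <- sample(c("ACUPUNCTURE", "MASSAGE"), n, replace = TRUE)
  modality <- ifelse(acu, paste("CHM", acu_kind, sep = ";"), "CHM")

  # ---- item inclusion: base draws, then one-pass adjuvant rules ----
  base_p <- base_inclusion_probs(cfg)
  k <- length(base_p)
  include <- matrix(stats::runif(n * k) < rep(base_p, each = n),
                    nrow = n, ncol = k,
                    dimnames = list(NULL, names(base_p)))
  base_include <- include
  if (nrow(cfg$adjuvant_rules)) {
    for (i in seq_len(nrow(cfg$adjuvant_rules))) {
      r <- cfg$adjuvant_rules[i, ]
      fire <- base_include[, r$given] & stats::runif(n) < r$prob
      include[, r$adjuvant] <- include[, r$adjuvant] | fire
    }
  }
  # a visit whose draws produce no item carries no CHM prescription at all:
  # it is recorded as an acupuncture-only visit (rare under realistic
  # configurations; ground truth conditions on a prescription existing)
  empty <- rowSums(include) == 0
  modality[empty] <- "ACUPUNCTURE"

  idx <- which(include, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  item_visit <- idx[, 1]
  item_chm <- colnames(include)[idx[, 2]]
  m <- length(item_chm)

  cat_row <- match(item_chm, cfg$catalog$chm_id)
  dp_row <- match(item_chm, cfg$dose_params$chm_id)
  dose <- round(rtruncnorm0(m, cfg$dose_params$mean[dp_row],
                            cfg$dose_params$sd[dp_row]), 2)
  duration <- sample_weighted(m, cfg$duration_choices$days,
                              cfg$duration_choices$weight)
  admin_visit <- sample_weighted(n, cfg$admin_choices$admin,
                                 cfg$admin_choices$weight)

  visits <- tibble::tibble(visit_id, patient_id,
                           visit_date, dx1, dx2, dx3, modality)
  items <- tibble::tibble(
    visit_id = visit_id[item_visit],
    chm_id = item_chm,
    chm_name = cfg$catalog$chm_name[cat_row],
    chm_type = cfg$catalog$chm_type[cat_row],
    dose_g_per_day = dose,
    duration_days = as.integer(duration),
    admin_per_day = as.integer(admin_visit[item_visit])
  )

  truth <- ground_truth(cfg)
  structure(list(dataset = claims_dataset(visits, items), truth = truth),
            class = "synthetic_claims")
}

# closed-form implied probabilities for every planted rule; marginals and
# pair supports are reported conditional on a non-empty prescription
# (p_nonempty = 1 - prod(1 - base probabilities); conditioning divides
# supports by p_nonempty and leaves conditional probabilities unchanged)
ground_truth <- function(cfg) {
  base <- base_inclusion_probs(cfg)
  p_nonempty <- 1 - prod(1 - base)
  marg <- marginal_inclusion_probs(cfg) / p_nonempty
  rules <- cfg$adjuvant_rules
  if (nrow(rules)) {
    cond <- numeric(nrow(rules))
    for (i in seq_len(nrow(rules))) {
      r <- rules[i, ]
      # P(adjuvant | given present in base set): adjuvant absent iff its own
      # base draw misses, this rule fails, and every OTHER rule targeting it
      # (whose antecedent base event is independent of `given`) fails
      miss <- (1 - base[[r$adjuvant]]) * (1 - r$prob)
      others <- rules[rules$adjuvant == r$adjuvant & rules$given != r$given, ]
      if (nrow(others)) {
        miss <- miss * prod(1 - base[others$given] * others$prob)
      }
      cond[i] <- 1 - miss
    }
    rule_truth <- tibble::tibble(
      given = rules$given, adjuvant = rules$adjuvant,
      rule_prob = rules$prob,
      given_prob = unname(base[rules$given]) / p_nonempty,
      cond_prob = cond,
      pair_prob = unname(base[rules$given]) * cond / p_nonempty
    )
  } else {
    rule_truth <- tibble::tibble(given = character(), adjuvant = character(),
                                 rule_prob = numeric(), given_prob = numeric(),
                                 cond_prob = numeric(), pair_prob = numeric())
  }
  structure(
    list(config = cfg,
         p_nonempty = p_nonempty,
         item_marginals = marg,
         rules = rule_truth,
         expected_items_per_prescription = sum(marg)),
    class = "claims_ground_truth"
  )
}

#' @export
print.claims_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<claims_ground_truth> %d item marginals, %d planted rules, E[items/rx] = %.2f\n",
    length(x$item_marginals), nrow(x$rules),
    x$expected_items_per_prescription))
  invisible(x)
}

#' Serialize / restore a generator configuration as YAML
#'
#' @param cfg A `generator_config`.
#' @param path File path.
#' @return `write_generator_config()` returns the path invisibly;
#'   `read_generator_config()` returns a `generator_config`.
#' @export
write_generator_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "generator_config"))
  out <- list(
    n_patients = cfg$n_patients,
    mean_visits_per_patient = cfg$mean_visits_per_patient,
    p_target_dx = cfg$p_target_dx,
    p_extra_dx = cfg$p_extra_dx,
    p_acu_massage = cfg$p_acu_massage,
    core_items = as.list(cfg$core_items),
    baseline_items = as.list(cfg$baseline_items),
    adjuvant_rules = lapply(seq_len(nrow(cfg$adjuvant_rules)), function(i)
      as.list(cfg$adjuvant_rules[i, ])),
    dose_params = lapply(seq_len(nrow(cfg$dose_params)), function(i)
      as.list(cfg$dose_params[i, ])),
    duration_choices = lapply(seq_len(nrow(cfg$duration_choices)), function(i)
      as.list(cfg$duration_choices[i, ])),
    admin_choices = lapply(seq_len(nrow(cfg$admin_choices)), function(i)
      as.list(cfg$admin_choices[i, ])),
    catalog = lapply(seq_len(nrow(cfg$catalog)), function(i)
      as.list(cfg$catalog[i, ])),
    seed = cfg$seed
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  generator_config(
    n_patients = raw$n_patients,
    mean_visits_per_patient = raw$mean_visits_per_patient,
    p_target_dx = raw$p_target_dx,
    p_extra_dx = raw$p_extra_dx,
    p_acu_massage = raw$p_acu_massage,
    core_items = unlist(raw$core_items),
    adjuvant_rules = dplyr::bind_rows(raw$adjuvant_rules),
    baseline_items = unlist(raw$baseline_items),
    dose_params = dplyr::bind_rows(raw$dose_params),
    duration_choices = dplyr::bind_rows(raw$duration_choices),
    admin_choices = dplyr::bind_rows(raw$admin_choices),
    catalog = dplyr::bind_rows(raw$catalog),
    seed = raw$seed
  )
}

#' Serialize ground truth as JSON
#'
#' @param truth A `claims_ground_truth`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "claims_ground_truth"))
  out <- list(
    p_nonempty = truth$p_nonempty,
    item_marginals = as.list(truth$item_marginals),
    rules = truth$rules,
    expected_items_per_prescription = truth$expected_items_per_prescription
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
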