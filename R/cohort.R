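#' Cohort selection settings
#'
#' Encodes the inclusion/exclusion procedure for the analysis cohort:
#' ambulatory visits whose diagnosis is the target ICD-9 code (by default as
#' the sole diagnosis, so visits with any co-morbidity code are dropped),
#' restricted to visits actually carrying a CHM prescription, with
#' acupuncture/massage visits excluded because those modalities can shift
#' the herbal prescription.
#'
#' @param target_code Target ICD-9 code (default "625.4", premenstrual
#'   tension syndromes); normalized to the dotted form.
#' @param require_sole_diagnosis If TRUE (default), a visit qualifies only
#'   when its diagnosis list is exactly the target code; if FALSE, the
#'   target anywhere among the up-to-three codes qualifies.
#' @param exclude_modalities Visits whose modality set intersects this set
#'   are dropped from the final cohort (default acupuncture and massage).
#' @param require_chm If TRUE (default), only visits with CHM modality and
#'   a non-empty prescription are retained.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(target_code = "625.4",
                          require_sole_diagnosis = TRUE,
                          exclude_modalities = c("ACUPUNCTURE", "MASSAGE"),
                          require_chm = TRUE) {
  if (!nzchar(target_code)) {
    stop("target_code must be non-empty", call. = FALSE)
  }
  structure(
    list(target_code = normalize_icd9(target_code),
         require_sole_diagnosis = isTRUE(require_sole_diagnosis),
         exclude_modalities = exclude_modalities,
         require_chm = isTRUE(require_chm)),
    class = "cohort_config"
  )
}

#' Select the analysis cohort from a claims dataset
#'
#' Two counters are carried so the modality share is auditable:
#' `n_all_target_visits` counts every visit passing the diagnosis rules
#' (before modality filtering) and is the denominator of the CHM share,
#' while `n_chm_prescriptions` counts the retained CHM prescriptions and is
#' the denominator N of every downstream prevalence. `n_patients` counts
#' distinct patients over the target-diagnosis visits.
#'
#' Filtering is idempotent: applying it to an already-filtered cohort's
#' visits returns the identical visit set.
#'
#' @param data A [claims_dataset()].
#' @param config A [cohort_config()].
#' @return An object of class `chm_cohort`: list with `visits` and `items`
#'   tibbles (retained visits only), `n_all_target_visits`,
#'   `n_chm_prescriptions`, `n_patients`, and the `config` used. An empty
#'   cohort is a valid result.
#' @examples
#' syn <- generate_claims(default_pms_config(seed = 1, n_patients = 100))
#' select_cohort(syn$dataset, cohort_config())
#' @export
select_cohort <- function(data, config = cohort_config()) {
  stopifnot(inherits(data, "claims_dataset"))
  stopifnot(inherits(config, "cohort_config"))
  v <- data$visits

  if (config$require_sole_diagnosis) {
    dx_ok <- v$dx1 == config$target_code & is.na(v$dx2) & is.na(v$dx3)
  } else {
    dx_ok <- v$dx1 == config$target_code |
      (!is.na(v$dx2) & v$dx2 == config$target_code) |
      (!is.na(v$dx3) & v$dx3 == config$target_code)
  }

  mods <- modality_list(v$modality)
  excluded <- vapply(mods, function(m)
    length(intersect(m, config$exclude_modalities)) > 0, logical(1))
  has_chm <- has_modality(v$modality, "CHM")
  has_items <- v$visit_id %in% data$items$visit_id

  keep <- dx_ok & !excluded
  if (config$require_chm) keep <- keep & has_chm & has_items

  dropped_empty <- sum(dx_ok & !excluded & has_chm & !has_items)
  if (dropped_empty > 0) {
    message(sprintf(
      "select_cohort: dropped %d CHM visit(s) with no prescription items",
      dropped_empty))
  }

  visits <- v[keep, , drop = FALSE]
  items <- data$items[data$items$visit_id %in% visits$visit_id, , drop = FALSE]
  structure(
    list(visits = visits,
         items = items,
         n_all_target_visits = sum(dx_ok),
         n_chm_prescriptions = nrow(visits),
         n_patients = dplyr::n_distinct(v$patient_id[dx_ok]),
         config = config),
    class = "chm_cohort"
  )
}

#' @export
print.chm_cohort <- function(x, ...) {
  s <- cohort_summary(x)
  cat(sprintf(
    "<chm_cohort> %d patients, %d target-diagnosis visits, %d CHM prescriptions (%s%%)\n",
    s$n_patients, s$n_all_target_visits, s$n_chm_prescriptions,
    ifelse(is.na(s$chm_share_pct), "NA", format(s$chm_share_pct))))
  invisible(x)
}

#' Summarize a cohort
#'
#' @param cohort A `chm_cohort`.
#' @return A list with `n_patients`, `n_all_target_visits`,
#'   `n_chm_prescriptions` and `chm_share_pct` (CHM prescriptions as a
#'   percent of all target-diagnosis visits, one decimal; `NA` when the
#'   denominator is zero rather than a misleading 0).
#' @examples
#' # 13,820 CHM prescriptions out of 14,312 target visits -> 96.6%
#' @export
cohort_summary <- function(cohort) {
  stopifnot(inherits(cohort, "chm_cohort"))
  share <- if (cohort$n_all_target_visits == 0) NA_real_ else
    round_half_up(100 * cohort$n_chm_prescriptions /
                    cohort$n_all_target_visits, 1)
  list(n_patients = cohort$n_patients,
       n_all_target_visits = cohort$n_all_target_visits,
       n_chm_prescriptions = cohort$n_chm_prescriptions,
       chm_share_pct = share)
}
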