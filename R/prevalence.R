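#' Per-CHM prevalence, dose and duration table
#'
#' One row per distinct CHM appearing in the cohort. "Instances" counts the
#' prescriptions (not patients, not grams) containing the CHM; prevalence
#' is instances over N = `n_chm_prescriptions`, as a percent to one
#' decimal. Dose and duration are means over the prescriptions containing
#' the CHM. Rows are sorted by instances descending, ties broken
#' lexicographically by `chm_id`.
#'
#' @param cohort A `chm_cohort` with at least one prescription.
#' @return Tibble with columns `chm_id`, `chm_name`, `chm_type`,
#'   `instances`, `dose_g_per_day`, `duration_days`, `prevalence_pct`.
#' @examples
#' syn <- generate_claims(default_pms_config(seed = 1, n_patients = 300))
#' coh <- select_cohort(syn$dataset)
#' head(item_prevalence(coh))
#' @export
item_prevalence <- function(cohort) {
  n <- check_nonempty_cohort(cohort)
  cohort$items |>
    dplyr::group_by(.data$chm_id, .data$chm_name, .data$chm_type) |>
    dplyr::summarise(
      instances = dplyr::n(),
      dose_g_per_day = mean(.data$dose_g_per_day),
      duration_days = mean(.data$duration_days),
      .groups = "drop"
    ) |>
    dplyr::mutate(prevalence_pct = prevalence_pct(.data$instances, n)) |>
    dplyr::arrange(dplyr::desc(.data$instances), .data$chm_id)
}

#' Pairwise co-prescription prevalence table
#'
#' One row per unordered CHM pair co-occurring in at least one
#' prescription. Within a row the more frequent member (by single-item
#' instances, ties lexicographic) is reported as `chm_a`. Rows are sorted
#' by pair instances descending, ties by the canonical pair order.
#'
#' @inheritParams item_prevalence
#' @return Tibble with columns `chm_a`, `chm_b`, `instances`,
#'   `prevalence_pct`.
#' @export
pair_prevalence <- function(cohort) {
  n <- check_nonempty_cohort(cohort)
  singles <- item_prevalence(cohort)
  rank_of <- stats::setNames(seq_len(nrow(singles)), singles$chm_id)

  it <- cohort$items[c("visit_id", "chm_id")]
  pairs <- dplyr::inner_join(it, it, by = "visit_id",
                             relationship = "many-to-many",
                             suffix = c("_x", "_y")) |>
    dplyr::filter(.data$chm_id_x < .data$chm_id_y) |>
    dplyr::count(.data$chm_id_x, .data$chm_id_y, name = "instances")
  flip <- rank_of[pairs$chm_id_y] < rank_of[pairs$chm_id_x]
  pairs |>
    dplyr::mutate(
      chm_a = unname(ifelse(flip, .data$chm_id_y, .data$chm_id_x)),
      chm_b = unname(ifelse(flip, .data$chm_id_x, .data$chm_id_y)),
      prevalence_pct = prevalence_pct(.data$instances, n)
    ) |>
    dplyr::select("chm_a", "chm_b", "instances", "prevalence_pct") |>
    dplyr::arrange(dplyr::desc(.data$instances),
                   .data$chm_a, .data$chm_b)
}

#' Type composition of the top co-prescribed pairs
#'
#' Classifies each of the top-k pairs by its members' types (herbal formula
#' HF vs single herb SH) into HF-HF / HF-SH / SH-SH and reports the
#' percentage of pairs in each class (summing to 100 up to rounding).
#'
#' @param pairs A pair table (top-k rows of [pair_prevalence()] or the
#'   bundled reference pairs) with columns `chm_a`, `chm_b`.
#' @param catalog Tibble `chm_id`, `chm_type` covering every pair member.
#' @return Named numeric vector over `c("HF-HF", "HF-SH", "SH-SH")`,
#'   percentages to one decimal.
#' @export
combo_type_share <- function(pairs, catalog) {
  if (nrow(pairs) < 1) stop("pairs table is empty", call. = FALSE)
  type_of <- stats::setNames(catalog$chm_type, catalog$chm_id)
  missing <- setdiff(unique(c(pairs$chm_a, pairs$chm_b)), names(type_of))
  if (length(missing)) {
    stop(sprintf("chm_id missing from catalog: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  ta <- type_of[pairs$chm_a]
  tb <- type_of[pairs$chm_b]
  cls <- paste(pmin(ta, tb), pmax(ta, tb), sep = "-") # HF < SH lexically
  counts <- table(factor(cls, levels = c("HF-HF", "HF-SH", "SH-SH")))
  stats::setNames(round_half_up(100 * as.numeric(counts) / nrow(pairs), 1),
                  names(counts))
}

#' Prescription-size summary
#'
#' @inheritParams item_prevalence
#' @return List with `mean_items` (to one decimal), `mean_items_raw`, and
#'   `histogram` (tibble `n_items`, `n_prescriptions`; counts sum to N).
#' @export
prescription_size_stats <- function(cohort) {
  check_nonempty_cohort(cohort)
  sizes <- as.integer(table(factor(cohort$items$visit_id,
                                   levels = cohort$visits$visit_id)))
  tab <- table(sizes)
  hist <- tibble::tibble(n_items = as.integer(names(tab)),
                         n_prescriptions = as.integer(tab))
  list(mean_items = round_half_up(mean(sizes), 1),
       mean_items_raw = mean(sizes),
       histogram = hist)
}

#' Dosing-frequency distribution over prescriptions
#'
#' `admin_per_day` is treated as a prescription-level attribute. When a
#' prescription's items disagree (possible in real extracts), the
#' prescription is counted by its modal value (ties to the lower value) and
#' a message reports how many prescriptions were resolved that way.
#'
#' @inheritParams item_prevalence
#' @return Tibble with columns `admin_per_day`, `n_prescriptions`, `pct`
#'   (percent of prescriptions, one decimal; sums to 100 up to rounding).
#' @export
dosing_frequency_distribution <- function(cohort) {
  n <- check_nonempty_cohort(cohort)
  per_visit <- split(cohort$items$admin_per_day, cohort$items$visit_id)
  mixed <- sum(vapply(per_visit, function(a) length(unique(a)) > 1,
                      logical(1)))
  if (mixed > 0) {
    message(sprintf(
      "dosing_frequency_distribution: %d prescription(s) with mixed admin_per_day resolved by modal value",
      mixed))
  }
  modal <- vapply(per_visit, function(a) {
    tab <- table(a)
    as.integer(names(tab)[which.max(tab)]) # which.max takes first = lowest
  }, integer(1))
  counts <- table(modal)
  tibble::tibble(
    admin_per_day = as.integer(names(counts)),
    n_prescriptions = as.integer(counts),
    pct = round_half_up(100 * as.integer(counts) / n, 1)
  )
}

check_nonempty_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "chm_cohort"))
  n <- cohort$n_chm_prescriptions
  if (n == 0) {
    stop("empty cohort: denominator n_chm_prescriptions is zero",
         call. = FALSE)
  }
  n
}
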