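#' Published reference tables for the PMS herbal cohort
#'
#' The summary tables reported by the nationwide Taiwanese claims analysis
#' of Chinese herbal medicine prescribed for premenstrual syndrome
#' (1998-2011; N = 13,820 CHM prescriptions from 14,312 target-diagnosis
#' visits by 5,668 patients): the five most-prescribed herbal formulas, the
#' ten most-prescribed single herbs, and the ten most frequent two-CHM
#' combinations. The underlying claims records are not redistributable, so
#' these printed counts are the inputs for worked-example arithmetic and
#' for the reference co-prescription network.
#'
#' Curcuma longa appears only in the pair table; its single-item count was
#' not published, so its `instances`/`prevalence_pct` are `NA`.
#'
#' @return List with elements:
#'   \describe{
#'     \item{hf}{top herbal formulas: `chm_id`, `chm_name`, `chm_type`,
#'       `instances`, `dose_g_per_day`, `duration_days`, `prevalence_pct`}
#'     \item{sh}{top single herbs, same columns}
#'     \item{items}{`hf` and `sh` stacked, plus the Curcuma placeholder row}
#'     \item{pairs}{top pairs: `chm_a`, `chm_b`, `instances`,
#'       `prevalence_pct`}
#'     \item{n_prescriptions}{13820}
#'     \item{n_all_target_visits}{14312}
#'     \item{n_patients}{5668}
#'   }
#' @examples
#' ref <- pms_reference_tables()
#' prevalence_pct(ref$hf$instances[1], ref$n_prescriptions) # 37.5
#' @export
pms_reference_tables <- function() {
  hf <- tibble::tribble(
    ~chm_id,   ~chm_name,               ~instances, ~dose_g_per_day, ~duration_days, ~prevalence_pct,
    "jwxys",   "Jia-Wei-Xiao-Yao-San",        5185L,            4.87,            6.4,            37.5,
    "dgsys",   "Dang-Gui-Shao-Yao-San",       2064L,            4.34,            6.4,            14.9,
    "gzflw",   "Gui-Zhi-Fu-Ling-Wan",         1245L,            3.87,            6.3,             9.0,
    "wjt",     "Wen-Jing-Tang",               1120L,            4.25,            6.3,             8.1,
    "sfzyt",   "Shao-Fu-Zhu-Yu-Tang",          994L,            3.97,            6.2,             7.2
  )
  hf$chm_type <- "HF"
  sh <- tibble::tribble(
    ~chm_id,       ~chm_name,                          ~instances, ~dose_g_per_day, ~duration_days, ~prevalence_pct,
    "cyperus",     "Cyperus rotundus L.",                    2485L,            1.38,            6.3,            18.0,
    "leonurus",    "Leonurus heterophyllus Sweet",           2097L,            1.33,            6.3,            15.2,
    "corydalis",   "Corydalis yanhusuo W. T. Wang",          1573L,            1.28,            6.2,            11.4,
    "salvia",      "Salvia miltiorrhiza Bge.",               1281L,            1.30,            6.4,             9.3,
    "eucommia",    "Eucommia ulmoides Oliv.",                1023L,            1.26,            6.3,             7.4,
    "scutellaria", "Scutellaria baicalensis Georgi",          858L,            1.30,            6.5,             6.2,
    "dipsacus",    "Dipsacus asperoides C. Y. Cheng",         644L,            1.17,            6.4,             4.7,
    "cuscuta",     "Cuscuta chinensis Lam.",                  639L,            1.44,            6.6,             4.6,
    "pueraria",    "Pueraria lobata (Willd.) Ohwi",           616L,            1.33,            6.4,             4.5,
    "moutan",      "Paeonia suffruticosa Andr.",              605L,            1.43,            6.6,             4.4
  )
  sh$chm_type <- "SH"
  curcuma <- tibble::tibble(
    chm_id = "curcuma", chm_name = "Curcuma longa L.", chm_type = "SH",
    instances = NA_integer_, dose_g_per_day = NA_real_,
    duration_days = NA_real_, prevalence_pct = NA_real_
  )
  cols <- c("chm_id", "chm_name", "chm_type", "instances",
            "dose_g_per_day", "duration_days", "prevalence_pct")
  pairs <- tibble::tribble(
    ~chm_a,    ~chm_b,        ~instances, ~prevalence_pct,
    "jwxys",   "cyperus",          1059L,             7.7,
    "jwxys",   "leonurus",          818L,             5.9,
    "cyperus", "leonurus",          773L,             5.6,
    "jwxys",   "corydalis",         564L,             4.1,
    "cyperus", "corydalis",         512L,             3.7,
    "jwxys",   "salvia",            467L,             3.4,
    "cyperus", "salvia",            377L,             2.7,
    "jwxys",   "gzflw",             375L,             2.7,
    "jwxys",   "scutellaria",       262L,             1.9,
    "jwxys",   "curcuma",           251L,             1.8
  )
  list(
    hf = hf[cols],
    sh = sh[cols],
    items = rbind(hf[cols], sh[cols], curcuma[cols]),
    pairs = pairs,
    n_prescriptions = 13820L,
    n_all_target_visits = 14312L,
    n_patients = 5668L
  )
}
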