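# Independent brute-force oracles. These deliberately share no code with the
# package internals: itemset supports come from exhaustive subset
# enumeration, cohort filtering from plain row logic on the raw tables.

# all itemsets of size 1..max_size with support >= min_support, by
# enumerating every combination of observed items and scanning every
# transaction for containment
oracle_itemsets <- function(sets, min_support, max_size = 3) {
  sets <- lapply(sets, function(s) sort(unique(s)))
  universe <- sort(unique(unlist(sets)))
  n <- length(sets)
  rows <- list()
  for (k in seq_len(min(max_size, length(universe)))) {
    combos <- utils::combn(universe, k, simplify = FALSE)
    for (cmb in combos) {
      cnt <- sum(vapply(sets, function(s) all(cmb %in% s), logical(1)))
      if (cnt / n >= min_support - 1e-9) {
        rows[[length(rows) + 1]] <- data.frame(
          itemset = paste(cmb, collapse = " + "),
          size = k, count = cnt, support = cnt / n,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(itemset = character(), size = integer(),
                      count = integer(), support = numeric())
  }
  out[order(out$size, -out$support, out$itemset), , drop = FALSE]
}

# directed single-consequent rules from the oracle itemsets
oracle_rules <- function(sets, min_support, min_confidence, max_size = 3) {
  fi <- oracle_itemsets(sets, min_support, max_size)
  count_of <- stats::setNames(fi$count, fi$itemset)
  rows <- list()
  multi <- fi[fi$size >= 2, , drop = FALSE]
  n <- length(sets)
  for (i in seq_len(nrow(multi))) {
    members <- strsplit(multi$itemset[i], " + ", fixed = TRUE)[[1]]
    for (d in seq_along(members)) {
      ante <- paste(members[-d], collapse = " + ")
      conf <- multi$count[i] / count_of[[ante]]
      if (conf >= min_confidence - 1e-9) {
        rows[[length(rows) + 1]] <- data.frame(
          antecedent = ante, consequent = members[d],
          count = multi$count[i], support = multi$count[i] / n,
          confidence = conf, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(antecedent = character(), consequent = character(),
                      count = integer(), support = numeric(),
                      confidence = numeric())
  }
  out[order(-out$support, -out$confidence, out$antecedent, out$consequent),
      , drop = FALSE]
}

# plain row filter over the raw visit table: sole-diagnosis target visits,
# then CHM present, items present, no excluded modality
oracle_cohort_ids <- function(visits_df, items_df, target = "625.4") {
  mods <- strsplit(ifelse(is.na(visits_df$modality), "", visits_df$modality),
                   ";", fixed = TRUE)
  sole <- visits_df$dx1 == target & is.na(visits_df$dx2) &
    is.na(visits_df$dx3)
  chm <- vapply(mods, function(m) "CHM" %in% m, logical(1))
  excl <- vapply(mods, function(m)
    any(c("ACUPUNCTURE", "MASSAGE") %in% m), logical(1))
  has_items <- visits_df$visit_id %in% items_df$visit_id
  list(target_ids = visits_df$visit_id[sole],
       kept_ids = visits_df$visit_id[sole & chm & has_items & !excl])
}

# per-item and per-pair prescription counts by double loop over item sets
oracle_item_counts <- function(sets) {
  tab <- table(unlist(lapply(sets, unique)))
  stats::setNames(as.integer(tab), names(tab))
}

oracle_pair_counts <- function(sets) {
  counts <- new.env(parent = emptyenv())
  for (s in sets) {
    s <- sort(unique(s))
    if (length(s) < 2) next
    for (a in seq_len(length(s) - 1)) {
      for (b in seq(a + 1, length(s))) {
        key <- paste(s[a], s[b], sep = "|")
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  vals <- mget(ls(counts), envir = counts)
  stats::setNames(as.integer(unlist(vals)), names(vals))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random transaction instance for property tests
random_instance <- function(n_items = 8, n_tx = 50) {
  universe <- LETTERS[seq_len(n_items)]
  repeat {
    sets <- lapply(seq_len(n_tx), function(i) {
      k <- sample.int(min(5, n_items), 1)
      sample(universe, k)
    })
    if (all(lengths(sets) > 0)) return(sets)
  }
}

# tiny hand-built claims dataset used across module tests
make_tiny_dataset <- function() {
  visits <- tibble::tibble(
    visit_id = c("V1", "V2", "V3", "V4", "V5"),
    patient_id = c("P1", "P1", "P2", "P3", "P4"),
    visit_date = as.Date(c("2005-01-10", "2005-02-11", "2006-03-12",
                           "2006-04-13", "2007-05-14")),
    dx1 = c("625.4", "625.4", "625.4", "625.4", "306.4"),
    dx2 = c(NA, "306.4", NA, NA, NA),
    dx3 = rep(NA_character_, 5),
    modality = c("CHM", "CHM", "CHM;ACUPUNCTURE", "CHM", "CHM")
  )
  items <- tibble::tibble(
    visit_id = c("V1", "V1", "V2", "V3", "V4", "V4", "V5"),
    chm_id = c("jwxys", "cyperus", "jwxys", "jwxys", "cyperus",
               "leonurus", "jwxys"),
    chm_name = c("Jia-Wei-Xiao-Yao-San", "Cyperus rotundus L.",
                 "Jia-Wei-Xiao-Yao-San", "Jia-Wei-Xiao-Yao-San",
                 "Cyperus rotundus L.", "Leonurus heterophyllus Sweet",
                 "Jia-Wei-Xiao-Yao-San"),
    chm_type = c("HF", "SH", "HF", "HF", "SH", "SH", "HF"),
    dose_g_per_day = c(4.5, 1.4, 5.0, 4.0, 1.2, 1.3, 4.8),
    duration_days = c(7, 7, 5, 7, 3, 3, 7),
    admin_per_day = c(3, 3, 3, 3, 4, 4, 3)
  )
  claims_dataset(visits, items)
}

# wrap a cohort's retained visits back into a claims_dataset (for
# idempotence checks)
dataset_from_cohort <- function(cohort) {
  claims_dataset(cohort$visits, cohort$items)
}
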