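#' Build mining transactions from a cohort
#'
#' Each retained CHM prescription becomes one transaction: the set of its
#' `chm_id` values (duplicates within a prescription are impossible by the
#' dataset invariant).
#'
#' @param cohort A non-empty `chm_cohort`.
#' @return Object of class `chm_transactions`: list with `items` (a list of
#'   sorted character vectors, one per prescription, named by `visit_id`)
#'   and `n_transactions`.
#' @export
transactions_from_cohort <- function(cohort) {
  check_nonempty_cohort(cohort)
  by_visit <- split(cohort$items$chm_id, cohort$items$visit_id)
  by_visit <- lapply(by_visit, function(x) sort(unique(x)))
  # preserve cohort visit order
  by_visit <- by_visit[cohort$visits$visit_id]
  structure(list(items = by_visit, n_transactions = length(by_visit)),
            class = "chm_transactions")
}

#' Transactions from an explicit list of item sets
#'
#' Convenience constructor used in tests and small examples.
#'
#' @param sets List of character vectors (each non-empty).
#' @return A `chm_transactions`.
#' @export
as_transactions <- function(sets) {
  if (any(lengths(sets) == 0)) {
    stop("every transaction must be non-empty", call. = FALSE)
  }
  items <- lapply(sets, function(x) sort(unique(as.character(x))))
  if (is.null(names(items))) {
    names(items) <- sprintf("T%04d", seq_along(items))
  }
  structure(list(items = items, n_transactions = length(items)),
            class = "chm_transactions")
}

#' @export
print.chm_transactions <- function(x, ...) {
  cat(sprintf("<chm_transactions> %d transactions, %d distinct items\n",
              x$n_transactions, length(unique(unlist(x$items)))))
  invisible(x)
}

ITEM_SEP <- " + "

itemset_key <- function(items) paste(items, collapse = ITEM_SEP)

# count threshold equivalent to support >= min_support, with an epsilon so
# counts sitting exactly on the boundary are kept (inclusive comparison)
support_floor <- function(min_support, n) min_support * n - 1e-9

#' Level-wise Apriori frequent-itemset mining
#'
#' Classic Apriori: frequent single items first, then size-k candidates
#' joined from frequent (k-1)-itemsets sharing a (k-2)-prefix, pruned by
#' downward closure (every (k-1)-subset must itself be frequent) before
#' counting. Counting uses per-item transaction-id lists intersected across
#' the candidate's members. Output is exactly the set of itemsets of size 1
#' to `max_size` whose support is at least `min_support` (inclusive
#' comparison), canonically sorted.
#'
#' @param transactions A `chm_transactions`.
#' @param min_support Minimum support in (0, 1]; the conventional claims
#'   analysis threshold is 0.01. A zero floor is rejected because it makes
#'   the output size unbounded; pass a small positive value instead.
#' @param max_size Largest itemset size to mine (default 3; pairs are the
#'   unit of reporting, triples are cheap).
#' @return Tibble with columns `items` (list of sorted character vectors),
#'   `itemset` (canonical " + "-joined string), `size`, `count`, `support`
#'   (= count / n_transactions exactly), sorted by size, then support
#'   descending, then itemset string.
#' @examples
#' tx <- as_transactions(list(c("A", "B"), c("A", "B"), c("A", "C"), "B"))
#' frequent_itemsets(tx, min_support = 0.5, max_size = 2)
#' @export
frequent_itemsets <- function(transactions, min_support = 0.01,
                              max_size = 3) {
  stopifnot(inherits(transactions, "chm_transactions"))
  if (min_support <= 0) {
    stop("min_support must be positive (a zero floor makes the output ",
         "unbounded); use a small positive value such as 0.001",
         call. = FALSE)
  }
  if (min_support > 1) stop("min_support must be <= 1", call. = FALSE)
  n <- transactions$n_transactions
  floor_count <- support_floor(min_support, n)

  long <- data.frame(
    tid = rep.int(seq_len(n), lengths(transactions$items)),
    item = unlist(transactions$items, use.names = FALSE)
  )
  tids <- lapply(split(long$tid, long$item), sort)

  l1_items <- names(tids)[lengths(tids) >= floor_count]
  l1_items <- sort(l1_items)
  levels <- list()
  levels[[1]] <- list(
    sets = as.list(l1_items),
    counts = vapply(l1_items, function(i) length(tids[[i]]), integer(1)),
    tids = tids[l1_items]
  )

  k <- 2
  while (k <= max_size && length(levels[[k - 1]]$sets) >= 2) {
    prev <- levels[[k - 1]]
    prev_keys <- vapply(prev$sets, itemset_key, character(1))
    cand_sets <- list()
    cand_tids <- list()
    # join step: pairs of (k-1)-itemsets sharing their first k-2 items
    prefixes <- vapply(prev$sets, function(s)
      itemset_key(s[-length(s)]), character(1))
    for (grp in split(seq_along(prev$sets), prefixes)) {
      if (length(grp) < 2) next
      for (a in seq_len(length(grp) - 1)) {
        for (b in seq(a + 1, length(grp))) {
          ia <- grp[a]; ib <- grp[b]
          cand <- sort(union(prev$sets[[ia]], prev$sets[[ib]]))
          if (length(cand) != k) next
          # prune: every (k-1)-subset must be frequent
          subs <- vapply(seq_len(k), function(d)
            itemset_key(cand[-d]), character(1))
          if (!all(subs %in% prev_keys)) next
          cand_sets[[length(cand_sets) + 1]] <- cand
          cand_tids[[length(cand_tids) + 1]] <-
            intersect(prev$tids[[match(itemset_key(cand[-k]), prev_keys)]],
                      tids[[cand[k]]])
        }
      }
    }
    keep <- lengths(cand_tids) >= floor_count
    if (!any(keep)) break
    ord <- order(vapply(cand_sets[keep], itemset_key, character(1)))
    levels[[k]] <- list(
      sets = cand_sets[keep][ord],
      counts = lengths(cand_tids[keep])[ord],
      tids = cand_tids[keep][ord]
    )
    k <- k + 1
  }

  rows <- dplyr::bind_rows(lapply(seq_along(levels), function(k) {
    lv <- levels[[k]]
    if (length(lv$sets) == 0) return(NULL)
    tibble::tibble(
      items = lv$sets,
      itemset = vapply(lv$sets, itemset_key, character(1)),
      size = k,
      count = as.integer(lv$counts),
      support = as.integer(lv$counts) / n
    )
  }))
  if (is.null(rows) || nrow(rows) == 0) {
    rows <- tibble::tibble(items = list(), itemset = character(),
                           size = integer(), count = integer(),
                           support = numeric())
  }
  dplyr::arrange(rows, .data$size, dplyr::desc(.data$support), .data$itemset)
}

#' Association rules from frequent itemsets
#'
#' For every frequent itemset of size >= 2, each single-item consequent
#' partition is emitted as a directed rule antecedent -> consequent with
#' `support = count(itemset) / n` and `confidence = count(itemset) /
#' count(antecedent)`. Rules are retained when support >= `min_support` AND
#' confidence >= `min_confidence` (both inclusive; the conventional claims
#' thresholds are 1% and 30%).
#'
#' @param itemsets Output of [frequent_itemsets()], mined at the same or a
#'   lower support floor.
#' @param n_transactions Number of transactions the itemsets were counted
#'   over.
#' @param min_support,min_confidence Retention thresholds (inclusive).
#' @return Tibble with columns `antecedent` (canonical string),
#'   `consequent` (single item), `antecedent_items` (list), `count`,
#'   `support`, `confidence`, sorted by support descending, confidence
#'   descending, then antecedent/consequent strings.
#' @examples
#' tx <- as_transactions(list(c("A", "B"), c("A", "B"), c("A", "C"), "B"))
#' fi <- frequent_itemsets(tx, min_support = 0.25)
#' association_rules(fi, tx$n_transactions, 0.25, 0.5)
#' @export
association_rules <- function(itemsets, n_transactions,
                              min_support = 0.01, min_confidence = 0.30) {
  if (min_confidence < 0 || min_confidence > 1) {
    stop("min_confidence must lie in [0, 1]", call. = FALSE)
  }
  count_of <- stats::setNames(itemsets$count, itemsets$itemset)
  multi <- itemsets[itemsets$size >= 2, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(multi))) {
    set <- multi$items[[i]]
    cnt <- multi$count[i]
    sup <- cnt / n_transactions
    if (sup < min_support - 1e-12) next
    for (d in seq_along(set)) {
      ante <- set[-d]
      ante_count <- unname(count_of[itemset_key(ante)])
      if (is.na(ante_count)) {
        # guarded by downward closure; reaching this means the itemset
        # table was mined at a higher floor than requested here
        stop(sprintf("antecedent %s missing from itemset table",
                     itemset_key(ante)), call. = FALSE)
      }
      conf <- cnt / ante_count
      if (conf < min_confidence - 1e-12) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        antecedent = itemset_key(ante),
        consequent = set[d],
        antecedent_items = list(ante),
        count = as.integer(cnt),
        support = sup,
        confidence = conf
      )
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(antecedent = character(), consequent = character(),
                          antecedent_items = list(), count = integer(),
                          support = numeric(), confidence = numeric()))
  }
  dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$support), dplyr::desc(.data$confidence),
                   .data$antecedent, .data$consequent)
}

#' Collapse directed pair rules to undirected significant pairs
#'
#' The field reports combinations as unordered "CHM A with CHM B" while the
#' confidence measure is directional; this collapses the two directed rules
#' on each item pair into one row. A pair is significant if either
#' direction passed the thresholds; both directions' confidences are
#' annotated. When one direction was pruned it is absent from `rules`, so
#' its confidence is recovered from the singleton supports in `itemsets`
#' when supplied, and reported `NA` otherwise.
#'
#' @param rules Output of [association_rules()].
#' @param itemsets Optional [frequent_itemsets()] table for recovering the
#'   pruned direction's confidence.
#' @return Tibble with columns `chm_a`, `chm_b` (lexicographic order),
#'   `count`, `support`, `confidence_a_to_b`, `confidence_b_to_a`, sorted
#'   by support descending then pair.
#' @export
undirected_pairs <- function(rules, itemsets = NULL) {
  pr <- rules[lengths(rules$antecedent_items) == 1, , drop = FALSE]
  if (nrow(pr) == 0) {
    return(tibble::tibble(chm_a = character(), chm_b = character(),
                          count = integer(), support = numeric(),
                          confidence_a_to_b = numeric(),
                          confidence_b_to_a = numeric()))
  }
  count_of <- if (!is.null(itemsets)) {
    stats::setNames(itemsets$count, itemsets$itemset)
  } else NULL
  pr$chm_a <- pmin(pr$antecedent, pr$consequent)
  pr$chm_b <- pmax(pr$antecedent, pr$consequent)
  out <- pr |>
    dplyr::group_by(.data$chm_a, .data$chm_b) |>
    dplyr::summarise(
      count = .data$count[1],
      support = .data$support[1],
      confidence_a_to_b = confidence_in_direction(
        .data$antecedent, .data$confidence, .data$chm_a[1],
        .data$count[1], count_of),
      confidence_b_to_a = confidence_in_direction(
        .data$antecedent, .data$confidence, .data$chm_b[1],
        .data$count[1], count_of),
      .groups = "drop"
    )
  dplyr::arrange(out, dplyr::desc(.data$support), .data$chm_a, .data$chm_b)
}

confidence_in_direction <- function(antecedents, confidences, from,
                                    pair_count, count_of) {
  hit <- which(antecedents == from)
  if (length(hit)) return(confidences[hit[1]])
  if (!is.null(count_of) && !is.na(count_of[from])) {
    return(unname(pair_count / count_of[from]))
  }
  NA_real_
}
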