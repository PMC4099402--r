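#' Configure a pipeline run
#'
#' A run takes its claims either from a pair of input CSV paths or from a
#' synthetic [generator_config()] — exactly one of the two — and carries
#' the cohort, mining and reporting settings for every downstream stage.
#'
#' @param out_dir Output directory (created if needed).
#' @param generator A `generator_config`, or `NULL` when reading files.
#' @param visits_path,items_path Input CSVs, or `NULL` when generating.
#' @param cohort A [cohort_config()].
#' @param min_support,min_confidence,max_itemset_size Mining thresholds,
#'   see [frequent_itemsets()] and [association_rules()].
#' @param top_hf,top_sh,top_pairs Row counts for the reported tables.
#' @param network_from `"pairs"` (default: top-k raw pair prevalence, the
#'   conventional rendering) or `"rules"` (rule-filtered significant
#'   pairs).
#' @param seed Integer seed recorded in the manifest; when generating, it
#'   overrides the generator config's seed so one value controls the run.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       generator = NULL,
                       visits_path = NULL, items_path = NULL,
                       cohort = cohort_config(),
                       min_support = 0.01, min_confidence = 0.30,
                       max_itemset_size = 3,
                       top_hf = 5, top_sh = 10, top_pairs = 10,
                       network_from = c("pairs", "rules"),
                       seed = 1L) {
  from_files <- !is.null(visits_path) || !is.null(items_path)
  if (is.null(generator) == !from_files) {
    stop("exactly one of a generator config or input paths must be given",
         call. = FALSE)
  }
  if (from_files && (is.null(visits_path) || is.null(items_path))) {
    stop("both visits_path and items_path are required", call. = FALSE)
  }
  if (!is.null(generator)) {
    stopifnot(inherits(generator, "generator_config"))
    generator$seed <- as.integer(seed)
  }
  structure(
    list(out_dir = out_dir, generator = generator,
         visits_path = visits_path, items_path = items_path,
         cohort = cohort,
         min_support = min_support, min_confidence = min_confidence,
         max_itemset_size = max_itemset_size,
         top_hf = top_hf, top_sh = top_sh, top_pairs = top_pairs,
         network_from = match.arg(network_from),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full prescription-pattern pipeline
#'
#' Executes simulate (or read) -> cohort -> stats -> mine -> network,
#' writing every table and graph artifact into `config$out_dir` together
#' with a JSON manifest recording the configuration echo, stage counts,
#' thresholds, seed and an MD5 checksum per output file. Identical config
#' and seed produce byte-identical outputs and therefore identical
#' manifest checksums. A failure in any stage removes the partial outputs
#' and aborts with the stage name.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @examples
#' \donttest{
#' cfg <- run_config(out_dir = tempfile("run"),
#'                   generator = default_pms_config(n_patients = 200),
#'                   seed = 7)
#' manifest <- run_pipeline(cfg)
#' manifest$counts$n_chm_prescriptions
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    written <<- c(written, path)
    path
  }
  stage <- "setup"
  result <- tryCatch({
    # ---- simulate / read ----
    stage <- "simulate"
    if (!is.null(config$generator)) {
      syn <- generate_claims(config$generator)
      data <- syn$dataset
      emit("visits.csv", function(p)
        write_claims(data, p, file.path(config$out_dir, "items.csv")))
      written <- c(written, file.path(config$out_dir, "items.csv"))
      emit("generator_config.yaml", function(p)
        write_generator_config(config$generator, p))
      emit("ground_truth.json", function(p) write_ground_truth(syn$truth, p))
    } else {
      data <- read_claims(config$visits_path, config$items_path)
    }

    # ---- cohort ----
    stage <- "cohort"
    cohort <- select_cohort(data, config$cohort)
    summary <- cohort_summary(cohort)
    message(sprintf(
      "cohort: %d target-diagnosis visits; %d CHM prescriptions retained (%s%% of target visits)",
      summary$n_all_target_visits, summary$n_chm_prescriptions,
      ifelse(is.na(summary$chm_share_pct), "NA",
             format(summary$chm_share_pct))))
    emit("cohort_summary.json", function(p)
      jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                           na = "null"))

    # ---- stats ----
    stage <- "stats"
    items <- item_prevalence(cohort)
    pairs <- pair_prevalence(cohort)
    sizes <- prescription_size_stats(cohort)
    dosing <- dosing_frequency_distribution(cohort)
    emit("table1_hf.csv", function(p)
      write_table(utils::head(items[items$chm_type == "HF", ],
                              config$top_hf), p))
    emit("table2_sh.csv", function(p)
      write_table(utils::head(items[items$chm_type == "SH", ],
                              config$top_sh), p))
    emit("table3_pairs.csv", function(p)
      write_table(utils::head(pairs, config$top_pairs), p))
    emit("item_prevalence.csv", function(p) write_table(items, p))
    emit("prescription_sizes.csv", function(p)
      write_table(sizes$histogram, p))
    emit("dosing_frequency.csv", function(p) write_table(dosing, p))

    # ---- mine ----
    stage <- "mine"
    tx <- transactions_from_cohort(cohort)
    itemsets <- frequent_itemsets(tx, config$min_support,
                                  config$max_itemset_size)
    rules <- association_rules(itemsets, tx$n_transactions,
                               config$min_support, config$min_confidence)
    rule_pairs <- undirected_pairs(rules, itemsets)
    emit("itemsets.csv", function(p)
      write_table(itemsets[c("itemset", "size", "count", "support")], p))
    emit("rules.csv", function(p)
      write_table(rules[c("antecedent", "consequent", "count",
                          "support", "confidence")], p))
    emit("rule_pairs.csv", function(p) write_table(rule_pairs, p))

    # ---- network ----
    stage <- "network"
    edge_table <- if (config$network_from == "rules") {
      tibble::tibble(chm_a = rule_pairs$chm_a, chm_b = rule_pairs$chm_b,
                     instances = rule_pairs$count)
    } else {
      pairs
    }
    net <- build_network(items, edge_table, config$top_pairs)
    emit("network.graphml", function(p)
      export_graph(net, p, format = "graphml"))
    emit("network_edges.csv", function(p)
      export_graph(net, p, format = "edgelist"))
    core <- if (nrow(net$nodes) > 0) identify_core(net) else NA_character_

    list(cohort_summary = summary, sizes = sizes, core = core,
         itemsets = itemsets, rules = rules, net = net)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline failed at stage '%s': %s",
                 stage, conditionMessage(e)), call. = FALSE)
  })

  manifest <- list(
    package = "herbmine",
    version = as.character(utils::packageVersion("herbmine")),
    seed = config$seed,
    thresholds = list(min_support = config$min_support,
                      min_confidence = config$min_confidence,
                      max_itemset_size = config$max_itemset_size),
    top_k = list(hf = config$top_hf, sh = config$top_sh,
                 pairs = config$top_pairs),
    network_from = config$network_from,
    source = if (is.null(config$generator)) {
      list(kind = "files", visits = config$visits_path,
           items = config$items_path)
    } else {
      list(kind = "synthetic", n_patients = config$generator$n_patients)
    },
    counts = c(result$cohort_summary,
               list(mean_items_per_prescription = result$sizes$mean_items,
                    n_frequent_itemsets = nrow(result$itemsets),
                    n_rules = nrow(result$rules),
                    n_network_nodes = nrow(result$net$nodes),
                    n_network_edges = nrow(result$net$edges))),
    core_treatment = result$core,
    files = {
      rel <- sort(unique(basename(written)))
      md5 <- unname(tools::md5sum(file.path(config$out_dir, rel)))
      stats::setNames(as.list(md5), rel)
    }
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(manifest)
}
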