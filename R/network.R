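#' Build a co-prescription network
#'
#' Nodes are the CHM appearing among the top-k co-prescribed pairs, sized
#' by their single-item prevalence; edges are those pairs, weighted by
#' co-occurrence count (no self-loops by construction). The convention
#' mirrors the standard claims-study rendering: larger node = higher
#' prevalence, thicker edge = more common combination.
#'
#' @param item_rows Item prevalence table ([item_prevalence()] or the
#'   bundled reference items): columns `chm_id`, `chm_type`,
#'   `prevalence_pct`, optionally `instances`. Every pair endpoint must be
#'   present; `NA` prevalence/instances are tolerated for items whose
#'   single counts are unknown.
#' @param pair_rows Pair table ([pair_prevalence()] or reference pairs):
#'   columns `chm_a`, `chm_b`, `instances`, sorted by instances descending
#'   (re-sorted defensively with canonical tie-break).
#' @param top_k_pairs Number of top pairs to keep as edges (default 10).
#' @return Object of class `coprescription_network`: list with `nodes`
#'   (tibble `chm_id`, `chm_type`, `prevalence_pct`, `instances`), `edges`
#'   (tibble `chm_a`, `chm_b`, `count`), and `metadata` (list with
#'   `top_k`).
#' @examples
#' ref <- pms_reference_tables()
#' net <- build_network(ref$items, ref$pairs, top_k_pairs = 10)
#' identify_core(net)
#' @export
build_network <- function(item_rows, pair_rows, top_k_pairs = 10) {
  pair_rows <- dplyr::arrange(tibble::as_tibble(pair_rows),
                              dplyr::desc(.data$instances),
                              .data$chm_a, .data$chm_b)
  edges <- utils::head(pair_rows, top_k_pairs)
  node_ids <- sort(unique(c(edges$chm_a, edges$chm_b)))
  missing <- setdiff(node_ids, item_rows$chm_id)
  if (length(missing)) {
    stop(sprintf(
      "inconsistent inputs: pair endpoint(s) %s absent from item table",
      paste(missing, collapse = ", ")), call. = FALSE)
  }
  item_rows <- tibble::as_tibble(item_rows)
  if (!"instances" %in% names(item_rows)) item_rows$instances <- NA_integer_
  nodes <- item_rows[match(node_ids, item_rows$chm_id),
                     c("chm_id", "chm_type", "prevalence_pct", "instances")]
  # edge weight can never exceed either endpoint's single-item count
  inst_of <- stats::setNames(nodes$instances, nodes$chm_id)
  cap <- pmin(inst_of[edges$chm_a], inst_of[edges$chm_b])
  bad <- which(!is.na(cap) & edges$instances > cap)
  if (length(bad)) {
    stop(sprintf(
      "inconsistent inputs: pair %s-%s count %d exceeds an endpoint's instances",
      edges$chm_a[bad[1]], edges$chm_b[bad[1]], edges$instances[bad[1]]),
      call. = FALSE)
  }
  # edges are undirected: store endpoints in lexicographic orientation so
  # exports and re-imports are bit-identical
  edge_tab <- tibble::tibble(chm_a = pmin(edges$chm_a, edges$chm_b),
                             chm_b = pmax(edges$chm_a, edges$chm_b),
                             count = as.integer(edges$instances))
  edge_tab <- dplyr::arrange(edge_tab, dplyr::desc(.data$count),
                             .data$chm_a, .data$chm_b)
  structure(
    list(nodes = nodes,
         edges = edge_tab,
         metadata = list(top_k = as.integer(top_k_pairs))),
    class = "coprescription_network"
  )
}

#' @export
print.coprescription_network <- function(x, ...) {
  cat(sprintf("<coprescription_network> %d nodes, %d edges (top %d pairs)\n",
              nrow(x$nodes), nrow(x$edges), x$metadata$top_k))
  invisible(x)
}

#' Weighted degree of network nodes
#'
#' The weighted degree of a CHM is the sum of co-occurrence counts on its
#' incident edges — the total frequency of its connections.
#'
#' @param network A `coprescription_network`.
#' @param chm_id A node id, or `NULL` (default) for all nodes.
#' @return Named numeric vector of weighted degrees (a single value when
#'   `chm_id` is given).
#' @export
weighted_degree <- function(network, chm_id = NULL) {
  stopifnot(inherits(network, "coprescription_network"))
  wd <- stats::setNames(numeric(nrow(network$nodes)), network$nodes$chm_id)
  for (i in seq_len(nrow(network$edges))) {
    e <- network$edges[i, ]
    wd[e$chm_a] <- wd[e$chm_a] + e$count
    wd[e$chm_b] <- wd[e$chm_b] + e$count
  }
  if (is.null(chm_id)) return(wd)
  if (!chm_id %in% names(wd)) {
    stop(sprintf("unknown node: %s", chm_id), call. = FALSE)
  }
  wd[chm_id]
}

#' Identify the core treatment of a network
#'
#' The core is the node with maximum weighted degree — the hub the rest of
#' the prescription network attaches to, interpreted in the field as the
#' principal therapy. Ties are broken by higher prevalence, then by
#' canonical (lexicographic) id, so the result is invariant to input
#' order.
#'
#' @param network A non-empty `coprescription_network`.
#' @return The `chm_id` of the core node.
#' @export
identify_core <- function(network) {
  stopifnot(inherits(network, "coprescription_network"))
  if (nrow(network$nodes) == 0) stop("empty network", call. = FALSE)
  wd <- weighted_degree(network)
  prev <- network$nodes$prevalence_pct[match(names(wd),
                                             network$nodes$chm_id)]
  prev[is.na(prev)] <- -Inf
  ord <- order(-wd, -prev, names(wd))
  names(wd)[ord[1]]
}

#' Export / import a co-prescription network
#'
#' GraphML carries node attributes `prevalence_pct` and `chm_type` and the
#' edge attribute `count` (plus the graph attribute `top_k`), and
#' round-trips the network exactly. The edge-list format is three-column
#' delimited text (`chm_a,chm_b,count`); importing an edge list recovers
#' the topology and weights but node attributes come back `NA`.
#'
#' @param network A `coprescription_network`.
#' @param path Output file.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `export_graph()` returns `path` invisibly; `import_graph()`
#'   returns a `coprescription_network`.
#' @export
export_graph <- function(network, path, format = c("graphml", "edgelist")) {
  stopifnot(inherits(network, "coprescription_network"))
  format <- match.arg(format)
  if (format == "edgelist") {
    readr::write_csv(network$edges, path)
    return(invisible(path))
  }
  g <- as_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graph <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    edges <- readr::read_csv(path, col_types = "cci")
    nodes <- tibble::tibble(chm_id = sort(unique(c(edges$chm_a,
                                                   edges$chm_b))),
                            chm_type = NA_character_,
                            prevalence_pct = NA_real_,
                            instances = NA_integer_)
    return(structure(list(nodes = nodes, edges = edges,
                          metadata = list(top_k = nrow(edges))),
                     class = "coprescription_network"))
  }
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::vcount(g) == 0) {
    return(structure(
      list(nodes = tibble::tibble(chm_id = character(),
                                  chm_type = character(),
                                  prevalence_pct = numeric(),
                                  instances = integer()),
           edges = tibble::tibble(chm_a = character(), chm_b = character(),
                                  count = integer()),
           metadata = list(top_k = as.integer(igraph::graph_attr(g, "top_k")))),
      class = "coprescription_network"))
  }
  nodes <- tibble::tibble(
    chm_id = igraph::V(g)$name,
    chm_type = igraph::V(g)$chm_type,
    prevalence_pct = clean_na(igraph::V(g)$prevalence_pct),
    instances = as.integer(clean_na(igraph::V(g)$instances))
  )
  el <- igraph::as_edgelist(g)
  edges <- tibble::tibble(
    chm_a = pmin(el[, 1], el[, 2]),
    chm_b = pmax(el[, 1], el[, 2]),
    count = as.integer(igraph::E(g)$count)
  )
  ord <- order(nodes$chm_id)
  nodes <- nodes[ord, ]
  eord <- order(-edges$count, edges$chm_a, edges$chm_b)
  structure(list(nodes = nodes, edges = edges[eord, ],
                 metadata = list(top_k = as.integer(igraph::graph_attr(
                   g, "top_k")))),
            class = "coprescription_network")
}

clean_na <- function(x) {
  x[is.nan(x)] <- NA_real_
  x
}

#' Convert a network to an igraph object
#'
#' @param network A `coprescription_network`.
#' @return An undirected weighted `igraph` graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "coprescription_network"))
  vertices <- data.frame(
    name = network$nodes$chm_id,
    chm_type = network$nodes$chm_type,
    prevalence_pct = network$nodes$prevalence_pct,
    instances = as.numeric(network$nodes$instances)
  )
  g <- igraph::graph_from_data_frame(
    data.frame(from = network$edges$chm_a, to = network$edges$chm_b,
               count = as.numeric(network$edges$count)),
    directed = FALSE, vertices = vertices)
  igraph::graph_attr(g, "top_k") <- as.numeric(network$metadata$top_k)
  g
}

#' Plot a co-prescription network
#'
#' Force-directed layout with node area proportional to prevalence and
#' edge width proportional to co-occurrence count.
#'
#' @param x A `coprescription_network`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @return Invisibly, `x`.
#' @export
plot.coprescription_network <- function(x, ...) {
  g <- as_igraph(x)
  prev <- igraph::V(g)$prevalence_pct
  prev[is.na(prev) | is.nan(prev)] <- min(prev, na.rm = TRUE)
  size <- 10 + 30 * sqrt(prev / max(prev))
  width <- 1 + 6 * igraph::E(g)$count / max(igraph::E(g)$count)
  igraph::plot.igraph(
    g, vertex.size = size, edge.width = width,
    vertex.color = ifelse(igraph::V(g)$chm_type == "HF",
                          "lightsteelblue", "palegreen3"),
    layout = igraph::layout_with_fr(g), ...)
  invisible(x)
}
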