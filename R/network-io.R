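# Conversion between cerna_network and igraph objects (used for GraphML
# I/O and plotting).
network_to_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = network$edges$from, to = network$edges$to,
                   edge_type = network$edges$edge_type),
    directed = FALSE,
    vertices = data.frame(name = network$nodes$id,
                          type = network$nodes$type,
                          direction = network$nodes$direction,
                          degree = network$nodes$degree))
  g <- igraph::set_graph_attr(g, "trend", as.character(network$trend))
  g
}

igraph_to_network <- function(g) {
  nodes <- tibble(id = igraph::V(g)$name, type = igraph::V(g)$type,
                  direction = igraph::V(g)$direction,
                  degree = as.integer(igraph::V(g)$degree))
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- tibble(from = el$from, to = el$to, edge_type = el$edge_type)
  # igraph may normalize endpoint order of undirected edges; restore the
  # regulator-first orientation (lncRNA->miRNA, miRNA->mRNA) from node types
  ntype <- setNames(nodes$type, nodes$id)
  want_from <- ifelse(edges$edge_type == "lnc_mir", "lncRNA", "miRNA")
  flip <- ntype[edges$from] != want_from
  tmp <- edges$from[flip]
  edges$from[flip] <- edges$to[flip]
  edges$to[flip] <- tmp
  trend <- igraph::graph_attr(g, "trend")
  nodes <- arrange(nodes, .data$type, .data$id)
  edges <- arrange(edges, .data$edge_type, .data$from, .data$to)
  structure(list(nodes = nodes, edges = edges,
                 trend = if (is.null(trend)) NA_character_ else trend),
            class = "cerna_network")
}

#' Export a ceRNA network
#'
#' `json` and `graphml` preserve node attributes (type, direction, degree)
#' and round-trip to an identical network; `sif` (rows
#' `source<TAB>interaction_type<TAB>target`) preserves topology and edge
#' types only.
#'
#' @param network A `cerna_network`.
#' @param path Output file path.
#' @param format One of `"json"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("json", "sif", "graphml")) {
  stopifnot(inherits(network, "cerna_network"))
  format <- match.arg(format)
  if (nrow(network$nodes) == 0) abort("Refusing to export an empty network.")
  switch(format,
    sif = {
      readr::write_lines(paste(network$edges$from, network$edges$edge_type,
                               network$edges$to, sep = "\t"), path)
    },
    graphml = {
      igraph::write_graph(network_to_igraph(network), path, format = "graphml")
    },
    json = {
      jsonlite::write_json(list(trend = network$trend,
                                nodes = network$nodes,
                                edges = network$edges),
                           path, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA)
    })
  invisible(path)
}

#' Import a ceRNA network written by [export_network()]
#'
#' @param path File path.
#' @param format One of `"json"`, `"sif"`, `"graphml"`.
#' @return A `cerna_network`. For SIF, node directions are `NA` and the
#'   trend is unknown (topology-only format).
#' @export
import_network <- function(path, format = c("json", "sif", "graphml")) {
  format <- match.arg(format)
  switch(format,
    graphml = igraph_to_network(igraph::read_graph(path, format = "graphml")),
    json = {
      x <- jsonlite::read_json(path, simplifyVector = TRUE)
      new_network(as_tibble(x$nodes[, c("id", "type", "direction")]),
                  as_tibble(x$edges), x$trend)
    },
    sif = {
      rows <- strsplit(readr::read_lines(path), "\t", fixed = TRUE)
      if (any(lengths(rows) != 3)) abort("Malformed SIF row.")
      edges <- tibble(from = vapply(rows, `[[`, character(1), 1),
                      edge_type = vapply(rows, `[[`, character(1), 2),
                      to = vapply(rows, `[[`, character(1), 3))
      nodes <- bind_rows(
        tibble(id = edges$from[edges$edge_type == "lnc_mir"], type = "lncRNA"),
        tibble(id = unique(c(edges$to[edges$edge_type == "lnc_mir"],
                             edges$from[edges$edge_type == "mir_mrna"])),
               type = "miRNA"),
        tibble(id = edges$to[edges$edge_type == "mir_mrna"], type = "mRNA"))
      nodes <- distinct(nodes)
      nodes$direction <- NA_character_
      new_network(nodes, edges[, c("from", "to", "edge_type")], NA_character_)
    })
}

#' One-row accounting summary per trend network
#'
#' @param networks Named list of `cerna_network` objects.
#' @return Tibble with one row per network: trend, node/edge/hub counts
#'   and per-class node counts.
#' @export
network_summary <- function(networks) {
  bind_rows(lapply(networks, glance))
}
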