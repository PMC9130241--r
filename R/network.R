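#' Assemble direction-annotated ceRNA triples
#'
#' Enumerates every (lncRNA, miRNA, mRNA) combination where the lncRNA and
#' the mRNA share the miRNA, joining the filtered lncRNA-miRNA and
#' miRNA-mRNA pair lists. The trend is `HLH` for directions
#' (up, down, up), `LHL` for (down, up, down), and `discordant` otherwise.
#'
#' @param lnc_mir Tibble `lncRNA`, `miRNA` with `lnc_direction`,
#'   `mir_direction` (see [filter_pairs_to_de()]), or bare pairs plus a
#'   `directions` table.
#' @param mir_mrna Tibble `miRNA`, `mRNA` with `mir_direction`,
#'   `mrna_direction`, or bare pairs.
#' @param directions Optional tibble `gene`, `direction` used to annotate
#'   bare pair lists; any molecule without a direction is an error.
#' @return Tibble of triples: `lncRNA`, `miRNA`, `mRNA`, `lnc_direction`,
#'   `mir_direction`, `mrna_direction`, `trend`.
#' @export
assemble_triples <- function(lnc_mir, mir_mrna, directions = NULL) {
  lnc_mir <- as_tibble(lnc_mir)
  mir_mrna <- as_tibble(mir_mrna)
  if (!all(c("lncRNA", "miRNA") %in% names(lnc_mir))) {
    names(lnc_mir)[1:2] <- c("lncRNA", "miRNA")
  }
  if (!all(c("miRNA", "mRNA") %in% names(mir_mrna))) {
    names(mir_mrna)[1:2] <- c("miRNA", "mRNA")
  }
  if (!is.null(directions)) {
    dd <- setNames(directions$direction, directions$gene)
    lnc_mir$lnc_direction <- unname(dd[lnc_mir$lncRNA])
    lnc_mir$mir_direction <- unname(dd[lnc_mir$miRNA])
    mir_mrna$mir_direction <- unname(dd[mir_mrna$miRNA])
    mir_mrna$mrna_direction <- unname(dd[mir_mrna$mRNA])
  }
  need_lm <- c("lnc_direction", "mir_direction")
  need_mm <- c("mir_direction", "mrna_direction")
  if (!all(need_lm %in% names(lnc_mir)) || !all(need_mm %in% names(mir_mrna))) {
    abort("Pair lists must carry directions (or supply `directions`).")
  }
  tri <- inner_join(
    distinct(lnc_mir[, c("lncRNA", "miRNA", "lnc_direction", "mir_direction")]),
    distinct(mir_mrna[, c("miRNA", "mRNA", "mrna_direction")]),
    by = "miRNA", relationship = "many-to-many")
  if (anyNA(tri[, c("lnc_direction", "mir_direction", "mrna_direction")])) {
    abort("A triple member is missing a differential-expression direction.")
  }
  tri %>%
    mutate(trend = case_when(
      .data$lnc_direction == "up" & .data$mir_direction == "down" &
        .data$mrna_direction == "up" ~ "HLH",
      .data$lnc_direction == "down" & .data$mir_direction == "up" &
        .data$mrna_direction == "down" ~ "LHL",
      TRUE ~ "discordant"
    )) %>%
    dplyr::select("lncRNA", "miRNA", "mRNA", "lnc_direction",
                  "mir_direction", "mrna_direction", "trend") %>%
    arrange(.data$lncRNA, .data$miRNA, .data$mRNA)
}

#' Partition triples by expression trend
#'
#' Discordant triples are discarded (and counted); the HLH and LHL lists
#' are disjoint and together exhaust the concordant triples.
#'
#' @param triples [assemble_triples()] output.
#' @return List with `HLH`, `LHL` (triple tibbles) and `n_discordant`.
#' @export
split_by_direction <- function(triples) {
  stopifnot("trend" %in% names(triples))
  list(HLH = filter(triples, .data$trend == "HLH"),
       LHL = filter(triples, .data$trend == "LHL"),
       n_discordant = sum(triples$trend == "discordant"))
}

#' Build the typed ceRNA network from same-trend triples
#'
#' Nodes are the union of triple members (typed lncRNA/miRNA/mRNA, with
#' direction and unique-edge degree); edges are the de-duplicated union of
#' (lncRNA, miRNA) and (miRNA, mRNA) pairs, undirected.
#'
#' @param triples Triples sharing a single trend (mixed trends error).
#' @return A `cerna_network`: list with `nodes` (tibble `id`, `type`,
#'   `direction`, `degree`), `edges` (tibble `from`, `to`, `edge_type`)
#'   and `trend`.
#' @export
build_graph <- function(triples) {
  trends <- unique(triples$trend)
  if (length(trends) > 1) {
    abort("`triples` mixes trends; split with split_by_direction() first.")
  }
  trend <- if (length(trends)) trends else NA_character_
  edges <- bind_rows(
    distinct(tibble(from = triples$lncRNA, to = triples$miRNA,
                    edge_type = "lnc_mir")),
    distinct(tibble(from = triples$miRNA, to = triples$mRNA,
                    edge_type = "mir_mrna"))
  )
  nodes <- bind_rows(
    distinct(tibble(id = triples$lncRNA, type = "lncRNA",
                    direction = triples$lnc_direction)),
    distinct(tibble(id = triples$miRNA, type = "miRNA",
                    direction = triples$mir_direction)),
    distinct(tibble(id = triples$mRNA, type = "mRNA",
                    direction = triples$mrna_direction))
  )
  if (anyDuplicated(nodes$id)) {
    abort("Node identifier collides across RNA classes or directions.")
  }
  new_network(nodes, edges, trend)
}

new_network <- function(nodes, edges, trend) {
  deg <- table(c(edges$from, edges$to))
  nodes$degree <- as.integer(deg[nodes$id])
  nodes$degree[is.na(nodes$degree)] <- 0L
  nodes <- arrange(nodes, .data$type, .data$id)
  edges <- arrange(distinct(edges), .data$edge_type, .data$from, .data$to)
  structure(list(nodes = nodes, edges = edges, trend = trend),
            class = "cerna_network")
}

#' Hub nodes of a ceRNA network
#'
#' Nodes whose unique-edge degree strictly exceeds `hub_threshold`
#' (default 5, i.e. "more than five interactions"), sorted by descending
#' degree, ties broken by ID.
#'
#' @param network A `cerna_network`.
#' @param hub_threshold Strict degree threshold.
#' @return Tibble with `id`, `type`, `direction`, `degree`.
#' @export
find_hubs <- function(network, hub_threshold = 5) {
  stopifnot(inherits(network, "cerna_network"))
  network$nodes %>%
    filter(.data$degree > hub_threshold) %>%
    arrange(desc(.data$degree), .data$id)
}

#' Extract the subnetwork seeded by a set of mRNAs
#'
#' Keeps the seed mRNAs, every miRNA adjacent to them, every lncRNA
#' adjacent to those miRNAs, and only the connecting edges, so every
#' retained node lies on a path to a seed mRNA. Seeds absent from the
#' network are skipped with a warning; an empty seed list is an error.
#' Degrees are recomputed within the subnetwork, making the operation
#' idempotent.
#'
#' @param network A `cerna_network`.
#' @param seed_mrnas Character vector of seed mRNA IDs.
#' @return A `cerna_network`.
#' @export
extract_subnetwork <- function(network, seed_mrnas) {
  stopifnot(inherits(network, "cerna_network"))
  if (length(seed_mrnas) == 0) abort("`seed_mrnas` is empty.")
  mrnas <- network$nodes$id[network$nodes$type == "mRNA"]
  missing <- setdiff(seed_mrnas, mrnas)
  if (length(missing)) {
    warn(sprintf("Seed mRNA(s) not in network, skipped: %s",
                 paste(missing, collapse = ", ")))
  }
  seeds <- intersect(seed_mrnas, mrnas)
  if (!length(seeds)) abort("No seed mRNA is present in the network.")
  e_mm <- filter(network$edges, .data$edge_type == "mir_mrna",
                 .data$to %in% seeds)
  mirs <- unique(e_mm$from)
  e_lm <- filter(network$edges, .data$edge_type == "lnc_mir",
                 .data$to %in% mirs)
  edges <- bind_rows(e_lm, e_mm)
  keep_ids <- unique(c(edges$from, edges$to, seeds))
  nodes <- filter(network$nodes, .data$id %in% keep_ids)
  nodes$degree <- NULL
  new_network(nodes, edges, network$trend)
}

#' Compare two ceRNA networks for equality
#'
#' @param a,b `cerna_network` objects.
#' @param attributes Compare node direction/degree attributes too
#'   (set `FALSE` for topology-only formats such as SIF).
#' @return `TRUE` or `FALSE`.
#' @export
network_equal <- function(a, b, attributes = TRUE) {
  cols <- if (attributes) c("id", "type", "direction", "degree") else c("id", "type")
  na <- arrange(a$nodes[, cols], .data$id)
  nb <- arrange(b$nodes[, cols], .data$id)
  ea <- arrange(a$edges, .data$edge_type, .data$from, .data$to)
  eb <- arrange(b$edges, .data$edge_type, .data$from, .data$to)
  isTRUE(all.equal(as.data.frame(na), as.data.frame(nb),
                   check.attributes = FALSE)) &&
    isTRUE(all.equal(as.data.frame(ea), as.data.frame(eb),
                     check.attributes = FALSE))
}

#' @export
print.cerna_network <- function(x, ...) {
  cc <- table(factor(x$nodes$type, levels = c("lncRNA", "miRNA", "mRNA")))
  cat(sprintf("<cerna_network> trend %s: %d nodes (%d lncRNA, %d miRNA, %d mRNA), %d edges\n",
              x$trend, nrow(x$nodes), cc[["lncRNA"]], cc[["miRNA"]],
              cc[["mRNA"]], nrow(x$edges)))
  invisible(x)
}

#' @rdname build_graph
#' @param x A `cerna_network`.
#' @param ... Unused.
#' @export
glance.cerna_network <- function(x, ...) {
  cc <- table(factor(x$nodes$type, levels = c("lncRNA", "miRNA", "mRNA")))
  tibble(trend = x$trend, n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_lnc = as.integer(cc[["lncRNA"]]), n_mir = as.integer(cc[["miRNA"]]),
         n_mrna = as.integer(cc[["mRNA"]]),
         n_hubs = nrow(find_hubs(x)))
}

#' @rdname build_graph
#' @export
tidy.cerna_network <- function(x, ...) x$nodes

#' @rdname build_graph
#' @param object A `cerna_network`.
#' @export
autoplot.cerna_network <- function(object, ...) {
  g <- network_to_igraph(object)
  set.seed(1)
  xy <- igraph::layout_with_fr(g)
  nd <- object$nodes
  nd$x <- xy[, 1]; nd$y <- xy[, 2]
  ed <- object$edges
  ed$x <- nd$x[match(ed$from, nd$id)]
  ed$y <- nd$y[match(ed$from, nd$id)]
  ed$xend <- nd$x[match(ed$to, nd$id)]
  ed$yend <- nd$y[match(ed$to, nd$id)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend), colour = "grey75") +
    ggplot2::geom_point(data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$type,
                   colour = .data$direction, size = .data$degree)) +
    ggplot2::scale_colour_manual(values = c(up = "#d73027", down = "#4575b4")) +
    ggplot2::theme_void()
}
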