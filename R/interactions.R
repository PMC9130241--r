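#' Read a regulator-target interaction table
#'
#' Expects a TSV with at least two columns (regulator, target); a header
#' row naming them is tolerated and skipped; extra columns (e.g. scores)
#' are ignored. Pairs are de-duplicated and whitespace-trimmed; IDs are
#' matched exactly with case preserved.
#'
#' @param path Path to the TSV file.
#' @param source_label Label recorded in the `source` column.
#' @return Tibble with `regulator`, `target`, `source`.
#' @export
read_interaction_table <- function(path, source_label) {
  lines <- readr::read_lines(path)
  keep_idx <- which(!grepl("^\\s*$", lines))
  if (!length(keep_idx)) {
    warn(sprintf("Interaction file '%s' is empty.", path))
    return(tibble(regulator = character(), target = character(),
                  source = character()))
  }
  fields <- strsplit(lines[keep_idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2)
  if (length(bad)) {
    abort(sprintf("Malformed interaction row (fewer than 2 columns) at line %d of '%s'.",
                  keep_idx[bad[1]], path))
  }
  first <- tolower(trimws(fields[[1]][1:2]))
  if (identical(first, c("regulator", "target"))) fields <- fields[-1]
  reg <- trimws(vapply(fields, `[[`, character(1), 1))
  tgt <- trimws(vapply(fields, `[[`, character(1), 2))
  if (any(reg == "" | tgt == "")) {
    abort(sprintf("Empty regulator or target ID in '%s'.", path))
  }
  tab <- tibble(regulator = reg, target = tgt)
  n0 <- nrow(tab)
  tab <- distinct(tab)
  if (nrow(tab) < n0) {
    inform(sprintf("%s: %d rows read, %d duplicate pair(s) removed.",
                   source_label, n0, n0 - nrow(tab)))
  }
  mutate(tab, source = source_label)
}

#' Multi-source consensus miRNA-target map
#'
#' Retains a miRNA-mRNA pair iff it appears in at least `min_sources`
#' distinct sources, recording per-pair support. With `min_sources = 1`
#' this is the union of all sources; raising `min_sources` can only remove
#' pairs.
#'
#' @param tables A list of interaction tibbles (`regulator`, `target`,
#'   `source`) or one tibble carrying several source labels.
#' @param min_sources Minimum number of distinct supporting sources
#'   (default: require all sources, the strict-intersection reading).
#' @return Tibble with `mirna`, `mrna`, `n_sources`, `sources`
#'   (comma-joined, sorted labels).
#' @export
consensus_targets <- function(tables, min_sources = NULL) {
  if (is.data.frame(tables)) tables <- list(tables)
  all_tab <- bind_rows(tables)
  if (!all(c("regulator", "target", "source") %in% names(all_tab))) {
    abort("Interaction tables need columns regulator, target, source.")
  }
  n_src <- n_distinct(all_tab$source)
  min_sources <- min_sources %||% n_src
  if (min_sources < 1 || min_sources > n_src) {
    abort(sprintf("`min_sources` must lie in [1, %d].", n_src))
  }
  all_tab %>%
    distinct(.data$regulator, .data$target, .data$source) %>%
    group_by(mirna = .data$regulator, mrna = .data$target) %>%
    summarise(n_sources = n(),
              sources = paste(sort(.data$source), collapse = ","),
              .groups = "drop") %>%
    filter(.data$n_sources >= min_sources) %>%
    arrange(.data$mirna, .data$mrna)
}

#' Restrict interaction pairs to differentially expressed molecules
#'
#' Keeps a lncRNA-miRNA pair iff both members are DEGs of their class and
#' a consensus miRNA-mRNA pair iff both members are DEGs; the DE direction
#' of every retained molecule is attached. An identifier appearing in more
#' than one DEG class is a namespace collision and an error.
#'
#' @param lnc_mir Interaction tibble (`regulator` = lncRNA,
#'   `target` = miRNA).
#' @param consensus [consensus_targets()] result (`mirna`, `mrna`).
#' @param deg_lnc,deg_mir,deg_mrna DEG tibbles with `gene`, `direction`
#'   (e.g. [degs()] output per class).
#' @return List with tibbles `lnc_mir` (`lncRNA`, `miRNA`,
#'   `lnc_direction`, `mir_direction`) and `mir_mrna` (`miRNA`, `mRNA`,
#'   `mir_direction`, `mrna_direction`).
#' @export
filter_pairs_to_de <- function(lnc_mir, consensus, deg_lnc, deg_mir, deg_mrna) {
  sets <- list(lncRNA = deg_lnc, miRNA = deg_mir, mRNA = deg_mrna)
  for (nm in names(sets)) {
    if (!all(c("gene", "direction") %in% names(sets[[nm]]))) {
      abort(sprintf("DEG set for %s needs columns gene and direction.", nm))
    }
  }
  ids <- unlist(lapply(sets, function(s) unique(s$gene)))
  if (anyDuplicated(ids)) {
    abort(sprintf("Identifier(s) present in multiple DEG classes: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  dir_of <- function(s) setNames(s$direction, s$gene)
  dl <- dir_of(deg_lnc); dm <- dir_of(deg_mir); dg <- dir_of(deg_mrna)
  lm <- lnc_mir %>%
    distinct(lncRNA = .data$regulator, miRNA = .data$target) %>%
    filter(.data$lncRNA %in% names(dl), .data$miRNA %in% names(dm)) %>%
    mutate(lnc_direction = unname(dl[.data$lncRNA]),
           mir_direction = unname(dm[.data$miRNA]))
  mm <- consensus %>%
    distinct(miRNA = .data$mirna, mRNA = .data$mrna) %>%
    filter(.data$miRNA %in% names(dm), .data$mRNA %in% names(dg)) %>%
    mutate(mir_direction = unname(dm[.data$miRNA]),
           mrna_direction = unname(dg[.data$mRNA]))
  list(lnc_mir = lm, mir_mrna = mm)
}
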