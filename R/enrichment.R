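#' Gene-set collection
#'
#' A named list of member-gene vectors plus the background universe
#' against which over-representation is tested. Members outside the
#' universe are dropped at test time; empty sets are rejected.
#'
#' @param sets Named list of character vectors.
#' @param universe Character vector of background genes.
#' @return A `geneset_collection`.
#' @export
geneset_collection <- function(sets, universe) {
  if (!length(universe)) abort("`universe` is empty.")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("All gene sets must be named.")
  }
  if (any(lengths(sets) == 0)) abort("Gene sets must be non-empty.")
  structure(list(sets = lapply(sets, unique), universe = unique(universe)),
            class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("<geneset_collection> %d sets over a %d-gene universe\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member...`.
#'
#' @param path GMT file path.
#' @param universe Background genes; defaults to the union of all members.
#' @return A [geneset_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  sets <- fgsea::gmtPathways(path)
  geneset_collection(sets, universe %||% unique(unlist(sets)))
}

#' Write a gene-set collection to GMT
#'
#' @param collection A [geneset_collection()] (or named list of sets).
#' @param path Output path.
#' @param descriptions Optional named character vector of set descriptions
#'   (defaults to `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  sets <- if (inherits(collection, "geneset_collection")) collection$sets else collection
  desc <- descriptions %||% setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, unname(desc[nm]), sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' One-sided hypergeometric over-representation p-value
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' drawn from a universe of `N` containing `K` annotated:
#' `p = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`, evaluated
#' through the log-space-stable hypergeometric tail.
#'
#' @param k Overlap between query and set.
#' @param K Set size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return The upper-tail p-value in (0, 1].
#' @export
#' @examples
#' hypergeometric_test(5, 5, 5, 10)  # = 1 / choose(10, 5)
hypergeometric_test <- function(k, K, n, N) {
  if (any(K > N) || any(n > N) || any(k < 0) || any(k > pmin(K, n))) {
    abort("Require 0 <= k <= min(K, n), K <= N, n <= N.")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a query gene list
#'
#' Restricts the query and every set to the universe, tests each set with
#' at least one overlapping gene by the one-sided hypergeometric test,
#' adjusts across tested sets with Benjamini-Hochberg, flags significance
#' at raw `p < alpha` (the FDR is reported alongside), and sorts by
#' p-value.
#'
#' @param query Character vector of query genes.
#' @param collection A [geneset_collection()].
#' @param alpha Raw-p significance threshold (default 0.05).
#' @return A tibble of class `cerna_enrichment`: `term`, `k`, `K`, `n`,
#'   `N`, `pvalue`, `fdr`, `significant`.
#' @export
enrich <- function(query, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "geneset_collection"))
  uni <- collection$universe
  if (!length(uni)) abort("Universe is empty.")
  q <- intersect(unique(query), uni)
  if (!length(q)) abort("Query has no genes in the universe.")
  rows <- purrr::map_dfr(names(collection$sets), function(nm) {
    s <- intersect(collection$sets[[nm]], uni)
    k <- length(intersect(q, s))
    if (k == 0 || length(s) == 0) return(NULL)
    tibble(term = nm, k = k, K = length(s), n = length(q), N = length(uni))
  })
  if (nrow(rows) == 0) {
    out <- tibble(term = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), pvalue = double(),
                  fdr = double(), significant = logical())
    class(out) <- c("cerna_enrichment", class(out))
    return(out)
  }
  rows$pvalue <- hypergeometric_test(rows$k, rows$K, rows$n, rows$N)
  rows$fdr <- bh_adjust(rows$pvalue)
  rows$significant <- rows$pvalue < alpha
  out <- arrange(rows, .data$pvalue, .data$term)
  class(out) <- c("cerna_enrichment", class(out))
  out
}

#' @rdname enrich
#' @param object A `cerna_enrichment` table.
#' @param top Number of top terms to draw.
#' @param ... Unused.
#' @export
autoplot.cerna_enrichment <- function(object, top = 15, ...) {
  dat <- head(as_tibble(object), top)
  dat$term <- factor(dat$term, levels = rev(dat$term))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$k / .data$n, y = .data$term,
                                    size = .data$k,
                                    colour = -log10(.data$pvalue))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "gene ratio (k / n)", y = NULL, size = "overlap",
                  colour = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}
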