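#' Simulate paired tumour/normal count matrices with planted ceRNA triples
#'
#' Draws gene-level counts for the three RNA classes from a
#' negative-binomial model. For gene g in sample i the mean is
#' `L_i * b_g * 2^(s_g * effect_log2fc * [tumour_i])`, where `L_i` is the
#' sample library size, `b_g` a relative baseline abundance (log-uniform
#' across four decades) and `s_g` is +1, -1 or 0 according to the planted
#' direction. The variance is `mu + phi * mu^2`; `phi = 0` gives Poisson
#' counts. Every member of every planted triple is differentially
#' expressed with the direction implied by the triple's trend: HLH plants
#' (lnc up, mir down, mRNA up) and LHL the reverse.
#'
#' @param config A [sim_config()].
#' @return A list of class `cerna_sim` with elements
#'   * `counts`: named list (`lncRNA`, `miRNA`, `mRNA`) of counts tibbles
#'     (`gene_id` + one column per sample),
#'   * `samples`: sample sheet tibble (`sample`, `condition`, `patient`),
#'   * `truth`: the planted truth (see [truth_consistent()]).
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_lnc = 20, n_mir = 10, n_mrna = 50,
#'                                   n_triples = 3, n_survival_genes = 2))
#' sim$truth$triples
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    genes <- list(
      lncRNA = sprintf("LNC%04d", seq_len(config$n_lnc)),
      miRNA  = sprintf("MIR%04d", seq_len(config$n_mir)),
      mRNA   = sprintf("MRNA%05d", seq_len(config$n_mrna))
    )
    nt <- config$n_triples
    triples <- tibble(
      lncRNA = sample(genes$lncRNA, nt),
      miRNA  = sample(genes$miRNA, nt),
      mRNA   = sample(genes$mRNA, nt),
      trend  = sample(c("HLH", "LHL"), nt, replace = TRUE)
    )
    de_genes <- bind_rows(
      tibble(gene = triples$lncRNA, class = "lncRNA",
             direction = ifelse(triples$trend == "HLH", "up", "down")),
      tibble(gene = triples$miRNA, class = "miRNA",
             direction = ifelse(triples$trend == "HLH", "down", "up")),
      tibble(gene = triples$mRNA, class = "mRNA",
             direction = ifelse(triples$trend == "HLH", "up", "down"))
    )
    surv_mrnas <- if (config$n_survival_genes > 0) {
      sample(triples$mRNA, config$n_survival_genes)
    } else character()
    survival_genes <- tibble(
      gene = surv_mrnas,
      risk_direction = if (length(surv_mrnas)) {
        rep_len(c("high", "low"), length(surv_mrnas))[sample(length(surv_mrnas))]
      } else character()
    )
    truth <- structure(list(
      de_genes = de_genes,
      triples = triples,
      enriched_set = sprintf("GS%03d", sample(config$n_genesets, 1)),
      survival_genes = survival_genes,
      genes = genes
    ), class = "cerna_truth")

    n_smp <- 2 * config$n_pairs
    samples <- tibble(
      sample = c(sprintf("T%d", seq_len(config$n_pairs)),
                 sprintf("N%d", seq_len(config$n_pairs))),
      condition = rep(c("tumour", "normal"), each = config$n_pairs),
      patient = rep(sprintf("P%d", seq_len(config$n_pairs)), 2)
    )
    lib_sizes <- round(runif(n_smp, config$lib_size_range[1],
                             config$lib_size_range[2]))
    is_tum <- samples$condition == "tumour"

    counts <- lapply(names(genes), function(cls) {
      ids <- genes[[cls]]
      base <- 10^runif(length(ids), config$baseline_log10_range[1],
                       config$baseline_log10_range[2])
      planted <- de_genes$gene[de_genes$class == cls]
      idx <- match(planted, ids)
      base[idx] <- 10^runif(length(idx), config$planted_log10_range[1],
                            config$planted_log10_range[2])
      rel <- base / sum(base)
      s <- numeric(length(ids))
      s[idx] <- ifelse(de_genes$direction[de_genes$class == cls] == "up", 1, -1)
      mu <- outer(rel, lib_sizes) *
        2^(outer(s, as.numeric(is_tum)) * config$effect_log2fc)
      y <- if (config$dispersion == 0) {
        rpois(length(mu), lambda = mu)
      } else {
        rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
      }
      mat <- matrix(y, nrow = length(ids), dimnames = list(ids, samples$sample))
      matrix_to_counts(mat)
    })
    names(counts) <- names(genes)
    structure(list(counts = counts, samples = samples, truth = truth),
              class = "cerna_sim")
  })
}

#' Check internal consistency of a planted truth
#'
#' Pure predicate: every planted triple must carry directions matching its
#' trend (HLH = up/down/up for lncRNA/miRNA/mRNA, LHL the reverse), and
#' every triple member must appear in the planted DE table with exactly
#' that direction.
#'
#' @param truth The `truth` element of a [simulate_counts()] result.
#' @return `TRUE` or `FALSE`.
#' @export
truth_consistent <- function(truth) {
  dirs <- truth$de_genes
  look <- function(g, cls) {
    d <- dirs$direction[dirs$gene == g & dirs$class == cls]
    if (length(d) == 1) d else NA_character_
  }
  ok <- vapply(seq_len(nrow(truth$triples)), function(i) {
    tr <- truth$triples[i, ]
    expect <- if (tr$trend == "HLH") c("up", "down", "up") else c("down", "up", "down")
    identical(c(look(tr$lncRNA, "lncRNA"), look(tr$miRNA, "miRNA"),
                look(tr$mRNA, "mRNA")), expect)
  }, logical(1))
  all(ok)
}

#' @export
print.cerna_sim <- function(x, ...) {
  cat("<cerna_sim>\n")
  for (cls in names(x$counts)) {
    cat(sprintf("  %s: %d genes x %d samples\n", cls, nrow(x$counts[[cls]]),
                ncol(x$counts[[cls]]) - 1))
  }
  cat(sprintf("  planted triples: %d\n", nrow(x$truth$triples)))
  invisible(x)
}
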