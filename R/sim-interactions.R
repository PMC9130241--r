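#' Simulate regulator-target interaction tables
#'
#' Produces one lncRNA-miRNA interaction table and `n_sources`
#' miRNA-mRNA tables. Every planted lncRNA-miRNA pair appears in the
#' single lncRNA-miRNA table and every planted miRNA-mRNA pair appears in
#' all miRNA-mRNA sources. Decoy pairs are added independently per source
#' with probability `decoy_pair_rate` per possible non-planted pair.
#' Unless `allow_confusable` is set, decoys never connect two planted
#' differentially expressed molecules, so decoys cannot complete a
#' direction-consistent triple among planted genes.
#'
#' @param truth Planted truth from [simulate_counts()].
#' @param config The same [sim_config()].
#' @return List with `lnc_mir` (tibble `regulator`, `target`, `source`) and
#'   `mir_mrna` (list of such tibbles, one per source).
#' @export
simulate_interactions <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "cerna_truth"))
  withr::with_seed(config$seed + 1L, {
    planted_de <- truth$de_genes$gene
    decoys_for <- function(regs, tgts, planted_pairs) {
      grid <- expand.grid(regulator = regs, target = tgts,
                          stringsAsFactors = FALSE)
      key <- paste(grid$regulator, grid$target)
      pk <- paste(planted_pairs$regulator, planted_pairs$target)
      keep <- runif(nrow(grid)) < config$decoy_pair_rate & !(key %in% pk)
      if (!config$allow_confusable) {
        keep <- keep & !(grid$regulator %in% planted_de &
                           grid$target %in% planted_de)
      }
      as_tibble(grid[keep, , drop = FALSE])
    }

    planted_lm <- distinct(tibble(regulator = truth$triples$lncRNA,
                                  target = truth$triples$miRNA))
    lnc_mir <- bind_rows(planted_lm,
                         decoys_for(truth$genes$lncRNA, truth$genes$miRNA,
                                    planted_lm)) %>%
      mutate(source = "lnc_mir_db")

    planted_mm <- distinct(tibble(regulator = truth$triples$miRNA,
                                  target = truth$triples$mRNA))
    mir_mrna <- lapply(seq_len(config$n_sources), function(s) {
      bind_rows(planted_mm,
                decoys_for(truth$genes$miRNA, truth$genes$mRNA, planted_mm)) %>%
        mutate(source = sprintf("source%d", s))
    })
    list(lnc_mir = lnc_mir, mir_mrna = mir_mrna)
  })
}

#' Simulate a gene-set collection with one set enriched for planted mRNAs
#'
#' Builds `n_genesets` sets over the mRNA universe. The set named by
#' `truth$enriched_set` receives at least 80% (by construction, 90%) of the
#' planted triple mRNAs plus random fillers; every other set is a plain
#' random sample of the universe.
#'
#' @inheritParams simulate_interactions
#' @return A [geneset_collection()] over the mRNA universe.
#' @export
simulate_genesets <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "cerna_truth"))
  withr::with_seed(config$seed + 2L, {
    universe <- truth$genes$mRNA
    nm <- sprintf("GS%03d", seq_len(config$n_genesets))
    sizes <- sample(seq(config$geneset_size_range[1],
                        config$geneset_size_range[2]),
                    config$n_genesets, replace = TRUE)
    sets <- lapply(sizes, function(k) sample(universe, k))
    names(sets) <- nm
    planted <- unique(truth$triples$mRNA)
    if (length(planted)) {
      keep <- sample(planted, ceiling(0.9 * length(planted)))
      target_size <- max(sizes[nm == truth$enriched_set], length(keep) + 5)
      fillers <- sample(setdiff(universe, keep), target_size - length(keep))
      sets[[truth$enriched_set]] <- sample(c(keep, fillers))
    }
    geneset_collection(sets, universe)
  })
}

#' Simulate an expression cohort with expression-dependent survival
#'
#' Generates a log-normal expression matrix for all mRNA genes across
#' `n_survival_samples` cohort samples and a clinical table with
#' exponential event times. A latent risk group (half the cohort) has its
#' event rate multiplied by `hazard_ratio`; each planted survival gene's
#' expression is shifted up (high-expression-risky) or down
#' (low-expression-risky) in the risky half strongly enough that a median
#' split of that gene recovers the risk group. Censoring is independent:
#' with probability `censor_rate` a record is censored at a uniform
#' fraction of its event time.
#'
#' @inheritParams simulate_interactions
#' @param base_rate Baseline exponential event rate per day
#'   (default: median survival of 1500 days).
#' @return List with `expression` (tibble `gene_id` + cohort sample columns)
#'   and `clinical` (tibble `sample`, `time_days`, `event`).
#' @export
simulate_survival <- function(truth, config, base_rate = log(2) / 1500) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "cerna_truth"))
  if (config$n_survival_samples < 10) {
    abort("`n_survival_samples` must be at least 10.")
  }
  withr::with_seed(config$seed + 3L, {
    n <- config$n_survival_samples
    ids <- truth$genes$mRNA
    smp <- sprintf("S%03d", seq_len(n))
    risky <- sample(rep_len(c(TRUE, FALSE), n))
    meanlog <- runif(length(ids), 2, 6)
    expr <- matrix(rlnorm(length(ids) * n, meanlog = rep(meanlog, n),
                          sdlog = 0.5),
                   nrow = length(ids), dimnames = list(ids, smp))
    sg <- truth$survival_genes
    for (i in seq_len(nrow(sg))) {
      g <- sg$gene[i]
      shift <- if (sg$risk_direction[i] == "high") 1.5 else -1.5
      expr[g, ] <- exp(meanlog[match(g, ids)] + ifelse(risky, shift, 0) +
                         rnorm(n, sd = 0.5))
    }
    rate <- base_rate * ifelse(risky, config$hazard_ratio, 1)
    t_event <- rexp(n, rate = rate)
    censored <- runif(n) < config$censor_rate
    time <- ifelse(censored, t_event * runif(n), t_event)
    clinical <- tibble(sample = smp,
                       time_days = pmax(time, 1e-6),
                       event = as.integer(!censored))
    list(expression = matrix_to_counts(expr), clinical = clinical)
  })
}
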