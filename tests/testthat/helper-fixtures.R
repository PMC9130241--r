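# Shared fixtures: small study configurations and a compact analysis
# driver used by several test files.

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_lnc = 30, n_mir = 20, n_mrna = 120, n_triples = 5,
         n_genesets = 10, n_survival_genes = 2, decoy_pair_rate = 0.05,
         seed = 101L),
    list(...))
  do.call(sim_config, args)
}

# counts tibble from a plain matrix
as_counts <- function(mat) {
  tibble::tibble(gene_id = rownames(mat)) |>
    dplyr::bind_cols(tibble::as_tibble(mat))
}

random_counts <- function(n_genes, n_samples, mu = 50, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnbinom(n_genes * n_samples, mu = mu, size = 5),
                nrow = n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%d", seq_len(n_samples))))
    as_counts(m)
  })
}

two_group_sheet <- function(n_per_group) {
  tibble::tibble(
    sample = c(sprintf("T%d", seq_len(n_per_group)),
               sprintf("N%d", seq_len(n_per_group))),
    condition = rep(c("tumour", "normal"), each = n_per_group))
}

# Run DE -> consensus -> filtering -> triples -> trend split for a
# simulated study; returns the trend partition plus planted recovery.
recover_planted <- function(study) {
  de <- lapply(study$counts, de_analysis, samples = study$samples)
  dg <- lapply(de, degs)
  cons <- consensus_targets(study$interactions$mir_mrna)
  pairs <- filter_pairs_to_de(study$interactions$lnc_mir, cons,
                              dg$lncRNA, dg$miRNA, dg$mRNA)
  triples <- assemble_triples(pairs$lnc_mir, pairs$mir_mrna)
  parts <- split_by_direction(triples)
  tr <- study$truth$triples
  key <- paste(tr$lncRNA, tr$miRNA, tr$mRNA)
  in_part <- function(p) key %in% paste(p$lncRNA, p$miRNA, p$mRNA)
  list(parts = parts, degs = dg,
       recovered = ifelse(tr$trend == "HLH", in_part(parts$HLH),
                          in_part(parts$LHL)),
       wrong = ifelse(tr$trend == "HLH", in_part(parts$LHL),
                      in_part(parts$HLH)))
}
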