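#' Simulate a complete synthetic ceRNA study
#'
#' Convenience wrapper running [simulate_counts()],
#' [simulate_interactions()], [simulate_genesets()] and
#' [simulate_survival()] from one configuration.
#'
#' @param config A [sim_config()].
#' @return A list of class `cerna_study` with elements `config`, `counts`,
#'   `samples`, `truth`, `interactions`, `genesets`, `survival`.
#' @export
#' @examples
#' study <- simulate_cerna_study(sim_config(n_lnc = 30, n_mir = 20,
#'   n_mrna = 120, n_triples = 4, n_survival_genes = 2, n_genesets = 10))
#' names(study)
simulate_cerna_study <- function(config = sim_config()) {
  sim <- simulate_counts(config)
  structure(list(
    config = config,
    counts = sim$counts,
    samples = sim$samples,
    truth = sim$truth,
    interactions = simulate_interactions(sim$truth, config),
    genesets = simulate_genesets(sim$truth, config),
    survival = simulate_survival(sim$truth, config)
  ), class = "cerna_study")
}

#' Write a simulated study to plain-text files
#'
#' Writes counts TSVs per class, the sample sheet, interaction TSVs
#' (columns `regulator`, `target`, `source`), the gene-set collection as
#' GMT, the clinical table, the cohort expression matrix, and the planted
#' truth as JSON.
#'
#' @param study Result of [simulate_cerna_study()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of written paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "cerna_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  paths <- c(
    lncRNA_counts = p("lncRNA_counts.tsv"),
    miRNA_counts = p("miRNA_counts.tsv"),
    mRNA_counts = p("mRNA_counts.tsv"),
    sample_sheet = p("sample_sheet.tsv"),
    lnc_mir = p("interactions_lnc_mir.tsv"),
    genesets = p("genesets.gmt"),
    clinical = p("clinical.tsv"),
    cohort_expression = p("cohort_expression.tsv"),
    truth = p("truth.json")
  )
  readr::write_tsv(study$counts$lncRNA, paths[["lncRNA_counts"]])
  readr::write_tsv(study$counts$miRNA, paths[["miRNA_counts"]])
  readr::write_tsv(study$counts$mRNA, paths[["mRNA_counts"]])
  readr::write_tsv(study$samples, paths[["sample_sheet"]])
  readr::write_tsv(study$interactions$lnc_mir, paths[["lnc_mir"]])
  for (i in seq_along(study$interactions$mir_mrna)) {
    f <- p(sprintf("interactions_mir_mrna_source%d.tsv", i))
    readr::write_tsv(study$interactions$mir_mrna[[i]], f)
    paths[sprintf("mir_mrna_source%d", i)] <- f
  }
  write_gmt(study$genesets, paths[["genesets"]])
  readr::write_tsv(study$survival$clinical, paths[["clinical"]])
  readr::write_tsv(study$survival$expression, paths[["cohort_expression"]])
  truth <- study$truth
  jsonlite::write_json(
    list(de_genes = truth$de_genes, triples = truth$triples,
         enriched_set = truth$enriched_set,
         survival_genes = truth$survival_genes),
    paths[["truth"]], dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @export
print.cerna_study <- function(x, ...) {
  cat("<cerna_study>\n")
  cat(sprintf("  %d lncRNA / %d miRNA / %d mRNA genes; %d planted triples\n",
              nrow(x$counts$lncRNA), nrow(x$counts$miRNA),
              nrow(x$counts$mRNA), nrow(x$truth$triples)))
  cat(sprintf("  %d-sample survival cohort; %d gene sets\n",
              nrow(x$survival$clinical), length(x$genesets$sets)))
  invisible(x)
}
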