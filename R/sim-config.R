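#' Configuration for the synthetic ceRNA study generator
#'
#' Bundles every knob of the synthetic-data generator into one validated
#' object. The defaults emulate a paired 3-tumour / 3-normal whole
#' transcriptome design with 20 planted, direction-coupled ceRNA triples,
#' decoy regulator-target interactions, one enriched gene set, and an
#' 85-patient survival cohort whose hazard depends on the expression of a
#' handful of planted mRNAs.
#'
#' @param n_lnc,n_mir,n_mrna Number of genes simulated per RNA class.
#' @param n_pairs Number of tumour/normal sample pairs (patients).
#' @param n_triples Number of planted ceRNA triples. Each triple uses a
#'   distinct lncRNA, miRNA and mRNA and is assigned an HLH
#'   (lnc up, mir down, mRNA up) or LHL (lnc down, mir up, mRNA down) trend.
#' @param effect_log2fc Absolute log2 fold change planted on every member of
#'   every triple (tumour relative to normal).
#' @param dispersion Negative-binomial dispersion phi >= 0
#'   (variance = mu + phi * mu^2); 0 gives Poisson counts.
#' @param lib_size_range Length-2 numeric, min/max library size per sample.
#' @param decoy_pair_rate Probability that any non-planted regulator-target
#'   pair is included as a decoy, independently per interaction source.
#' @param n_sources Number of miRNA-mRNA interaction sources.
#' @param n_genesets Number of gene sets in the simulated collection.
#' @param geneset_size_range Length-2 integer, min/max gene-set size.
#' @param n_survival_samples Cohort size for the clinical table.
#' @param n_survival_genes Number of planted triple mRNAs given an
#'   expression-linked hazard in the survival cohort.
#' @param hazard_ratio Event-rate multiplier for the risky half of the
#'   cohort; must be > 0. 1 means no survival signal.
#' @param censor_rate Fraction of cohort records censored, in [0, 1).
#' @param baseline_log10_range Log10 range of relative baseline abundances
#'   for non-planted genes (log-uniform draw).
#' @param planted_log10_range Log10 range for planted triple members; kept in
#'   the upper decades so that network actors are appreciably expressed.
#' @param allow_confusable If `FALSE` (default), decoy pairs never connect
#'   two planted differentially expressed molecules, so no decoy can
#'   complete a direction-consistent triple and recovery metrics stay
#'   interpretable.
#' @param seed Integer RNG seed; all `simulate_*()` functions derive their
#'   streams from it.
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_lnc = 30, n_mir = 20, n_mrna = 100, n_triples = 5)
#' cfg$n_triples
sim_config <- function(n_lnc = 300, n_mir = 150, n_mrna = 1500,
                       n_pairs = 3, n_triples = 20,
                       effect_log2fc = 3, dispersion = 0.1,
                       lib_size_range = c(1e5, 5e5),
                       decoy_pair_rate = 0.02, n_sources = 3,
                       n_genesets = 50, geneset_size_range = c(10, 40),
                       n_survival_samples = 85, n_survival_genes = 5,
                       hazard_ratio = 3, censor_rate = 0.3,
                       baseline_log10_range = c(-4, 0),
                       planted_log10_range = c(-2, 0),
                       allow_confusable = FALSE, seed = 1L) {
  cfg <- list(
    n_lnc = n_lnc, n_mir = n_mir, n_mrna = n_mrna, n_pairs = n_pairs,
    n_triples = n_triples, effect_log2fc = effect_log2fc,
    dispersion = dispersion, lib_size_range = lib_size_range,
    decoy_pair_rate = decoy_pair_rate, n_sources = n_sources,
    n_genesets = n_genesets, geneset_size_range = geneset_size_range,
    n_survival_samples = n_survival_samples,
    n_survival_genes = n_survival_genes, hazard_ratio = hazard_ratio,
    censor_rate = censor_rate,
    baseline_log10_range = baseline_log10_range,
    planted_log10_range = planted_log10_range,
    allow_confusable = isTRUE(allow_confusable),
    seed = as.integer(seed)
  )
  problems <- character()
  for (f in c("n_lnc", "n_mir", "n_mrna", "n_pairs", "n_sources",
              "n_genesets", "n_survival_samples")) {
    if (!is_count1(cfg[[f]])) problems <- c(problems, sprintf("`%s` must be a positive integer", f))
  }
  for (f in c("n_triples", "n_survival_genes")) {
    if (!(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 && cfg[[f]] >= 0 && cfg[[f]] == round(cfg[[f]]))) {
      problems <- c(problems, sprintf("`%s` must be a non-negative integer", f))
    }
  }
  if (!is.numeric(effect_log2fc) || effect_log2fc < 0) {
    problems <- c(problems, "`effect_log2fc` must be >= 0")
  }
  if (!is.numeric(dispersion) || dispersion < 0) {
    problems <- c(problems, "`dispersion` must be >= 0")
  }
  if (length(lib_size_range) != 2 || any(lib_size_range <= 0) ||
      lib_size_range[1] > lib_size_range[2]) {
    problems <- c(problems, "`lib_size_range` must be an increasing positive pair")
  }
  if (!is.numeric(decoy_pair_rate) || decoy_pair_rate < 0 || decoy_pair_rate > 1) {
    problems <- c(problems, "`decoy_pair_rate` must lie in [0, 1]")
  }
  if (!is.numeric(censor_rate) || censor_rate < 0 || censor_rate >= 1) {
    problems <- c(problems, "`censor_rate` must lie in [0, 1)")
  }
  if (!is.numeric(hazard_ratio) || hazard_ratio <= 0) {
    problems <- c(problems, "`hazard_ratio` must be > 0")
  }
  if (is_count1(cfg$n_lnc) && is_count1(cfg$n_mir) && is_count1(cfg$n_mrna) &&
      is.numeric(cfg$n_triples) &&
      cfg$n_triples > min(n_lnc, n_mir, n_mrna)) {
    problems <- c(problems, "`n_triples` cannot exceed min(n_lnc, n_mir, n_mrna)")
  }
  if (is.numeric(cfg$n_survival_genes) && is.numeric(cfg$n_triples) &&
      cfg$n_survival_genes > cfg$n_triples) {
    problems <- c(problems, "`n_survival_genes` cannot exceed `n_triples`")
  }
  if (length(problems)) {
    abort(c("Invalid simulation configuration:", problems))
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genes: %d lncRNA, %d miRNA, %d mRNA; %d tumour/normal pairs\n",
              x$n_lnc, x$n_mir, x$n_mrna, x$n_pairs))
  cat(sprintf("  planted: %d triples at |log2FC| = %g, NB dispersion %g\n",
              x$n_triples, x$effect_log2fc, x$dispersion))
  cat(sprintf("  cohort: %d samples, hazard ratio %g, censor rate %g; seed %d\n",
              x$n_survival_samples, x$hazard_ratio, x$censor_rate, x$seed))
  invisible(x)
}
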