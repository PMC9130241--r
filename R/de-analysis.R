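#' Run the full differential-expression screen for one RNA class
#'
#' TMM normalization, common-dispersion estimation (unless supplied),
#' negative-binomial exact test, BH adjustment, and DEG calling with the
#' fold change > `fc_threshold` and FDR < `fdr_threshold` rule.
#'
#' @param counts Counts tibble (gene_id + sample columns).
#' @param samples Sample sheet (`sample`, `condition`).
#' @param dispersion Optional NB dispersion; estimated from the data when
#'   `NULL` (requires >= 2 samples per condition).
#' @param fc_threshold,fdr_threshold DEG thresholds (strict inequalities).
#' @param prior_count Prior count for fold-change shrinkage.
#' @return An object of class `cerna_de` with `results` (gene, log2fc,
#'   pvalue, fdr, direction), `factors`, `dispersion` and `thresholds`.
#'   Use [tidy()] for the per-gene table, [glance()] for a one-row
#'   summary, [autoplot()] for a volcano plot and [degs()] for the DEG
#'   subset.
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_lnc = 20, n_mir = 10, n_mrna = 60,
#'                                   n_triples = 3, n_survival_genes = 0))
#' de <- de_analysis(sim$counts$mRNA, sim$samples)
#' glance(de)
de_analysis <- function(counts, samples, dispersion = NULL,
                        fc_threshold = 2, fdr_threshold = 0.05,
                        prior_count = 0.5) {
  factors <- tmm_norm_factors(counts)
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(counts, samples, factors)
  }
  res <- exact_test(counts, samples, factors, dispersion, prior_count)
  res$fdr <- bh_adjust(res$pvalue)
  res <- call_degs(res, fc_threshold, fdr_threshold)
  structure(list(results = res, factors = factors, dispersion = dispersion,
                 thresholds = c(fc = fc_threshold, fdr = fdr_threshold)),
            class = "cerna_de")
}

#' Extract the DEG subset of a differential-expression screen
#'
#' @param x A `cerna_de` object or an annotated results tibble.
#' @return Tibble of genes with direction `up` or `down`.
#' @export
degs <- function(x) {
  res <- if (inherits(x, "cerna_de")) x$results else as_tibble(x)
  filter(res, .data$direction != "ns")
}

#' @export
print.cerna_de <- function(x, ...) {
  d <- degs(x)
  cat(sprintf("<cerna_de> %d genes tested, dispersion %.4g\n",
              nrow(x$results), x$dispersion))
  cat(sprintf("  %d DEGs (%d up, %d down) at |FC| > %g, FDR < %g\n",
              nrow(d), sum(d$direction == "up"), sum(d$direction == "down"),
              x$thresholds["fc"], x$thresholds["fdr"]))
  invisible(x)
}

#' @rdname de_analysis
#' @param x A `cerna_de` object.
#' @param ... Unused.
#' @export
tidy.cerna_de <- function(x, ...) x$results

#' @rdname de_analysis
#' @export
glance.cerna_de <- function(x, ...) {
  d <- degs(x)
  tibble(n_genes = nrow(x$results), n_deg = nrow(d),
         n_up = sum(d$direction == "up"),
         n_down = sum(d$direction == "down"),
         dispersion = x$dispersion)
}

#' @rdname de_analysis
#' @param object A `cerna_de` object.
#' @export
autoplot.cerna_de <- function(object, ...) {
  dat <- de_volcano_coords(object$results)
  dat$direction <- object$results$direction
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log2fc, y = .data$neg_log10_fdr,
                                    colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(up = "#d73027", down = "#4575b4",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change (tumour / normal)",
                  y = expression(-log[10] ~ FDR), colour = NULL) +
    ggplot2::theme_minimal()
}
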