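#' Aggregate transcript-level counts to gene level
#'
#' Sums counts of transcripts sharing a gene name, per sample. Transcripts
#' absent from the mapping are dropped and their number reported.
#'
#' @param counts Counts tibble keyed by transcript (first column = IDs).
#' @param mapping Data frame with columns `transcript`, `gene`. A
#'   transcript mapping to more than one gene is an error.
#' @return Counts tibble keyed by gene.
#' @export
aggregate_by_gene <- function(counts, mapping) {
  check_counts(counts)
  if (!is.data.frame(mapping) || !all(c("transcript", "gene") %in% names(mapping))) {
    abort("`mapping` must have columns `transcript` and `gene`.")
  }
  mapping <- distinct(as_tibble(mapping[, c("transcript", "gene")]))
  if (nrow(mapping) == 0) abort("`mapping` is empty.")
  dup <- mapping$transcript[duplicated(mapping$transcript)]
  if (length(dup)) {
    abort(sprintf("Transcripts mapped to multiple genes: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  tx <- counts[[1]]
  hit <- match(tx, mapping$transcript)
  n_unmapped <- sum(is.na(hit))
  if (n_unmapped > 0) {
    inform(sprintf("Dropping %d unmapped transcript(s).", n_unmapped))
  }
  keep <- !is.na(hit)
  mat <- counts_matrix(counts)[keep, , drop = FALSE]
  agg <- rowsum(mat, group = mapping$gene[hit[keep]])
  matrix_to_counts(agg[order(rownames(agg)), , drop = FALSE])
}

# edgeR-recipe TMM factor of one library against the reference library.
tmm_factor_one <- function(obs, ref, lib_obs, lib_ref,
                           logratio_trim = 0.3, sum_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) {
    warn("No genes expressed in both libraries; TMM factor set to 1.")
    return(1)
  }
  obs <- obs[keep]; ref <- ref[keep]
  logR <- log2((obs / lib_obs) / (ref / lib_ref))
  absE <- (log2(obs / lib_obs) + log2(ref / lib_ref)) / 2
  v <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1
  hiS <- n + 1 - loS
  keep2 <- rank(logR) >= loL & rank(logR) <= hiL &
    rank(absE) >= loS & rank(absE) <= hiS
  if (!any(keep2)) {
    warn("No genes retained after trimming; TMM factor set to 1.")
    return(1)
  }
  f <- sum(logR[keep2] / v[keep2]) / sum(1 / v[keep2])
  if (!is.finite(f)) {
    warn("Non-finite trimmed mean; TMM factor set to 1.")
    return(1)
  }
  2^f
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: for each sample versus a reference sample,
#' genes with a zero in either library are excluded, M-values
#' `log2((y_gk/N_k)/(y_gr/N_r))` and average abundances
#' `A = (log2(y_gk/N_k) + log2(y_gr/N_r))/2` are computed, the top and
#' bottom 30% by M and 5% by A are trimmed, and the factor is two to the
#' precision-weighted mean of the remaining M-values (weights from
#' binomial delta-method variances). Factors are rescaled so their
#' geometric mean is 1. The reference defaults to the sample whose
#' 75th-percentile CPM is closest to the mean of those percentiles.
#'
#' @param counts Counts tibble (gene_id + sample columns).
#' @param ref_sample Optional reference sample name.
#' @return Tibble with `sample`, `lib_size`, `norm_factor`.
#' @export
#' @examples
#' cts <- tibble::tibble(gene_id = paste0("g", 1:4),
#'                       a = c(10, 20, 30, 40), b = c(100, 200, 300, 400))
#' tmm_norm_factors(cts)
tmm_norm_factors <- function(counts, ref_sample = NULL) {
  check_counts(counts)
  y <- counts_matrix(counts)
  if (ncol(y) < 2) abort("TMM needs at least two samples.")
  lib <- colSums(y)
  if (any(lib == 0)) {
    abort(sprintf("All-zero sample(s): %s",
                  paste(colnames(y)[lib == 0], collapse = ", ")))
  }
  if (is.null(ref_sample)) {
    q75 <- vapply(seq_len(ncol(y)), function(k) {
      quantile(y[, k] / lib[k], 0.75, names = FALSE)
    }, numeric(1))
    ref_sample <- colnames(y)[which.min(abs(q75 - mean(q75)))]
  }
  if (!ref_sample %in% colnames(y)) {
    abort(sprintf("Reference sample '%s' not found.", ref_sample))
  }
  r <- match(ref_sample, colnames(y))
  f <- vapply(seq_len(ncol(y)), function(k) {
    if (k == r) return(1)
    tmm_factor_one(y[, k], y[, r], lib[k], lib[r])
  }, numeric(1))
  f <- f / geometric_mean(f)
  tibble(sample = colnames(y), lib_size = unname(lib), norm_factor = f)
}

# Round counts to the pseudo-scale of a common effective library size.
pseudo_counts <- function(y, factors) {
  eff <- factors$lib_size * factors$norm_factor
  eff <- eff[match(colnames(y), factors$sample)]
  common <- geometric_mean(eff)
  list(pseudo = round(sweep(y, 2, common / eff, "*")), eff = eff,
       common = common)
}

golden_section_max <- function(f, lower, upper, tol = 1e-10, max_iter = 200) {
  gr <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  for (i in seq_len(max_iter)) {
    if (abs(b - a) < tol) break
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  (a + b) / 2
}

#' Estimate a common negative-binomial dispersion
#'
#' Maximizes the summed per-gene conditional NB log-likelihood given each
#' gene's group totals, on counts rescaled to a common effective library
#' size (which makes the conditional distribution free of the gene mean).
#' Maximization is by golden-section search on the log scale over
#' `interval`.
#'
#' @param counts Counts tibble.
#' @param samples Sample sheet with `sample`, `condition`.
#' @param factors Optional [tmm_norm_factors()] result (computed if NULL).
#' @param interval Search interval for the dispersion.
#' @return The dispersion estimate (scalar, >= `interval[1]`).
#' @export
estimate_common_dispersion <- function(counts, samples, factors = NULL,
                                       interval = c(1e-6, 10)) {
  check_counts(counts)
  check_samples(samples, colnames(counts)[-1])
  grp <- split(samples$sample, samples$condition)
  if (any(lengths(grp) < 2)) {
    abort("Each condition needs >= 2 samples to estimate a common dispersion; supply one instead.")
  }
  y <- counts_matrix(counts)
  if (all(y == 0)) abort("Count matrix is all zero.")
  if (is.null(factors)) factors <- tmm_norm_factors(counts)
  ps <- pseudo_counts(y, factors)$pseudo
  groups <- lapply(grp, function(s) ps[, s, drop = FALSE])
  # conditional log-likelihood given gene totals, equal library sizes
  ll <- function(log_phi) {
    r <- 1 / exp(log_phi)
    tot <- 0
    for (g in groups) {
      ng <- ncol(g)
      z <- rowSums(g)
      tot <- tot + sum(lgamma(g + r)) - length(z) * ng * lgamma(r) +
        length(z) * lgamma(ng * r) - sum(lgamma(z + ng * r))
    }
    tot
  }
  u <- golden_section_max(ll, log(interval[1]), log(interval[2]))
  phi <- exp(u)
  if (phi < interval[1] * 1.01) phi <- interval[1]
  phi
}

# Two-sided conditional exact p-values for group-sum splits of gene totals.
# Conditioned on z = zA + zB the group sum follows the convolution of the
# per-sample NB distributions; the p-value sums the probabilities of every
# partition at most as probable as the observed one.
cond_exact_p <- function(zA, zB, nA, nB, phi, block_limit = 4e6) {
  z <- zA + zB
  p <- rep(1, length(z))
  pos <- which(z > 0)
  if (!length(pos)) return(p)
  lens <- z[pos] + 1
  blocks <- split(pos, ceiling(cumsum(lens) / block_limit))
  for (blk in blocks) {
    idx <- rep(seq_along(blk), z[blk] + 1)
    a <- sequence(z[blk] + 1) - 1
    zg <- z[blk][idx]
    if (phi == 0) {
      lp <- stats::dbinom(a, size = zg, prob = nA / (nA + nB), log = TRUE)
    } else {
      r <- 1 / phi
      mu <- zg / (nA + nB)
      lp <- stats::dnbinom(a, size = nA * r, mu = nA * mu, log = TRUE) +
        stats::dnbinom(zg - a, size = nB * r, mu = nB * mu, log = TRUE)
    }
    lp_split <- split(lp, idx)
    a_split <- split(a, idx)
    p[blk] <- vapply(seq_along(blk), function(i) {
      lpi <- lp_split[[i]]
      w <- exp(lpi - max(lpi))
      lobs <- lpi[a_split[[i]] == zA[blk[i]]]
      sum(w[lpi <= lobs + 1e-8]) / sum(w)
    }, numeric(1))
  }
  pmin(p, 1)
}

#' Negative-binomial exact test for two-group differential expression
#'
#' Counts are equalized to a common effective library size (geometric mean
#' of the TMM-effective sizes, rounded to integers); conditioned on each
#' gene's total, the two group sums follow NB convolutions and the
#' two-sided p-value is the summed probability of all partitions at most
#' as probable as the observed one. The log2 fold change is computed from
#' TMM-normalized CPM group means with a prior count added to each mean.
#'
#' @param counts Counts tibble.
#' @param samples Sample sheet (`sample`, `condition` in tumour/normal).
#' @param factors [tmm_norm_factors()] result (computed if NULL).
#' @param dispersion NB dispersion phi >= 0.
#' @param prior_count Prior added to each group's mean CPM (default 0.5).
#' @return Tibble with `gene`, `log2fc` (tumour over normal), `pvalue`.
#' @export
exact_test <- function(counts, samples, factors = NULL, dispersion,
                       prior_count = 0.5) {
  check_counts(counts)
  check_samples(samples, colnames(counts)[-1])
  if (!is.numeric(dispersion) || length(dispersion) != 1 || dispersion < 0) {
    abort("`dispersion` must be a single value >= 0.")
  }
  y <- counts_matrix(counts)
  y <- y[, samples$sample, drop = FALSE]
  if (is.null(factors)) factors <- tmm_norm_factors(counts)
  ps <- pseudo_counts(y, factors)
  tum <- samples$sample[samples$condition == "tumour"]
  nor <- samples$sample[samples$condition == "normal"]
  if (!length(tum) || !length(nor)) abort("Both conditions must be present.")
  zT <- rowSums(ps$pseudo[, tum, drop = FALSE])
  zN <- rowSums(ps$pseudo[, nor, drop = FALSE])
  pval <- cond_exact_p(zT, zN, length(tum), length(nor), dispersion)
  cpm <- sweep(y, 2, ps$eff / 1e6, "/")
  mT <- rowMeans(cpm[, tum, drop = FALSE])
  mN <- rowMeans(cpm[, nor, drop = FALSE])
  lfc <- log2((mT + prior_count) / (mN + prior_count))
  zero <- rowSums(y) == 0
  lfc[zero] <- 0
  pval[zero] <- 1
  tibble(gene = rownames(y), log2fc = unname(lfc), pvalue = unname(pval))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `fdr_i = min_{j >= rank(i)} m * p_(j) / j`,
#' clipped at 1, input order preserved.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Vector of adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1)) {
    abort("`pvalues` must be numeric in [0, 1] with no missing values.")
  }
  p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed genes
#'
#' A gene is a DEG iff `|log2fc| > log2(fc_threshold)` and
#' `fdr < fdr_threshold` (both strict); direction is `up` for positive
#' fold change, `down` for negative, `ns` otherwise.
#'
#' @param results Tibble with `gene`, `log2fc`, `fdr` (see [bh_adjust()]).
#' @param fc_threshold Fold-change threshold on the natural scale
#'   (default 2).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @return `results` with a `direction` column in `up`/`down`/`ns`.
#' @export
call_degs <- function(results, fc_threshold = 2, fdr_threshold = 0.05) {
  if (!all(c("gene", "log2fc", "fdr") %in% names(results))) {
    abort("`results` must have columns gene, log2fc and fdr.")
  }
  mutate(as_tibble(results), direction = case_when(
    abs(.data$log2fc) > log2(fc_threshold) & .data$fdr < fdr_threshold &
      .data$log2fc > 0 ~ "up",
    abs(.data$log2fc) > log2(fc_threshold) & .data$fdr < fdr_threshold ~ "down",
    TRUE ~ "ns"
  ))
}

#' Heatmap transform for normalized expression
#'
#' `log10(value + 0.001)`, the transform used for expression heatmap
#' export; errors on negative input.
#'
#' @param value Non-negative normalized expression value(s).
#' @return Transformed value(s).
#' @export
#' @examples
#' normalized_log_transform(c(0, 0.999, 99.999))
normalized_log_transform <- function(value) {
  if (any(value < 0)) abort("Normalized expression must be >= 0.")
  log10(value + 0.001)
}

#' TMM-normalized counts per million
#'
#' @param counts Counts tibble.
#' @param factors [tmm_norm_factors()] result (computed if NULL).
#' @return Tibble (`gene_id` + sample columns) of CPM on the effective
#'   library sizes.
#' @export
cpm_normalized <- function(counts, factors = NULL) {
  check_counts(counts)
  y <- counts_matrix(counts)
  if (is.null(factors)) factors <- tmm_norm_factors(counts)
  eff <- factors$lib_size * factors$norm_factor
  eff <- eff[match(colnames(y), factors$sample)]
  matrix_to_counts(sweep(y, 2, eff / 1e6, "/"))
}

#' Heatmap matrix on the log10(normalized + 0.001) scale
#'
#' @inheritParams cpm_normalized
#' @return Tibble of transformed CPM values.
#' @export
de_heatmap_matrix <- function(counts, factors = NULL) {
  cpm <- cpm_normalized(counts, factors)
  mutate(cpm, across(-1, normalized_log_transform))
}

#' Volcano-plot coordinates
#'
#' @param results DE results with `gene`, `log2fc`, `fdr`.
#' @return Tibble with `gene`, `log2fc` (abscissa) and `neg_log10_fdr`
#'   (ordinate).
#' @export
de_volcano_coords <- function(results) {
  if (!all(c("gene", "log2fc", "fdr") %in% names(results))) {
    abort("`results` must have columns gene, log2fc and fdr.")
  }
  tibble(gene = results$gene, log2fc = results$log2fc,
         neg_log10_fdr = -log10(results$fdr))
}
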