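#' Dichotomize an expression vector into high/low groups
#'
#' Median split by default: samples strictly above the cut point are
#' `high`, samples at or below it are `low` (ties go to the low group).
#' A quantile rule is available via `rule = "quantile"`.
#'
#' @param expression Numeric vector (>= 4 values, non-constant).
#' @param rule `"median"` or `"quantile"`.
#' @param q Quantile for `rule = "quantile"` (default 0.5).
#' @return Character vector of `"high"`/`"low"` labels.
#' @export
#' @examples
#' dichotomize(1:10)
dichotomize <- function(expression, rule = c("median", "quantile"), q = 0.5) {
  rule <- match.arg(rule)
  if (length(expression) < 4) abort("Need at least 4 samples to dichotomize.")
  if (max(expression) == min(expression)) {
    abort("Cannot dichotomize a constant expression vector.")
  }
  cut <- if (rule == "median") median(expression) else quantile(expression, q, names = FALSE)
  labels <- ifelse(expression > cut, "high", "low")
  if (length(unique(labels)) < 2) {
    abort("Dichotomization produced an empty group.")
  }
  labels
}

#' Kaplan-Meier product-limit survival estimate
#'
#' `S(t_i) = prod_{j <= i} (1 - d_j / n_j)` over distinct times;
#' censored-only times reduce the risk set but add no step.
#'
#' @param times Positive follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return A tibble of class `cerna_km` with `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`.
#' @export
#' @examples
#' km_estimator(c(1, 2, 3), c(1, 0, 1))
km_estimator <- function(times, events) {
  if (!length(times)) abort("Need at least one record.")
  if (any(times <= 0)) abort("Follow-up times must be positive.")
  if (!all(events %in% c(0, 1))) abort("Events must be 0 or 1.")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                n_censor = fit$n.censor, survival = fit$surv)
  class(out) <- c("cerna_km", class(out))
  out
}

#' Two-group log-rank test
#'
#' The 1-df log-rank chi-square
#' `(sum_i (O_1i - E_1i))^2 / sum_i V_i` over distinct event times, with
#' `E_1i = d_i n_1i / n_i` and the hypergeometric variance
#' `V_i = d_i (n_1i/n_i)(1 - n_1i/n_i)(n_i - d_i)/(n_i - 1)`. The risky
#' group is the one with more observed than expected events. With no
#' events at all, the statistic is 0 and p = 1 (with a warning).
#'
#' @param groups Two-level group labels (e.g. `"high"`/`"low"`).
#' @param times Positive follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return List with `chi_square`, `pvalue`, `risky_group`, `n` per group.
#' @export
logrank_test <- function(groups, times, events) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2 || any(table(groups) == 0)) {
    abort("Exactly two non-empty groups required.")
  }
  if (any(times <= 0)) abort("Follow-up times must be positive.")
  n_by <- table(groups)
  if (sum(events) == 0) {
    warn("No events in either group; log-rank statistic is 0.")
    return(list(chi_square = 0, pvalue = 1, risky_group = NA_character_,
                n = as.list(n_by)))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  chi <- unname(sd$chisq)
  oe <- sd$obs - sd$exp
  grp_names <- sub("^groups=", "", names(sd$n))
  risky <- if (abs(oe[1] - oe[2]) < 1e-12) NA_character_ else grp_names[which.max(oe)]
  list(chi_square = chi, pvalue = pchisq(chi, df = 1, lower.tail = FALSE),
       risky_group = risky, n = as.list(n_by))
}

#' Screen network mRNAs for survival association
#'
#' For every gene in the expression matrix: dichotomize cohort expression
#' (median split by default), run the log-rank test on overall survival,
#' and keep genes with raw `p < alpha`. A BH-FDR column is always
#' reported alongside the raw p-values. Genes with no usable expression
#' (absent from clinically matched samples, or constant) are skipped with
#' a warning.
#'
#' @param expression Tibble `gene_id` + one column per cohort sample.
#' @param clinical Tibble `sample`, `time_days`, `event`.
#' @param alpha Raw-p significance threshold.
#' @param rule,q Dichotomization rule, see [dichotomize()].
#' @param keep_all Return all screened genes, not only significant ones.
#' @return Tibble with `gene`, `chi_square`, `pvalue`, `fdr`,
#'   `risky_group`, `n_high`, `n_low`, `significant`, sorted by p-value.
#' @export
screen_survival_genes <- function(expression, clinical, alpha = 0.05,
                                  rule = "median", q = 0.5,
                                  keep_all = FALSE) {
  if (!all(c("sample", "time_days", "event") %in% names(clinical))) {
    abort("`clinical` must have columns sample, time_days, event.")
  }
  if (anyDuplicated(clinical$sample)) abort("Duplicate samples in `clinical`.")
  if (any(clinical$time_days <= 0)) abort("Clinical times must be positive.")
  smp <- intersect(colnames(expression)[-1], clinical$sample)
  if (length(smp) < 10) abort("Fewer than 10 usable cohort samples.")
  clin <- clinical[match(smp, clinical$sample), ]
  mat <- counts_matrix(expression[, c(1, match(smp, colnames(expression)))])
  skipped <- character()
  rows <- purrr::map_dfr(rownames(mat), function(g) {
    x <- mat[g, ]
    if (max(x) == min(x)) {
      skipped <<- c(skipped, g)
      return(NULL)
    }
    grp <- dichotomize(x, rule = rule, q = q)
    lr <- logrank_test(grp, clin$time_days, clin$event)
    tibble(gene = g, chi_square = lr$chi_square, pvalue = lr$pvalue,
           risky_group = lr$risky_group,
           n_high = sum(grp == "high"), n_low = sum(grp == "low"))
  })
  if (length(skipped)) {
    warn(sprintf("Skipped %d gene(s) with unusable expression: %s",
                 length(skipped), paste(head(skipped, 5), collapse = ", ")))
  }
  if (nrow(rows) == 0) {
    return(tibble(gene = character(), chi_square = double(), pvalue = double(),
                  fdr = double(), risky_group = character(),
                  n_high = integer(), n_low = integer(),
                  significant = logical()))
  }
  rows$fdr <- bh_adjust(rows$pvalue)
  rows$significant <- rows$pvalue < alpha
  rows <- arrange(rows, .data$pvalue, .data$gene)
  if (!keep_all) rows <- filter(rows, .data$significant)
  rows[, c("gene", "chi_square", "pvalue", "fdr", "risky_group",
           "n_high", "n_low", "significant")]
}

#' Kaplan-Meier curves per expression group for one gene
#'
#' @param gene Gene ID present in `expression`.
#' @param expression,clinical As in [screen_survival_genes()].
#' @param rule,q Dichotomization rule.
#' @return A `cerna_km` tibble with an extra `group` column, suitable for
#'   plotting or TSV export.
#' @export
km_by_expression <- function(gene, expression, clinical, rule = "median",
                             q = 0.5) {
  smp <- intersect(colnames(expression)[-1], clinical$sample)
  mat <- counts_matrix(expression[, c(1, match(smp, colnames(expression)))])
  if (!gene %in% rownames(mat)) abort(sprintf("Gene '%s' not found.", gene))
  clin <- clinical[match(smp, clinical$sample), ]
  grp <- dichotomize(mat[gene, ], rule = rule, q = q)
  out <- bind_rows(lapply(c("high", "low"), function(gv) {
    sel <- grp == gv
    mutate(km_estimator(clin$time_days[sel], clin$event[sel]), group = gv)
  }))
  class(out) <- c("cerna_km", class(out))
  out
}

#' @rdname km_estimator
#' @param object A `cerna_km` tibble.
#' @param ... Unused.
#' @export
autoplot.cerna_km <- function(object, ...) {
  dat <- as_tibble(object)
  if (!"group" %in% names(dat)) dat$group <- "all"
  dat <- bind_rows(
    tibble(time = 0, survival = 1, group = unique(dat$group)),
    dat[, c("time", "survival", "group")])
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$survival,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
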