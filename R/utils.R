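# Internal helpers shared across modules.

# A counts table is a tibble whose first column (`gene_id`) holds unique
# gene identifiers and whose remaining columns are non-negative integer
# counts, one column per sample.

check_counts <- function(counts, arg = "counts") {
  if (!is.data.frame(counts) || ncol(counts) < 2) {
    abort(sprintf("`%s` must be a data frame with a gene_id column and at least one sample column.", arg))
  }
  if (anyDuplicated(counts[[1]])) {
    abort(sprintf("`%s` contains duplicate gene identifiers.", arg))
  }
  mat <- as.matrix(counts[, -1, drop = FALSE])
  if (!is.numeric(mat)) abort(sprintf("`%s` sample columns must be numeric.", arg))
  if (any(mat < 0)) abort(sprintf("`%s` contains negative counts.", arg))
  if (any(abs(mat - round(mat)) > 1e-8)) {
    abort(sprintf("`%s` contains non-integer counts.", arg))
  }
  invisible(counts)
}

# gene x sample numeric matrix with rownames, from a counts tibble
counts_matrix <- function(counts) {
  mat <- as.matrix(counts[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(counts[[1]])
  mat
}

matrix_to_counts <- function(mat, id_col = "gene_id") {
  out <- as_tibble(mat)
  out <- dplyr::bind_cols(tibble(!!id_col := rownames(mat)), out)
  out
}

check_samples <- function(samples, sample_names = NULL) {
  if (!is.data.frame(samples) || !all(c("sample", "condition") %in% names(samples))) {
    abort("`samples` must be a data frame with columns `sample` and `condition`.")
  }
  bad <- setdiff(unique(samples$condition), c("tumour", "normal"))
  if (length(bad)) {
    abort(sprintf("`condition` must be 'tumour' or 'normal'; found: %s", paste(bad, collapse = ", ")))
  }
  if (!is.null(sample_names)) {
    missing <- setdiff(sample_names, samples$sample)
    if (length(missing)) {
      abort(sprintf("Samples missing from the sample sheet: %s", paste(missing, collapse = ", ")))
    }
  }
  invisible(samples)
}

is_count1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == round(x)

geometric_mean <- function(x) exp(mean(log(x)))
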