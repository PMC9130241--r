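test_that("gene aggregation sums member transcripts and conserves totals", {
  cts <- as_counts(matrix(c(3, 4, 5, 10, 20, 30), nrow = 3,
                          dimnames = list(c("t1", "t2", "t3"), c("a", "b"))))
  map <- tibble::tibble(transcript = c("t1", "t2", "t3"),
                        gene = c("G", "G", "H"))
  agg <- aggregate_by_gene(cts, map)
  expect_equal(agg$a[agg$gene_id == "G"], 7)
  expect_equal(agg$b[agg$gene_id == "G"], 30)
  # one transcript per gene is a pure renaming
  map1 <- tibble::tibble(transcript = c("t1", "t2", "t3"),
                         gene = c("x1", "x2", "x3"))
  agg1 <- aggregate_by_gene(cts, map1)
  expect_equal(unname(as.matrix(agg1[, -1])),
               unname(as.matrix(cts[order(map1$gene), -1])))
  # conservation on a random fixture with unmapped transcripts
  big <- random_counts(50, 4, seed = 8)
  mapb <- tibble::tibble(transcript = big$gene_id[1:40],
                         gene = sample(sprintf("G%02d", 1:12), 40, replace = TRUE))
  expect_message(aggb <- aggregate_by_gene(big, mapb), "10 unmapped")
  expect_equal(colSums(as.matrix(aggb[, -1])),
               colSums(as.matrix(big[1:40, -1])))
  expect_error(aggregate_by_gene(cts, map[0, ]), "empty")
  expect_error(aggregate_by_gene(cts, tibble::tibble(
    transcript = c("t1", "t1"), gene = c("G", "H"))), "multiple genes")
})

test_that("TMM factors are 1 for scalar-multiple libraries and rescale to geometric mean 1", {
  m <- matrix(c(10, 20, 30, 40, 100, 200, 300, 400), ncol = 2,
              dimnames = list(paste0("g", 1:4), c("a", "b")))
  f <- tmm_norm_factors(as_counts(m))
  expect_equal(f$norm_factor, c(1, 1))
  # general fixture: geometric mean exactly 1
  f2 <- tmm_norm_factors(random_counts(300, 5, seed = 2))
  expect_equal(exp(mean(log(f2$norm_factor))), 1, tolerance = 1e-12)
  expect_error(tmm_norm_factors(as_counts(
    matrix(c(1, 2, 0, 0), 2, dimnames = list(c("g1", "g2"), c("a", "b"))))),
    "All-zero")
})

test_that("a single shared expressed gene determines the factor from its M-value alone", {
  m <- matrix(c(80, 20, 0, 40, 0, 60), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  f <- tmm_norm_factors(as_counts(m), ref_sample = "a")
  # only g1 is expressed in both; M = log2((40/100)/(80/100))
  expected_ratio <- 2^(log2((40 / 100) / (80 / 100)))
  expect_equal(f$norm_factor[f$sample == "b"] / f$norm_factor[f$sample == "a"],
               expected_ratio)
})

test_that("TMM matches a straight-line re-implementation of the trim-then-weight recipe", {
  withr::local_seed(42)
  y <- matrix(rnbinom(500 * 4, mu = outer(rexp(500, 1 / 50), c(1, 1.5, 0.7, 1.2)),
                      size = 5), 500,
              dimnames = list(paste0("g", 1:500), paste0("s", 1:4)))
  y[1:25, 3] <- y[1:25, 3] * 20  # 5% high-count contaminant subset
  f <- tmm_norm_factors(as_counts(y), ref_sample = "s1")
  lib <- colSums(y)
  oracle <- vapply(1:4, function(k) {
    if (k == 1) return(1)
    keep <- y[, k] > 0 & y[, 1] > 0
    obs <- y[keep, k]; ref <- y[keep, 1]
    M <- log2((obs / lib[k]) / (ref / lib[1]))
    A <- (log2(obs / lib[k]) + log2(ref / lib[1])) / 2
    w <- 1 / ((lib[k] - obs) / (lib[k] * obs) + (lib[1] - ref) / (lib[1] * ref))
    n <- length(M)
    keepM <- rank(M) >= floor(0.3 * n) + 1 & rank(M) <= n - floor(0.3 * n)
    keepA <- rank(A) >= floor(0.05 * n) + 1 & rank(A) <= n - floor(0.05 * n)
    2^(sum((M * w)[keepM & keepA]) / sum(w[keepM & keepA]))
  }, numeric(1))
  oracle <- oracle / exp(mean(log(oracle)))
  expect_equal(f$norm_factor, oracle, tolerance = 1e-12)
  # independent package cross-check
  skip_if_not_installed("edgeR")
  eg <- edgeR::calcNormFactors(edgeR::DGEList(y), method = "TMM")
  expect_equal(f$norm_factor, eg$samples$norm.factors, tolerance = 0.02)
})

test_that("common dispersion is recovered from data with known truth", {
  cfg0 <- sim_config(n_lnc = 2, n_mir = 2, n_mrna = 1000, n_triples = 0,
                     n_survival_genes = 0, dispersion = 0, seed = 71)
  sim0 <- simulate_counts(cfg0)
  expect_lte(estimate_common_dispersion(sim0$counts$mRNA, sim0$samples), 0.01)
  cfg2 <- sim_config(n_lnc = 2, n_mir = 2, n_mrna = 1000, n_triples = 0,
                     n_survival_genes = 0, dispersion = 0.2, seed = 72)
  sim2 <- simulate_counts(cfg2)
  phi <- estimate_common_dispersion(sim2$counts$mRNA, sim2$samples)
  expect_gte(phi, 0.1)
  expect_lte(phi, 0.4)
})

test_that("identical samples drive the dispersion estimate to the lower bound", {
  m <- matrix(rep(c(5, 9, 13, 40), each = 4), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), c("T1", "T2", "N1", "N2")))
  phi <- estimate_common_dispersion(as_counts(m), two_group_sheet(2))
  expect_equal(phi, 1e-6)
})

test_that("the exact test honours its symmetry and degenerate contracts", {
  sheet <- two_group_sheet(2)
  fac <- tibble::tibble(sample = sheet$sample, lib_size = 1e4, norm_factor = 1)
  m <- matrix(c(10, 0, 12, 0, 10, 0, 12, 0), nrow = 2,
              dimnames = list(c("same", "zero"), sheet$sample))
  res <- exact_test(as_counts(m), sheet, fac, dispersion = 0.1)
  expect_equal(res$pvalue[res$gene == "same"], 1)   # identical group sums
  expect_equal(res$pvalue[res$gene == "zero"], 1)   # all-zero gene
  expect_equal(res$log2fc[res$gene == "zero"], 0)
  # swapping group labels leaves p unchanged and negates the fold change
  m2 <- matrix(rpois(40, 25), nrow = 10,
               dimnames = list(paste0("g", 1:10), sheet$sample))
  swapped <- sheet
  swapped$condition <- rev(sheet$condition)
  a <- exact_test(as_counts(m2), sheet, fac, dispersion = 0.1)
  b <- exact_test(as_counts(m2), swapped, fac, dispersion = 0.1)
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-12)
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-12)
})

test_that("with zero dispersion the exact test reduces to the binomial split", {
  withr::local_seed(99)
  sheet <- two_group_sheet(2)
  fac <- tibble::tibble(sample = sheet$sample, lib_size = 1e4, norm_factor = 1)
  m <- matrix(rpois(200, 30), nrow = 50,
              dimnames = list(paste0("g", 1:50), sheet$sample))
  res <- exact_test(as_counts(m), sheet, fac, dispersion = 0)
  oracle <- vapply(1:50, function(i) {
    zA <- sum(m[i, 1:2]); z <- sum(m[i, ])
    pr <- dbinom(0:z, z, 0.5)
    sum(pr[pr <= dbinom(zA, z, 0.5) * (1 + 1e-8)])
  }, numeric(1))
  expect_equal(res$pvalue, oracle, tolerance = 1e-12)
})

test_that("planted fold changes are recalled with the planted direction", {
  hits <- lapply(1:5, function(r) {
    cfg <- small_config(n_mrna = 400, seed = 400 + r)
    sim <- simulate_counts(cfg)
    de <- de_analysis(sim$counts$mRNA, sim$samples)
    d <- degs(de)
    planted <- sim$truth$de_genes[sim$truth$de_genes$class == "mRNA", ]
    found <- planted$gene %in% d$gene
    agree <- planted$direction[found] ==
      d$direction[match(planted$gene[found], d$gene)]
    c(recall = mean(found), agree = mean(agree))
  })
  hits <- do.call(rbind, hits)
  expect_gte(mean(hits[, "recall"]), 0.9)
  expect_equal(mean(hits[, "agree"]), 1)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.037), 0.037)
  stepup <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    for (i in seq_len(m)) {
      j <- which(o == i)  # rank of p[i]
      adj[i] <- min(1, min(m * p[o][j:m] / (j:m)))
    }
    adj
  }
  withr::local_seed(7)
  for (r in 1:1000) {
    p <- runif(sample(1:30, 1))
    expect_identical(bh_adjust(p) <= 1, rep(TRUE, length(p)))
    expect_equal(bh_adjust(p), stepup(p), tolerance = 1e-13)
  }
  # monotone in rank and permutation-equivariant
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), adj[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("DEG calling applies strict fold-change and FDR thresholds", {
  res <- tibble::tibble(gene = c("a", "b", "c", "d"),
                        log2fc = c(1.3, 1.0, -2, -1.7),
                        fdr = c(0.01, 0.001, 0.2, 0.049))
  out <- call_degs(res)
  expect_equal(out$direction, c("up", "ns", "ns", "down"))
})

test_that("the heatmap transform is log10(value + 0.001)", {
  expect_equal(normalized_log_transform(0), -3)
  expect_equal(normalized_log_transform(0.999), 0)
  expect_equal(normalized_log_transform(99.999), 2)
  expect_error(normalized_log_transform(-1), ">= 0")
})

test_that("volcano coordinates and the cerna_de accessors are consistent", {
  cfg <- small_config()
  sim <- simulate_counts(cfg)
  de <- de_analysis(sim$counts$miRNA, sim$samples)
  v <- de_volcano_coords(tidy(de))
  expect_equal(v$neg_log10_fdr, -log10(tidy(de)$fdr))
  g <- glance(de)
  expect_equal(g$n_deg, nrow(degs(de)))
  expect_equal(g$n_deg, g$n_up + g$n_down)
  expect_s3_class(autoplot(de), "ggplot")
  hm <- de_heatmap_matrix(sim$counts$miRNA, de$factors)
  cpm <- cpm_normalized(sim$counts$miRNA, de$factors)
  expect_equal(as.matrix(hm[, -1]), log10(as.matrix(cpm[, -1]) + 0.001))
})
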