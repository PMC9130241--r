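test_that("configuration invariants are enforced", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_lnc = 0), "positive integer")
  expect_error(sim_config(effect_log2fc = -1), "effect_log2fc")
  expect_error(sim_config(dispersion = -0.1), "dispersion")
  expect_error(sim_config(decoy_pair_rate = 1.5), "decoy_pair_rate")
  expect_error(sim_config(censor_rate = 1), "censor_rate")
  expect_error(sim_config(n_triples = 500, n_mir = 100), "n_triples")
})

test_that("the same configuration and seed give bit-identical output", {
  cfg <- small_config()
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_survival(a$truth, cfg),
                   simulate_survival(b$truth, cfg))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s <- simulate_cerna_study(cfg)
  f1 <- write_study(s, d1); f2 <- write_study(s, d2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("planted truth is internally direction-consistent", {
  for (seed in c(3, 17, 202)) {
    study <- simulate_counts(small_config(seed = seed))
    expect_true(truth_consistent(study$truth))
    expect_true(all(study$truth$de_genes$direction %in% c("up", "down")))
  }
})

test_that("zero planted effect records directions but shifts no means", {
  cfg <- small_config(effect_log2fc = 0, dispersion = 0, n_pairs = 20,
                      planted_log10_range = c(0, 0),
                      lib_size_range = c(2e5, 2e5))
  sim <- simulate_counts(cfg)
  expect_equal(nrow(sim$truth$de_genes), 3 * cfg$n_triples)
  y <- as.matrix(sim$counts$mRNA[, -1])
  rownames(y) <- sim$counts$mRNA$gene_id
  planted <- sim$truth$de_genes$gene[sim$truth$de_genes$class == "mRNA"]
  tum <- sim$samples$condition == "tumour"
  ratio <- rowMeans(y[planted, tum]) / rowMeans(y[planted, !tum])
  expect_true(all(ratio > 0.8 & ratio < 1.25))
})

test_that("counts match the configured negative-binomial moments", {
  # one gene per class, fixed library size -> mu = L for the mRNA gene
  cfg <- sim_config(n_lnc = 1, n_mir = 1, n_mrna = 1, n_pairs = 5000,
                    n_triples = 0, n_survival_genes = 0, dispersion = 0.1,
                    lib_size_range = c(1000, 1000), seed = 11)
  sim <- simulate_counts(cfg)
  x <- as.numeric(sim$counts$mRNA[1, -1])
  mu <- 1000
  se <- sqrt((mu + cfg$dispersion * mu^2) / length(x))
  expect_lt(abs(mean(x) - mu), 3 * se)
})

test_that("strong planted effects separate tumour and normal means", {
  hits <- lapply(seq_len(20), function(r) {
    cfg <- small_config(seed = 300 + r, effect_log2fc = 3,
                        dispersion = 0.1)
    sim <- simulate_counts(cfg)
    up <- sim$truth$de_genes |> dplyr::filter(class == "mRNA",
                                              direction == "up")
    y <- as.matrix(sim$counts$mRNA[, -1])
    rownames(y) <- sim$counts$mRNA$gene_id
    tum <- sim$samples$condition == "tumour"
    ratio <- rowMeans(y[up$gene, tum, drop = FALSE]) /
      pmax(rowMeans(y[up$gene, !tum, drop = FALSE]), 1e-9)
    ratio > 2
  })
  expect_gte(mean(unlist(hits)), 0.99)
})

test_that("interaction tables contain exactly the planted pairs when decoys are off", {
  cfg <- small_config(decoy_pair_rate = 0)
  sim <- simulate_counts(cfg)
  ints <- simulate_interactions(sim$truth, cfg)
  planted_lm <- unique(paste(sim$truth$triples$lncRNA, sim$truth$triples$miRNA))
  expect_setequal(paste(ints$lnc_mir$regulator, ints$lnc_mir$target), planted_lm)
  planted_mm <- unique(paste(sim$truth$triples$miRNA, sim$truth$triples$mRNA))
  for (tab in ints$mir_mrna) {
    expect_setequal(paste(tab$regulator, tab$target), planted_mm)
  }
})

test_that("every planted miRNA-mRNA pair appears in all sources, decoys follow the binomial", {
  cfg <- sim_config(n_lnc = 20, n_mir = 100, n_mrna = 200, n_triples = 0,
                    n_survival_genes = 0, decoy_pair_rate = 0.01, seed = 5)
  sim <- simulate_counts(cfg)
  ints <- simulate_interactions(sim$truth, cfg)
  # 100 x 200 possible pairs at rate 0.01 -> ~200 decoys per source
  lims <- qbinom(c(0.005, 0.995), 100 * 200, 0.01)
  for (tab in ints$mir_mrna) {
    expect_gte(nrow(tab), lims[1])
    expect_lte(nrow(tab), lims[2])
  }
  # planted pairs present in every source
  cfg2 <- small_config()
  sim2 <- simulate_counts(cfg2)
  ints2 <- simulate_interactions(sim2$truth, cfg2)
  pm <- paste(sim2$truth$triples$miRNA, sim2$truth$triples$mRNA)
  for (tab in ints2$mir_mrna) {
    expect_true(all(pm %in% paste(tab$regulator, tab$target)))
  }
})

test_that("decoys never join two planted DE molecules unless allowed", {
  cfg <- small_config(decoy_pair_rate = 0.3)
  sim <- simulate_counts(cfg)
  ints <- simulate_interactions(sim$truth, cfg)
  planted <- sim$truth$de_genes$gene
  planted_mm <- paste(sim$truth$triples$miRNA, sim$truth$triples$mRNA)
  for (tab in ints$mir_mrna) {
    both <- tab$regulator %in% planted & tab$target %in% planted
    expect_true(all(paste(tab$regulator, tab$target)[both] %in% planted_mm))
  }
})

test_that("the enriched gene set holds >= 80% of planted mRNAs", {
  cfg <- small_config()
  sim <- simulate_counts(cfg)
  gs <- simulate_genesets(sim$truth, cfg)
  planted <- unique(sim$truth$triples$mRNA)
  ov <- length(intersect(gs$sets[[sim$truth$enriched_set]], planted))
  expect_gte(ov / length(planted), 0.8)
  # no planted triples -> the flagged set is an ordinary random set
  cfg0 <- small_config(n_triples = 0, n_survival_genes = 0)
  sim0 <- simulate_counts(cfg0)
  gs0 <- simulate_genesets(sim0$truth, cfg0)
  expect_true(length(gs0$sets[[sim0$truth$enriched_set]]) <=
                cfg0$geneset_size_range[2])
})

test_that("random sets overlap planted mRNAs at the hypergeometric mean", {
  cfg <- small_config()
  sim <- simulate_counts(cfg)
  planted <- unique(sim$truth$triples$mRNA)
  N <- cfg$n_mrna
  obs <- exp <- 0
  for (r in seq_len(500)) {
    cfg_r <- small_config(seed = 5000 + r)
    gs <- simulate_genesets(sim$truth, cfg_r)
    others <- setdiff(names(gs$sets), sim$truth$enriched_set)
    sizes <- lengths(gs$sets[others])
    obs <- obs + sum(vapply(gs$sets[others],
                            function(s) length(intersect(s, planted)),
                            numeric(1)))
    exp <- exp + sum(sizes * length(planted) / N)
  }
  expect_lt(abs(obs - exp) / exp, 0.1)
})

test_that("survival simulation honours censoring and hazard contracts", {
  cfg <- small_config(censor_rate = 0)
  sim <- simulate_counts(cfg)
  sv <- simulate_survival(sim$truth, cfg)
  expect_true(all(sv$clinical$event == 1))
  expect_true(all(sv$clinical$time_days > 0))
  expect_error(simulate_survival(sim$truth, small_config(hazard_ratio = -1)),
               "hazard_ratio")
  expect_error(simulate_survival(sim$truth, small_config(n_survival_samples = 5)),
               "at least 10")
})

test_that("a hazard ratio of 3 shortens risky-group survival in nearly all replicates", {
  shorter <- vapply(seq_len(200), function(r) {
    cfg <- small_config(n_mrna = 30, n_triples = 2, n_survival_genes = 1,
                        hazard_ratio = 3, censor_rate = 0,
                        seed = 9000 + r)
    sim <- simulate_counts(cfg)
    sv <- simulate_survival(sim$truth, cfg)
    sg <- sim$truth$survival_genes
    x <- as.numeric(sv$expression[match(sg$gene, sv$expression$gene_id), -1])
    grp <- dichotomize(x)
    risky <- if (sg$risk_direction == "high") grp == "high" else grp == "low"
    median(sv$clinical$time_days[risky]) < median(sv$clinical$time_days[!risky])
  }, logical(1))
  expect_gte(mean(shorter), 0.95)
})
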