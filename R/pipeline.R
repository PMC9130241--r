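default_thresholds <- function() {
  list(fc_threshold = 2, fdr_threshold = 0.05, min_sources = NULL,
       hub_threshold = 5, enrichment_alpha = 0.05, survival_alpha = 0.05,
       dichotomize_rule = "median", dichotomize_q = 0.5)
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a list. Fills threshold defaults,
#' checks every constraint, and reports *all* violations at once. Exactly
#' one of a `simulate` block (see [sim_config()] fields) or an `inputs`
#' block (paths to counts, sample sheet, interaction tables, GMT, clinical
#' and cohort-expression files) must be present.
#'
#' @param config Path to a YAML/JSON config or an equivalent list.
#' @return A validated `cerna_config` list with every default filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("Config file '%s' not found.", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("Config must be a list or a path to a YAML file.")
  problems <- character()
  thr <- utils::modifyList(default_thresholds(), config$thresholds %||% list())
  for (f in c("fc_threshold", "fdr_threshold", "hub_threshold",
              "enrichment_alpha", "survival_alpha", "dichotomize_q")) {
    v <- thr[[f]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0) {
      problems <- c(problems, sprintf("threshold `%s` must be a positive number", f))
    }
  }
  if (!is.null(thr$min_sources) &&
      (!is.numeric(thr$min_sources) || thr$min_sources < 1)) {
    problems <- c(problems, "threshold `min_sources` must be >= 1 (or null for all sources)")
  }
  if (!thr$dichotomize_rule %in% c("median", "quantile")) {
    problems <- c(problems, "`dichotomize_rule` must be 'median' or 'quantile'")
  }
  if (is.null(config$outdir) || !is.character(config$outdir)) {
    problems <- c(problems, "`outdir` (output directory) is missing")
  }
  seed <- config$seed %||% 1L
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed)) {
    problems <- c(problems, "`seed` must be a single integer")
  }
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp) {
    problems <- c(problems, "exactly one of `simulate` or `inputs` must be given")
  }
  sim <- NULL
  if (has_sim && !has_inp) {
    sim_args <- config$simulate
    if (isTRUE(sim_args)) sim_args <- list()
    sim_args$seed <- sim_args$seed %||% seed
    sim <- tryCatch(do.call(sim_config, sim_args), error = function(e) {
      problems <<- c(problems, conditionMessage(e))
      NULL
    })
  }
  if (has_inp && !has_sim) {
    need <- c("lncRNA_counts", "miRNA_counts", "mRNA_counts", "sample_sheet",
              "lnc_mir", "mir_mrna", "genesets", "clinical",
              "cohort_expression")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss)) {
      problems <- c(problems, sprintf("`inputs` missing: %s", paste(miss, collapse = ", ")))
    }
    paths <- unlist(config$inputs[setdiff(need, miss)], use.names = FALSE)
    gone <- paths[!file.exists(paths)]
    if (length(gone)) {
      problems <- c(problems, sprintf("input file(s) not found: %s", paste(gone, collapse = ", ")))
    }
  }
  if (!is.null(config$dispersion) &&
      (!is.numeric(config$dispersion) || config$dispersion < 0)) {
    problems <- c(problems, "`dispersion` must be >= 0 when given")
  }
  if (length(problems)) abort(c("Invalid pipeline configuration:", problems))
  structure(list(seed = as.integer(seed), outdir = config$outdir,
                 thresholds = thr, simulate = sim,
                 inputs = config$inputs,
                 dispersion = config$dispersion),
            class = "cerna_config")
}

load_study_inputs <- function(inputs) {
  read_counts <- function(p) {
    tab <- readr::read_tsv(p, show_col_types = FALSE)
    check_counts(tab)
    tab
  }
  mm_paths <- unlist(inputs$mir_mrna)
  list(
    counts = list(lncRNA = read_counts(inputs$lncRNA_counts),
                  miRNA = read_counts(inputs$miRNA_counts),
                  mRNA = read_counts(inputs$mRNA_counts)),
    samples = readr::read_tsv(inputs$sample_sheet, show_col_types = FALSE),
    interactions = list(
      lnc_mir = read_interaction_table(inputs$lnc_mir, "lnc_mir_db"),
      mir_mrna = lapply(seq_along(mm_paths), function(i) {
        read_interaction_table(mm_paths[i], sprintf("source%d", i))
      })),
    genesets = NULL,  # filled below with the mRNA universe
    genesets_path = inputs$genesets,
    survival = list(
      expression = readr::read_tsv(inputs$cohort_expression,
                                   show_col_types = FALSE),
      clinical = readr::read_tsv(inputs$clinical, show_col_types = FALSE))
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  })
}

#' Run the full ceRNA inference pipeline
#'
#' Executes, in order: data simulation (or loading), per-class
#' differential expression, DEG calling, multi-source target consensus,
#' DE filtering of interaction pairs, triple assembly and trend
#' splitting, trend-network construction and hub detection, gene-set
#' over-representation per trend network, survival screening of network
#' mRNAs, and survival-seeded subnetwork extraction. Every intermediate
#' is written under `outdir` as a plain-text file and a JSON run manifest
#' records per-stage counts; the same configuration and seed reproduce
#' identical manifest counts.
#'
#' @param config A `cerna_config` from [validate_config()] (or a list/path
#'   accepted by it).
#' @param outdir Output directory override.
#' @return A list of class `cerna_run` with `manifest` and all stage
#'   results (`de`, `degs`, `consensus`, `pairs`, `triples`, `networks`,
#'   `hubs`, `enrichment`, `survival`, `subnetworks`).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (!inherits(config, "cerna_config")) config <- validate_config(config)
  outdir <- outdir %||% config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  thr <- config$thresholds
  t_start <- Sys.time()
  p <- function(...) file.path(outdir, sprintf(...))

  # -- data -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    study <- run_stage("simulate", simulate_cerna_study(config$simulate))
    write_study(study, file.path(outdir, "data"))
    universe <- study$truth$genes$mRNA
  } else {
    study <- run_stage("load", load_study_inputs(config$inputs))
    universe <- study$counts$mRNA[[1]]
    study$genesets <- read_gmt(study$genesets_path, universe = universe)
  }

  # -- differential expression ------------------------------------------
  de <- run_stage("diffexpr", {
    lapply(study$counts, function(cts) {
      de_analysis(cts, study$samples, dispersion = config$dispersion,
                  fc_threshold = thr$fc_threshold,
                  fdr_threshold = thr$fdr_threshold)
    })
  })
  deg <- lapply(de, degs)
  for (cls in names(de)) {
    readr::write_tsv(tidy(de[[cls]]), p("de_%s.tsv", cls))
    readr::write_tsv(de_volcano_coords(tidy(de[[cls]])), p("volcano_%s.tsv", cls))
    readr::write_tsv(de_heatmap_matrix(study$counts[[cls]], de[[cls]]$factors),
                     p("heatmap_%s.tsv", cls))
  }

  # -- interactions and consensus ---------------------------------------
  consensus <- run_stage("consensus", {
    consensus_targets(study$interactions$mir_mrna,
                      min_sources = thr$min_sources)
  })
  readr::write_tsv(consensus, p("consensus_mir_mrna.tsv"))
  pairs <- run_stage("filter_pairs", {
    filter_pairs_to_de(study$interactions$lnc_mir, consensus,
                       deg$lncRNA, deg$miRNA, deg$mRNA)
  })

  # -- network -----------------------------------------------------------
  triples <- run_stage("triples", {
    assemble_triples(pairs$lnc_mir, pairs$mir_mrna)
  })
  readr::write_tsv(triples, p("triples.tsv"))
  parts <- split_by_direction(triples)
  networks <- list()
  hubs <- list()
  for (tr in c("HLH", "LHL")) {
    if (nrow(parts[[tr]]) == 0) next
    net <- run_stage(paste0("network_", tr), build_graph(parts[[tr]]))
    networks[[tr]] <- net
    hubs[[tr]] <- find_hubs(net, thr$hub_threshold)
    export_network(net, p("network_%s.json", tr), "json")
    export_network(net, p("network_%s.sif", tr), "sif")
    readr::write_tsv(hubs[[tr]], p("hubs_%s.tsv", tr))
  }
  if (length(networks)) {
    readr::write_tsv(network_summary(networks), p("network_summary.tsv"))
  }

  # -- enrichment --------------------------------------------------------
  enrichment <- list()
  for (tr in names(networks)) {
    query <- networks[[tr]]$nodes$id[networks[[tr]]$nodes$type == "mRNA"]
    if (!length(intersect(query, study$genesets$universe))) next
    enrichment[[tr]] <- run_stage(paste0("enrich_", tr), {
      enrich(query, study$genesets, alpha = thr$enrichment_alpha)
    })
    readr::write_tsv(as_tibble(enrichment[[tr]]), p("enrichment_%s.tsv", tr))
  }

  # -- survival ----------------------------------------------------------
  net_mrnas <- unique(unlist(lapply(networks, function(n) {
    n$nodes$id[n$nodes$type == "mRNA"]
  })))
  surv <- NULL
  subnets <- list()
  if (length(net_mrnas)) {
    expr <- study$survival$expression
    expr <- expr[expr[[1]] %in% net_mrnas, , drop = FALSE]
    if (nrow(expr)) {
      surv <- run_stage("survival", {
        screen_survival_genes(expr, study$survival$clinical,
                              alpha = thr$survival_alpha,
                              rule = thr$dichotomize_rule,
                              q = thr$dichotomize_q, keep_all = TRUE)
      })
      readr::write_tsv(surv, p("survival_screen.tsv"))
      sig <- surv$gene[surv$significant]
      for (tr in names(networks)) {
        seeds <- intersect(sig, networks[[tr]]$nodes$id)
        if (!length(seeds)) next
        subnets[[tr]] <- run_stage(paste0("subnetwork_", tr), {
          extract_subnetwork(networks[[tr]], seeds)
        })
        export_network(subnets[[tr]], p("subnetwork_%s.json", tr), "json")
      }
    }
  }

  # -- manifest ----------------------------------------------------------
  count_net <- function(n) {
    if (is.null(n)) list(nodes = 0L, edges = 0L, hubs = 0L)
    else list(nodes = nrow(n$nodes), edges = nrow(n$edges),
              hubs = nrow(find_hubs(n, thr$hub_threshold)))
  }
  manifest <- structure(list(
    package = "cernet",
    version = as.character(packageVersion("cernet")),
    seed = config$seed,
    thresholds = thr[!vapply(thr, is.null, logical(1))],
    counts = list(
      degs = lapply(deg, nrow),
      consensus_pairs = nrow(consensus),
      pairs_lnc_mir = nrow(pairs$lnc_mir),
      pairs_mir_mrna = nrow(pairs$mir_mrna),
      triples = nrow(triples),
      discordant_triples = parts$n_discordant,
      networks = lapply(stats::setNames(nm = c("HLH", "LHL")), function(tr) {
        count_net(networks[[tr]])
      }),
      enriched_terms = lapply(enrichment, function(e) sum(e$significant)),
      survival_genes = if (is.null(surv)) 0L else sum(surv$significant),
      subnetworks = lapply(stats::setNames(nm = c("HLH", "LHL")), function(tr) {
        count_net(subnets[[tr]])
      })
    ),
    started = format(t_start, "%Y-%m-%dT%H:%M:%OS3%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")
  ), class = "cerna_manifest")
  jsonlite::write_json(unclass(manifest), p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(list(manifest = manifest, de = de, degs = deg,
                 consensus = consensus, pairs = pairs, triples = triples,
                 networks = networks, hubs = hubs, enrichment = enrichment,
                 survival = surv, subnetworks = subnets,
                 truth = study$truth %||% NULL, outdir = outdir),
            class = "cerna_run")
}

#' Stage counts of a run manifest
#'
#' Timestamp-free view of a manifest, suitable for determinism
#' comparisons: two runs with the same configuration and seed must agree
#' on it exactly.
#'
#' @param manifest A `cerna_manifest` (or a `cerna_run`).
#' @return A nested list of per-stage counts.
#' @export
manifest_counts <- function(manifest) {
  if (inherits(manifest, "cerna_run")) manifest <- manifest$manifest
  manifest$counts
}

#' @export
print.cerna_manifest <- function(x, ...) {
  cat(sprintf("<cerna_manifest> %s %s, seed %d\n", x$package, x$version, x$seed))
  cat(sprintf("  DEGs: %s; triples: %d (%d discordant)\n",
              paste(sprintf("%s=%d", names(x$counts$degs),
                            unlist(x$counts$degs)), collapse = ", "),
              x$counts$triples, x$counts$discordant_triples))
  for (tr in names(x$counts$networks)) {
    n <- x$counts$networks[[tr]]
    cat(sprintf("  %s network: %d nodes, %d edges, %d hubs\n",
                tr, n$nodes, n$edges, n$hubs))
  }
  cat(sprintf("  survival-associated mRNAs: %d\n", x$counts$survival_genes))
  invisible(x)
}

#' @export
print.cerna_run <- function(x, ...) {
  print(x$manifest)
  invisible(x)
}
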