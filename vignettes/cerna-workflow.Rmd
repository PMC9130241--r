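---
title: "Inferring lncRNA-miRNA-mRNA ceRNA networks with cernet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring lncRNA-miRNA-mRNA ceRNA networks with cernet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

## The biological model

Competing endogenous RNAs (ceRNAs) are transcripts that share miRNA
response elements. A lncRNA that sponges a miRNA de-represses that
miRNA's mRNA targets, so a functional lncRNA--miRNA--mRNA axis leaves a
characteristic fingerprint in tumour-versus-normal expression data: the
sponge and the target move together while the miRNA moves the other way.
`cernet` operationalizes this as two admissible trend patterns for a
triple (lncRNA, miRNA, mRNA):

* **HLH** (high--low--high): lncRNA up, miRNA down, mRNA up in tumour;
* **LHL** (low--high--low): lncRNA down, miRNA up, mRNA down.

Any other direction combination is *discordant* and is discarded, because
it is not explicable by sponging. The pipeline is: per-class differential
expression → multi-source miRNA-target consensus → restriction of
interaction pairs to differentially expressed molecules → triple assembly
and trend splitting → network construction and hub detection → gene-set
over-representation of network mRNAs → survival screening in an external
cohort → survival-seeded subnetwork extraction.

## Differential expression

Counts are modelled as negative binomial with variance
$\mu + \phi\mu^2$. The screen has four stages, each its own function so
that any stage can be audited in isolation.

**TMM normalization** (`tmm_norm_factors()`). For sample $k$ against a
reference $r$, genes with a zero in either library are removed and

$$M_g = \log_2 \frac{y_{gk}/N_k}{y_{gr}/N_r}, \qquad
  A_g = \tfrac12\left(\log_2 \frac{y_{gk}}{N_k} + \log_2 \frac{y_{gr}}{N_r}\right).$$

The top and bottom 30% by $M$ and 5% by $A$ are trimmed and the factor is
$2$ raised to the precision-weighted mean of the surviving $M_g$, with
weights from binomial delta-method variances; factors are rescaled to
geometric mean 1. These trim fractions are the standard TMM recipe; no
alternative is exposed because composition bias, not the trim, is the
quantity of interest. The reference defaults to the sample whose
75th-percentile CPM is closest to the mean of those percentiles.

**Common dispersion** (`estimate_common_dispersion()`). With three
samples per group there is far too little information for per-gene
dispersions, so a single $\phi$ is estimated by maximizing the summed
per-gene conditional NB log-likelihood given each gene's group totals,
after rescaling counts to a common effective library size (the geometric
mean of the TMM-effective sizes, rounded to integers — rounding keeps
the subsequent convolution exact). The maximizer is a golden-section
search on $\log\phi$ over $[10^{-6}, 10]$; data with no overdispersion
signal are driven to the lower bound, which is then reported as the
estimate. No tagwise shrinkage is applied: a 3-vs-3 design cannot
support it, and the added hierarchy would only obscure what the exact
test is conditioning on.

**Exact test** (`exact_test()`). Conditioned on a gene's total across
the equalized libraries, the tumour-group sum follows a convolution of NB
distributions that does not depend on the gene's mean. The two-sided
p-value sums the probabilities of every partition of the total whose
point probability is at most that of the observed partition (ties,
within a $10^{-8}$ relative tolerance, are included in the rejection
mass). At $\phi = 0$ this reduces exactly to a two-sided binomial split,
which the test suite exploits as an enumeration oracle. A gene with
total zero gets $p = 1$ and log-fold-change 0.

**Fold change and calling.** The reported effect is
$\log_2\{(\bar c_T + 0.5)/(\bar c_N + 0.5)\}$ on TMM-normalized CPM
group means; the 0.5 prior avoids infinite ratios at zero counts and
shrinks only genes near the detection floor. A gene is differentially
expressed iff $|\log_2 FC| > 1$ **and** BH-FDR $< 0.05$, both strict,
matching the "fold change greater than 2" convention. The heatmap export
uses $\log_{10}(\text{normalized} + 0.001)$, and volcano coordinates are
$(\log_2 FC,\, -\log_{10} \text{FDR})$.

The design is deliberately a two-group comparison: although the samples
are patient-paired, a paired NB model is not identifiable at this size
and the exact test conditions pairing away. This is stated rather than
guessed at; the sample sheet retains the patient column so a paired
analysis could be added.

## Interaction consensus and triple assembly

lncRNA--miRNA pairs come from a single interaction source; miRNA--mRNA
pairs from several (three by default). `consensus_targets()` keeps a pair
iff it appears in at least `min_sources` distinct sources. Whether a
practitioner should require *all* sources or *any* is genuinely
ambiguous in common usage; the default is the strictest reading
(`min_sources = `number of sources) because target databases have high
individual false-positive rates and the intersection is the conventional
noise filter — the knob is exposed for sensitivity analyses.
`filter_pairs_to_de()` then intersects both pair lists with the DEG sets
of the matching classes; an identifier occurring in more than one class
is treated as a namespace collision and refused rather than silently
merged. `assemble_triples()` enumerates the complete join on the shared
miRNA, classifies trends, and `split_by_direction()` partitions
concordant triples (conserving the total count). Degree is counted on
unique undirected edges — a pair supported by several sources still
contributes one edge — and a node is a hub iff its degree strictly
exceeds 5 (configurable).

## Enrichment

Over-representation of network mRNAs uses the one-sided hypergeometric
tail computed in log space (`stats::phyper`), with the universe set to
all genes of the expression matrix rather than all annotated genes: only
genes that could have entered the network belong in the background.
Genes outside the universe are dropped from both query and sets.
Significance is flagged at raw $p < 0.05$ to mirror the conventional
reporting of ORA figures, but a BH-FDR column is always emitted
alongside; both are in the output precisely because reports often do not
say which was used.

## Survival screening

Cohort expression is dichotomized at the median (ties to the low group;
a quantile rule is available), compared by the standard 1-df log-rank
test, and genes with $p < 0.05$ seed the subnetwork extraction — the
seed mRNAs, their adjacent miRNAs, the lncRNAs adjacent to those miRNAs,
and only the connecting edges. No multiplicity correction is applied to
the screen itself, matching the per-gene reporting convention for this
kind of analysis, but again a BH column is emitted. Kaplan--Meier curves
and the log-rank statistic are delegated to the `survival` package; the
test suite verifies them against hand-computed product-limit and
observed-minus-expected tables.

## What the synthetic generator emulates

`simulate_cerna_study()` produces the full input bundle with a known
planted truth. Counts follow
$y_{gi} \sim \mathrm{NB}(L_i\, b_g\, 2^{s_g \delta [i \in T]},\ \phi)$
with library sizes $L_i$ uniform on `lib_size_range`, baselines $b_g$
log-uniform over four decades (so normalization is actually exercised),
planted direction $s_g \in \{+1, -1, 0\}$ and effect $\delta$
(`effect_log2fc`). Defaults are the study design: 3 tumour/3 normal
pairs, 20 planted triples at $|\log_2 FC| = 3$, $\phi = 0.1$, an
85-patient cohort with hazard ratio 3.

Choices worth knowing about:

* **Library sizes** default to $10^5$--$5\times10^5$. Real libraries are
  deeper; this is a deliberately down-scaled depth that keeps per-gene
  counts (a few hundred on average) in the regime where the exact test's
  behaviour is representative while simulations stay cheap. Problem
  sizes used throughout the package's own validation are 120--2000 genes
  per class, 20 replicates for recovery properties, 200 for survival
  power and 1000 for null calibrations.
* **Planted genes draw their baseline from the top two abundance
  decades.** Sponging is a stoichiometric mechanism: a ceRNA axis among
  trace transcripts is not biologically credible, and network actors
  should be robustly detectable. This is a property of the generator's
  model of a "real" ceRNA axis, not a tuning knob.
* **Pairing is not simulated** (no patient random effect): samples are
  independent given $b_g$, consistent with the two-group test used
  downstream.
* **Decoy interactions** are added independently per source at
  `decoy_pair_rate`, never duplicating planted pairs, and — unless
  `allow_confusable = TRUE` — never joining two planted DE molecules, so
  a decoy can never complete a direction-consistent triple among planted
  genes and recovery metrics stay interpretable.
* **Survival**: a latent risky half of the cohort has its exponential
  event rate multiplied by the hazard ratio; each planted survival
  gene's expression is shifted by $\pm 1.5$ on the log scale (about
  three within-group SDs) in the risky half, so its median split
  recovers the risk group almost surely. Censoring is independent, at a
  uniform fraction of the event time. With several survival genes a
  single latent risk group keeps the joint model well defined.
* **Gene sets**: one randomly chosen set receives 90% of the planted
  triple mRNAs plus fillers (guaranteeing the $\ge 80\%$ overlap
  contract); all others are uniform draws from the mRNA universe.

What passing tests on these data do **not** show: robustness to
isoform-level structure, batch effects, patient-level correlation,
alias-ridden identifiers, or database bias in real interaction
resources — none of which the generator emulates. The generator's
recoverable truth validates the *machinery*, not the biology of any
particular dataset.

## Numerical and degenerate-input conventions

* The exact-test convolution is evaluated gene-by-gene over the full
  partition support in log space with per-gene max subtraction; p-values
  are clipped to $(0, 1]$.
* Dispersion search interval $[10^{-6}, 10]$ on the log scale;
  golden-section to a $10^{-10}$ interval width; estimates within 1% of
  the lower bound are reported as the bound.
* TMM with no shared expressed genes, an empty post-trim set, or a
  non-finite weighted mean falls back to factor 1 with a warning; an
  all-zero sample is an error.
* `dichotomize()` refuses constant vectors and fewer than 4 samples;
  a log-rank screen with zero events warns and returns
  $\chi^2 = 0,\ p = 1$; tied observed-minus-expected gives no risky
  group (`NA`).
* Empty DEG sets cascade gracefully: downstream stages record zero
  counts rather than failing, and the run manifest still covers every
  stage.

## A worked run

```{r, eval = FALSE}
study <- simulate_cerna_study(sim_config())
de <- lapply(study$counts, de_analysis, samples = study$samples)
deg <- lapply(de, degs)
cons <- consensus_targets(study$interactions$mir_mrna)
pairs <- filter_pairs_to_de(study$interactions$lnc_mir, cons,
                            deg$lncRNA, deg$miRNA, deg$mRNA)
triples <- assemble_triples(pairs$lnc_mir, pairs$mir_mrna)
parts <- split_by_direction(triples)
net <- build_graph(parts$HLH)
glance(net)
enrich(net$nodes$id[net$nodes$type == "mRNA"], study$genesets)
screen_survival_genes(study$survival$expression, study$survival$clinical)
```

Or in one call with every intermediate written to disk:

```{r, eval = FALSE}
run <- run_pipeline(list(seed = 1, outdir = "cerna_out",
                         simulate = list()))
run$manifest
```

## Known limitations

* The exact test is two-group only; paired or covariate-adjusted designs
  need a GLM framework, out of scope here.
* Identifier matching is exact-string after whitespace trimming; no
  alias resolution is attempted because alias maps are
  database-version-dependent.
* Hub counts and network sizes from real data depend strongly on
  database versions and thresholds; the package validates its accounting
  on synthetic graphs with known answers rather than claiming to
  reproduce any particular published network.
* The survival screen's median split discards within-group dose
  information; a Cox model would use it, but the log-rank screen is the
  field's convention for expression dichotomies.
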