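---
title: "Models and methods behind coseg"
author: "coseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coseg)
```

# The problem

Aphids secrete salivary proteins into their host plants; some of these act
as effectors that suppress or trigger host immunity. When a virulent (VIR)
and an avirulent (AVR) aphid genotype differ at thousands of loci — as
divergent biotypes within a species complex do — a straight VIR-vs-AVR
differential expression contrast is dominated by genomic background and
says little about which genes actually determine the interaction outcome.

`coseg` implements a bulk-segregant co-segregation strategy around a cross
between a VIR and an AVR parent. A dominant virulence allele (call it *V*)
carried heterozygously by the VIR parent segregates 1:1 among F1 clones.
Pooling the most virulent and the most avirulent F1 siblings (22 each)
averages out unlinked background differences — each pool contains roughly
50% of each parental genome — while genes cis-linked to the virulence locus
keep their full expression contrast between pools. Intersecting pool-level
transcriptomics with parental transcriptomics and label-free proteomics of
saliva and salivary glands then filters candidates down to genes whose
expression co-segregates with phenotype.

# The synthetic cross

Every stage is exercisable without any external data through the generator
in `simulateCross()`, `simulatePhenotypes()`, `simulateCounts()` and
`simulateIntensities()`, parameterised by a single `simConfig()` object.
The generator's defaults encode the study design the package emulates:

* **Genetics.** 78 F1 clones from clonal diploid parents; parents carry
  private heterozygous alleles at 7 neutral marker loci (so true hybrids
  are verifiable: each clone must carry exactly one allele from each parent
  at every locus, `verifyF1()`); the VIR parent is *Vv* at the virulence
  locus, the AVR parent *vv*, so F1 genotypes segregate 1:1 with complete
  dominance.
* **Expression model.** 2000 genes; baseline log2 relative expression is
  Normal(0, 1.5). 200 *background* genes are homozygous-divergent between
  the parental backgrounds with a ±4 log2 effect split between alleles;
  diploid expression is the linear-scale mean of the two allele values, so
  every F1 clone is the same heterozygote and an F1 pool carries exactly
  zero background contrast while the parent contrast sees the full effect.
  10 *linked* genes follow the *V* allele with dominant coding (any *V*
  shifts the mean by ±4 log2), so they separate both the parents and the
  pools. The effect size 4 is deliberately well above the |log2FC| > 2
  call threshold so the end-to-end recovery property is a test of the
  pipeline, not of marginal power. Host-responsive expression is
  configurable (`n_host_responsive`) but defaults to off: the study found
  only a few dozen host-affected genes, and none of the package's claims
  depend on them.
* **Counts.** Negative binomial with dispersion φ = 0.1 (φ = 0 gives the
  Poisson limit used by calibration tests); library sizes are log-normal
  with 10% CV around 2 × 10⁵ so that normalisation is actually exercised.
  Pooled-F1 samples average the member clones' expected expression before
  sampling — pooling equal numbers of aphids pools transcripts
  approximately additively. The desk-scale library size keeps a full
  simulated contrast in the low seconds; the statistical structure (not
  sequencing depth) is what the downstream claims depend on.
* **Phenotypes.** Per clone × host, 10 plants each infested with 5 nymphs;
  survivors ~ Binomial(5, p) and nymphs ~ NB(mean, size 5), with nymphs
  forced to 0 on plants with no survivors (dead clones cannot reproduce).
  The NB size 5 (moderate overdispersion) is a package choice; nothing
  downstream is sensitive to it. Survival defaults are p = 0.95 for
  virulent combinations and p = 0.05 for avirulent clones on resistant
  hosts. The virulent value is set clear of the day-5 confirmation cutoff
  (> 80% survival) because the emulated design requires 22 confirmed
  clones per side to exist — with p at 0.9 the screen would reject a
  quarter of genuinely virulent clones, which contradicts the tightly
  separated populations the workflow assumes.
* **Proteins.** 1000 proteins with log2 abundance Normal(25, 2), replicate
  noise SD 0.3, 4 replicates per genotype; 100 truly differential
  (±2 log2) and 20 truly absent in one genotype. Missingness is
  missing-not-at-random: an observation at log2 intensity *x* drops out
  with probability `plogis((20 - x) * 0.8)`, i.e. ~2% at the centre of the
  abundance distribution rising steeply below log2 intensity ≈ 21.

All randomness flows from one master seed through named per-stage
substreams, so any stage can be re-run alone and reproduce its output
byte-for-byte.

**What the generator does not emulate:** sequence-level structure (reads,
peptides, genomes), recombination maps and linkage decay around the locus,
epistasis, parent-of-origin effects, correlated protein–transcript noise,
batch effects, and the long-tailed peptide-level missingness of real
MaxQuant output. Passing tests therefore demonstrate that the *methods*
recover the structure they assume; they are not evidence about any real
aphid dataset.

# Phenotyping

The virulence index is `log2(mean survivors out of 5 × nymphs + 1)`, with
both factors averaged per plant over the 10 plants (per-plant averaging
makes the two factors scale-compatible; `virulenceCalls(nymphs = "total")`
exposes the clone-total alternative). Classification uses strict
inequalities — VIR iff index > 4 on A17 and > 5 on RNIL, AVR iff < 2 and
< 4.5; boundary values stay unclassified, and the asymmetric cutoffs
reflect RNIL's slightly weaker resistance. The day-5 confirmation screen
(> 80% survival on both hosts for VIR; < 20% on A17 and < 70% on RNIL for
AVR, with an override flag for weak-growth clones categorised AVR) uses
survival fractions over 4 plants × 5 aphids = 20 infested individuals.
Bulk selection takes the top/bottom `k = 22` confirmed clones by A17
index with deterministic tie-breaking (RNIL index, then clone id).

# The differential expression engine

The count engine is written from the published definitions of each step
rather than delegating to a DE library (an installed library is used only
as an independent cross-check in the test suite).

* **TMM.** The reference sample minimises the distance of its
  75th-percentile count fraction from the mean of those fractions. Per
  sample, M and A values over genes expressed in both sample and
  reference; 30% two-sided trim on M, 5% on A; factor = 2 to the
  precision-weighted mean of retained M values with delta-method binomial
  weights; factors rescaled to geometric mean 1.
* **TMM-FPKM** for reporting and heat-map export:
  `counts × 10⁹ / (length × library × factor)`, log2(x + 1) and gene-wise
  mean-centring for the "log2 zero-centred" matrix and PCA.
* **Dispersion.** Method-of-moments on counts scaled to a common effective
  library: φ̂ = max(0, (s² − μ)/μ²) from pooled within-group residuals,
  shrunk toward the median per-gene value with prior weight d₀ = 10
  against the residual degrees of freedom. d₀ = 10 stabilises the n = 3–5
  designs this engine targets; the exact value is uncritical because the
  simulation's genes share one dispersion.
* **Exact test.** Counts are scaled to the geometric-mean effective
  library size and rounded to pseudo-counts; group sums a and b are
  treated as NB with means proportional to replicate numbers and
  dispersion φ/n, and the two-sided p sums, over all splits of t = a + b,
  the conditional probabilities no larger than the observed split's
  (normalised over t). This group-sum conditional formulation fits every
  contrast in the workflow (all are two-group) and admits an exact
  independent oracle: at φ = 0 it reduces to the conditional binomial
  test, which the suite checks to 10⁻¹⁰ on every split of every total up
  to 50. Ties at the observed probability are included using a 1 + 10⁻¹²
  relative tolerance, and t = 0 returns p = 1 by convention.
* **Calling.** log2FC from factor-normalised CPM with a prior count of 0.5
  added to both group means; genes with zero counts across the contrast
  are excluded before Benjamini–Hochberg; calls require |log2FC| > 2 and
  FDR < 0.05 with strict inequalities. A mean-CPM filter exists
  (`cpm_filter`) but is off by default, matching an engine that tests all
  nonzero genes.

# The proteomics workflow

MaxQuant-style tables are filtered of reverse, contaminant and
identified-by-site entries and log2-transformed. Missing values are imputed
from Normal(μ − 2.1σ, (0.1σ)²), where μ and σ are the mean and SD of *all*
measured values (global scope is the default because the downshift is
defined against all measured values; `scope = "per_sample"` exposes the
common per-column convention). SSDA testing is a per-protein Welch t-test
at p ≤ 0.05 with no multiple-testing correction — mirroring the plain
cutoff convention of the emulated workflow — with a BH mode behind
`adjust = TRUE`. Welch is used because nothing guarantees equal variances;
degenerate rows are guarded (equal constants → p = 1; unequal constants →
flagged `exactly_separated` rather than reporting a meaningless 0 from the
t formula). Signed relative fold changes are computed on raw-scale group
means of the imputed matrix as A/B when A ≥ B else −(B/A), so |RFC| ≥ 1
on both sides. Exclusive proteins require detection in *all* replicates of
one genotype and *none* of the other, evaluated before imputation.
PCA uses imputed intensities by default (unimputed matrices contain NA);
both are accessible since `pcaSummary()` takes any matrix.

# Evidence integration

`buildEvidence()` assembles a gene × dataset matrix over the five datasets
(saliva, salivary gland, parent head, parent body, F1 body). For proteomic
datasets "represented" means detected or differentially abundant
(undirected presence is a distinct state); for transcriptomic datasets it
means DE-called. Directed calls take precedence over presence;
contradictory directed calls within one dataset are a hard error; id
unification is an explicit input map and unmapped ids are reported, never
dropped. The candidate filter keeps genes represented in ≥ 3 datasets or
in the F1 transcriptome plus ≥ 1 other. Side assignment requires
direction concordance across datasets; genes with opposing directions are
labelled `conflict` and surface separately (also via
`directionConflicts()`, which enumerates the parent-body/F1-body opposing
patterns), and presence-only candidates are labelled `undirected` rather
than forced onto a side.

Category enrichment is a one-sided hypergeometric test (strict mode:
BH FDR < 0.05; lenient mode: ≥ 2 set members and p < 0.05). A Wallenius
noncentral option accepts per-gene bias weights and collapses them to a
single odds ratio per term (mean weight inside over outside), computed by
numerical integration of the Wallenius pmf — an approximation to full
length-bias correction, which is out of scope. Percentages throughout are
rounded to the nearest integer, half away from zero.

# Numerical and design notes

* Probabilities in the exact test are computed in log space and
  renormalised, so totals in the 10⁵ range remain stable.
* `selectBulks()` raises a selection error naming the shortfall when fewer
  than k clones confirm on a side; `runAll()` propagates it with the stage
  name (`bulk_selection`) and retains earlier artifacts.
* The orchestrator writes every table with a `# stage=` header line and a
  YAML manifest with parameters, seed and md5 checksums; identical
  configuration and seed reproduce identical checksums.
* Problem sizes used by the test suite and the acceptance script — 2000
  genes, 10 + 10 body samples, 1000 proteins, five simulation seeds — are
  the package's desk-scale defaults; they are large enough for the binomial
  and moment calibration intervals asserted in the tests and complete in
  seconds per run.

# Known limitations

Single biallelic virulence locus with complete dominance (incomplete
penetrance only via survival probabilities); two-group contrasts only (no
multi-factor designs or batch correction); enrichment ignores the GO DAG;
the Welch test treats imputed values as data, so SSDA p-values near the
detection limit inherit imputation assumptions — the same caveat that
applies to the workflow it reproduces; and the simulated host correlation
of virulence indices (~0.99) is tighter than real screens, where
environmental noise between assays dominates.
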