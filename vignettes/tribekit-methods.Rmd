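---
title: "Identifying RBP targets from HyperTRIBE editing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying RBP targets from HyperTRIBE editing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tribekit)
```

## The measurement and the statistical problem

HyperTRIBE fuses an RNA-binding protein (RBP) to the hyperactive catalytic
domain of Drosophila ADAR. Wherever the fusion binds an mRNA, ADAR deposits
A-to-I edits, which sequencers read as A-to-G mismatches. Sequencing
libraries from cells expressing the fusion, a catalytically dead fusion
(expression-matched control), and an empty vector therefore carry the RBP's
binding footprint as a set of positions where the fusion libraries show a
reproducibly higher fraction of edited reads.

The statistical task is to decide, per site, whether the edit frequency in
fusion libraries exceeds the controls by more than biological replicate
noise allows. At a site covered by $n$ reads of which $k$ carry the edited
allele, a binomial model understates replicate-to-replicate variability:
the true per-library edit frequency $p$ itself varies between animals,
transductions, and sorts. We therefore model $p \sim
\mathrm{Beta}(\alpha, \beta)$ and $k \mid n, p \sim \mathrm{Binomial}(n,
p)$, giving the beta-binomial

$$f(k \mid n, \alpha, \beta) = \binom{n}{k}
  \frac{B(k + \alpha,\; n - k + \beta)}{B(\alpha, \beta)},$$

reparametrised by the mean $\mu = \alpha / (\alpha + \beta)$ and
overdispersion $\rho = 1 / (\alpha + \beta + 1)$, both in $(0, 1)$, so that
$E(k) = n\mu$ and $\mathrm{Var}(k) = n \mu (1 - \mu)\,[1 + (n - 1)\rho]$.
`dbetabinom()` evaluates the density in log space; `bb_moments()` and
`rbetabinom()` expose the moments and the generative sampler.

## The differential-editing test

Per site, `test_editing()` fits two nested models by maximum likelihood
over the per-library counts:

* **null** — all libraries share one beta distribution $(\mu_0, \rho)$;
* **alternative** — fusion libraries draw from $(\mu_1, \rho)$ and pooled
  control libraries (catalytic-dead and empty vector together) from
  $(\mu_2, \rho)$, with a shared $\rho$.

Twice the log-likelihood-ratio is referred to a chi-square distribution.
We use one degree of freedom: the alternative adds exactly one free mean
parameter while $\rho$ is shared within each fit (it is re-estimated
separately under null and alternative). P-values from all tested sites are
Benjamini–Hochberg adjusted (`bh_adjust()`), and `call_significant_sites()`
applies a strict `fdr < threshold` rule with the conventional presets of
0.05, 0.01, and 0.1 for increasingly noisy experiment classes.

The effect size reported alongside is the **differential edit frequency**
(`diff_frequency()`): the mean of per-library $k/n$ over fusion libraries
minus the mean over pooled controls. Libraries with $n = 0$ at a site are
excluded from their group's mean — $k/n$ is undefined at $n = 0$, and
imputing 0 would bias low-coverage libraries toward "unedited".

`test_celltype()` reuses the same machinery one-vs-rest: the null pools
all cell types, the alternative gives the target cell type its own mean
against the pooled remainder. We pool the non-target cell types rather
than modelling them per-type because the alternative as formulated is a
two-beta comparison; permutation of the pooled labels leaves the result
unchanged (a tested invariant).

### Numerical choices

Likelihoods are maximised in $(\mathrm{logit}\,\mu, \mathrm{logit}\,\rho)$
space with `optim(method = "L-BFGS-B")` inside box boundaries at
$10^{-6}$ and $1 - 10^{-6}$. Starts: a method-of-moments estimate plus two
fixed fallbacks; for the alternative fit the null optimum
$(\mu_0, \mu_0, \rho_0)$ is always included as a start, which guarantees
the nested alternative never scores below the null and the LRT statistic
is nonnegative up to optimizer tolerance (tiny negatives are clipped;
anything beyond $10^{-6}$ raises an error rather than passing silently).
Degenerate all-zero or all-$n$ sites resolve to boundary-clipped maxima
and are flagged `boundary = TRUE`, never dropped silently.

### Calibration: what the tests show and do not show

With 20 libraries per group at ~100x negative-binomial coverage, the
chi-square(1) reference is well calibrated: across 10,000 null-simulated
sites the type-I error at $\alpha = 0.05$ is ~0.05–0.06 and the
Kolmogorov–Smirnov distance of the p-values from uniform is ~0.02. At the
replication depth of a typical experiment (3 libraries per group) the LRT
is measurably anticonservative — we observe type-I error near 0.10 at
nominal 0.05 — which is a known finite-sample property of likelihood-ratio
tests, not an implementation artefact (the inflation decays monotonically
with replicate count). This is one reason target calling layers an effect
size floor (diff.frequency ≥ 0.1) and FDR control on top of the raw test,
and why the stricter FDR presets exist for the deeply sequenced
experiment classes.

## From sites to gene targets

`call_targets()` retains a gene when it is expressed at **fpkm ≥ 5** and
owns at least one significant site with **diff.frequency ≥ 0.1** (both
boundaries inclusive, per "at least"). Genes whose significant sites lack
an expression record are excluded with a warning — the expression rule
cannot be evaluated for them — and the expression table is expected from
the control (empty-vector) libraries of the profiled cell type, since the
filter is about what the profiled cells express.

`compare_target_sets()` performs the exact set algebra behind
shared/unique target comparisons. `ge_independent_filter()` removes genes
whose apparent differential binding could be an expression artefact: a
gene is kept when its differential expression is not significant
(FDR ≥ 0.05) or is significant but small in the stated direction
(log2 fold change ≤ 0.26, i.e. fold change ≤ 1.2); the `direction`
argument flips the ratio for the reciprocal comparison.

For display matrices, `build_difffreq_matrix()` records each gene's
maximum diff.frequency per cell type, filling untested pairs with 0 but
returning a `tested` mask so "no evidence" is distinguishable from
"tested, not significant". `zscore_expression_matrix()` averages replicate
libraries per condition and z-transforms each gene using the population
(n-denominator) standard deviation — the convention is stated here because
either choice is defensible and they differ by a constant factor.
`wpgma_row_order()` orders heatmap rows by hierarchical clustering with
McQuitty (WPGMA) linkage on Euclidean row distances.

## Variant filtering

`strand_consistent_filter()` encodes the directionality of A-to-I editing:
on the forward genomic strand, a genuine edit is A→G in a plus-strand
transcript or T→C in a minus-strand transcript; every other substitution
is removed, as are variants outside annotated exons. Known germline SNPs
(dbSNP-style lists, BED or VCF) are excluded by exact position
(`exclude_known_snps()`), with BED's 0-based half-open coordinates
converted on read — internally everything is 1-based inclusive (VCF
convention).

Two policies are deliberate design choices where practice varies:

* A site overlapping transcripts on both strands is kept if at least one
  host transcript makes it strand-consistent; all consistent host genes
  are recorded and the primary gene/region follows the priority
  **3'UTR > CDS > 5'UTR > other-exonic**, reflecting where RBP-guided
  editing concentrates.
* In the assembled union matrix (`assemble_count_matrix()`), a library
  that reported no variant at a site contributes (0, 0) and is excluded
  from that site's frequency means rather than counted as frequency 0.

## Motif analysis and edit-site clustering

`motif_pwm()` converts a position count matrix to per-column
probabilities with a sampling correction — pseudo-mass `c = 0.5` added to
every cell before normalising, so no probability is zero; `c` is
configurable. Scores are summed log-odds against a background nucleotide
distribution. An offset is a motif occurrence when its score reaches 90%
of the maximum attainable score. Because log-odds can be negative, "90%
of the maximum" is ambiguous in the raw scale; by default the rule is
applied to the score linearly rescaled so the minimum attainable score
maps to 0 (`mode = "rescaled"`), with raw-scale thresholding available as
`mode = "raw"`. Site-to-motif distances (`distance_to_nearest()`) use the
occurrence midpoint as the anchor for point-like features and
nearest-interval-point distance for peaks (0 inside a peak).

`extract_site_windows()` takes ±100 bp around each 3'UTR edit site and
merges overlapping windows; `sample_background_windows()` draws 201-bp
windows uniformly from 3'UTR space with any position covered by target
windows removed first, so background can never overlap a target window.

`select_cluster_window()` chooses the edit-site clustering scale: for each
candidate half-width $W$ (default 1–50 bp in 1-bp steps) it classifies
significantly and non-significantly edited sites by whether a motif
occurrence overlaps $[\mathrm{site} - W, \mathrm{site} + W]$, tests
enrichment with a one-sided Fisher's exact test, and returns the largest
$W$ with $p < 0.01$. The logic rests on weakly edited sites sharing
sequence context with strongly edited ones: as $W$ grows, background
windows begin to capture the motifs anchoring nearby true sites and the
enrichment dissolves, which is what bounds the window.
`cluster_edit_sites()` then chains consecutive sites within the chosen
half-width (single linkage) and reports cluster sizes and the singleton
fraction.

## The synthetic-data generator

`simulation_scenario()` fixes the study conditions; `simulate_genome()`,
`simulate_counts()`, and `simulate_experiment()` realise them. Defaults:

* 500 genes, one single-exon transcript per contig, 5'UTR/CDS/3'UTR of
  100/300/600 bp, random strand; 2 candidate sites per gene, 94% placed in
  the 3'UTR (5% CDS, 1% 5'UTR), the reference base forced to A (plus
  strand) or T (minus strand).
* 10% of sites are true targets: fusion libraries edit at $\mu = 0.35$,
  controls at 0.02; non-target sites carry low-level background editing
  ($\mu = 0.005$) in every group, mimicking endogenous editing seen in
  controls; overdispersion $\rho = 0.02$ throughout.
* Read depth per site and library is negative binomial (mean 100,
  dispersion 5), scaled per gene by a Gamma(4, 4) expression factor that
  also sets the gene's fpkm (scale 20); coupling coverage to expression
  reflects how editing detection actually depends on transcript abundance.
* Three replicates each of fusion, catalytic-dead, and empty-vector
  libraries.
* A UAG-repeat consensus motif (`TAGTAG`) is planted 30 bp downstream of
  every true site in transcript sense; decoy germline SNPs (optional) are
  strand-consistent positions "edited" at 50% in all groups and listed in
  the known-SNP output, so the dbSNP filter is exercised end to end.

`write_fixtures()` emits FASTA/GTF/VCF/BED/YAML/TSV files that round-trip
exactly through the package's own readers (a tested invariant).

What the generator does **not** emulate: alignment artefacts, strand
bleed-through, sequencing error as a separate mixture component,
multi-isoform genes, and non-uniform coverage along transcripts. Passing
tests on synthetic data therefore validate the statistical machinery and
the bookkeeping, not robustness to upstream alignment or calling noise —
those live upstream of this package's inputs (it consumes variant calls,
not reads).

For the window-selection benchmark specifically,
`simulate_window_benchmark()` plants the geometry that bounds the chosen
window: each strongly edited site has a motif instance ending exactly
`inner = 15` bp away, and each weakly edited background site flanks a
motif at edge distance `outer = 18` bp. Enrichment is then significant
precisely for half-widths below `outer`, so the selected width should fall
in `[inner, inner + motif length]`.

## Pipeline, determinism, and problem sizes

`run_pipeline()` composes the stages (filter → assemble → test → FDR →
targets → window selection/clustering/distances) from a validated YAML or
list config (`validate_config()`), writes per-stage artifacts and a JSON
report, and halts with the stage name on failure. Every simulation-facing
function takes an explicit seed; deterministic stages reproduce byte-for-
byte under a fixed seed.

The test suite and the acceptance script run their statistical checks at
these sizes, chosen to make Monte-Carlo error small relative to the
tolerances being checked: 10,000 sites for null calibration (20 libraries
per group), a 5 × 3 $(\mu, \rho)$ grid × 20 replicates for parameter
recovery, the full 500-gene default scenario for end-to-end target
recovery, and 20 seeded replicates for window selection.

## Known limitations

* The chi-square(1) reference is anticonservative at 2–4 replicates per
  group (see calibration above); interpret raw p-values at study scale
  through the FDR + effect-size filters, as the target-calling rules do.
* Gene assignment takes the highest-priority region over all isoforms;
  genuinely ambiguous dual-strand sites are resolved toward sensitivity.
* The motif model is a single PWM; no de novo discovery is attempted (the
  upstream tool's PWM is an input), and no E-value statistics are
  computed.
* fpkm filtering uses whatever expression table is supplied; whether that
  table comes from control or fusion libraries is the caller's choice
  (control libraries recommended, as expression of the profiled cells).
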