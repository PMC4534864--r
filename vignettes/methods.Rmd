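---
title: "Methods: quantifying micropropagation-induced methylation change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying micropropagation-induced methylation change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epifidelity)
```

## The scientific problem

Clonal crops such as cassava are multiplied either by field cuttings or by
*in vitro* meristem culture.  Meristem culture is usually assumed to be
epigenetically faithful because it regenerates pre-existing meristems, yet
culture conditions (high humidity, exogenous sugars, growth regulators, low
light) are a sustained stress, and stress reshapes DNA methylation.
`epifidelity` implements two complementary assays for detecting
propagation-system methylation differences across several varieties,
tissues and replicates:

* **MSAP track** — methylation-sensitive amplified polymorphism.  Genomic
  DNA is restricted in parallel with the isoschizomers *Hpa*II and *Msp*I,
  which both cut unmethylated `CCGG` but respond differently to cytosine
  methylation.  Fragment presence/absence across samples becomes a binary
  epilocus matrix analysed with distance-based AMOVA (PhiPT), PCoA and
  fixed-difference diagnostic markers; fragment peak heights become a
  quantitative matrix analysed with count statistics.
* **msGBS track** — methylation-sensitive genotyping-by-sequencing.
  Reduced-representation reads anchored at *Msp*I cut sites are
  demultiplexed by exact barcode, collapsed to 64-mer tags, filtered, and
  tested per variety for differential abundance between propagation
  systems; tags responding in the same direction in most varieties are
  called micropropagation-induced DMRs and annotated against gene models.

## Isoschizomer logic

For a `CCGG` site, presence calls from the two enzymes map to a methylation
state:

| HpaII | MspI | state |
|---|---|---|
| 1 | 1 | unmethylated |
| 0 | 1 | internal cytosine methylated (CmCGG) |
| 1 | 0 | hemimethylated external cytosine (mCCGG) |
| 0 | 0 | hypermethylated or fragment absent (uninterpretable) |

`call_methylation_state()` implements exactly this table.  Because the
(0,0) class is ambiguous, group-level inference never relies on a single
state: a marker polymorphic between groups in only one enzyme can only be
epigenetic (`classify_marker_origin()`), while polymorphism in both enzymes
may be genetic or epigenetic.

## MSAP scoring

Peaks are clustered into loci per enzyme by single linkage with a gap
tolerance (default 0.5 bp): two peaks from the *same* sample never share a
bin — the taller keeps the bin and the other seeds the next one — because
one sample cannot contribute two alleles of identical size.  Binary
scoring keeps bins whose center lies in the closed window [100, 580] bp
(size homoplasy grows outside it); peak-height analysis uses [50, 550] bp
and removes epiloci whose intensity across all samples falls below a
configurable low filter (`mean` or `total`; the filter threshold used by
the original instrument software is not recoverable, so it is exposed
rather than fixed).  Both windows are treated as inclusive at the bounds.
The default presence threshold is "any peak with height > 0"; real
chromatogram noise floors can be set through `presence_threshold`.

## PhiPT, AMOVA and PCoA

For binary profiles the squared Euclidean distance between two samples is
the number of differing loci.  The total sum of squared distances is
partitioned into among- and within-group components,

$$SSD_{tot} = \frac{1}{N}\sum_{i<j} d_{ij}, \qquad
  SSD_{w} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij},$$

with $MS_a = (SSD_{tot}-SSD_w)/(k-1)$, $MS_w = SSD_w/(N-k)$, the
unequal-size coefficient $n_0 = (N - \sum_g n_g^2/N)/(k-1)$, and

$$\Phi_{PT} = \frac{V_a}{V_a + V_w}, \qquad
  V_a = \max\!\left(0, \frac{MS_a - MS_w}{n_0}\right),\ V_w = MS_w.$$

Negative among-group components are truncated at zero before the ratio,
and the degenerate case $V_a + V_w = 0$ (all samples identical) is defined
as $\Phi_{PT} = 0$.  Significance comes from permuting group labels:
sampled permutations use the add-one estimator $(b+1)/(n_{perm}+1)$; when
the two-group label assignments number at most `n_perm` (e.g. 20 for a
3-vs-3 contrast) they are enumerated exhaustively and the p-value is the
exact tail fraction.  The default `n_perm = 999` balances resolution
(p down to 0.001) against runtime.  Pairwise contrasts (condition within
cultivar, tissue pairs within condition) are computed by subsetting to the
two groups rather than from a global model, and missing design cells are
dropped listwise per comparison.

PCoA embeds the squared-distance matrix by Gower double-centering of
$-\tfrac12 d$ and eigendecomposition (delegated to `stats::cmdscale` on
the unsquared distances); axes with negative eigenvalues are reported but
dropped from the coordinates, and explained proportions are relative to
the positive-eigenvalue total.

## Count statistics (quantitative MSAP and msGBS)

Both quantitative tracks share one negative-binomial engine, written from
the underlying definitions:

* **TMM normalization** (`tmm_factors()`): the reference sample is the one
  whose 75th count-proportion percentile is closest to the mean; per
  sample, M-values (log2 depth-normalized ratios) and A-values are doubly
  trimmed (30 % / 5 %, the published defaults of the weighted trimmed-mean
  method) and averaged with inverse asymptotic-binomial-variance weights;
  factors are anchored to a unit geometric mean.  Exact library rescaling
  cancels in M and A but slightly reshuffles the precision weights, so
  scale invariance holds closely rather than to machine precision.
* **Quantile-adjusted conditional likelihood**: effective library sizes
  are equalized to their geometric mean by mapping each count through the
  mid-P CDF of its fitted NB to the matching quantile of the common-size
  NB, interpolating linearly between integer knots (identical input and
  output laws map a count exactly to itself).  The common dispersion
  maximizes the conditional (given group totals) log-likelihood summed
  over tags, searched on the log scale in $[10^{-6}, 10]$, iterating the
  pseudo-count/estimate pair twice from a working value of 0.01.
* **Tagwise empirical Bayes** (`tagwise_dispersion()`): each tag maximizes
  its own conditional log-likelihood plus `prior_n` (default 10) times the
  average per-tag log-likelihood curve, shrinking toward the common value;
  `prior_n = 0` recovers per-tag conditional MLEs and very large values
  collapse onto the common estimate.
* **Exact test** (`exact_test()`): conditional on the total pseudo-count
  $t$, the group-1 sum follows a negative hypergeometric (the NB
  convolution given the total), enumerated over $0..t$; the two-sided
  p-value is the minimum-likelihood sum with ties included at $10^{-12}$
  relative tolerance, with no doubling.  At dispersion 0 this is the exact
  binomial test.  Fold changes use normalized group means with a prior
  count of 0.125 per observation so zero counts stay finite.
* **BH FDR** (`bh_fdr()`): the step-up procedure via `stats::p.adjust`.

Peak heights are not integers; they are rounded before entering the NB
machinery, mirroring how fluorescence intensities are treated as counts.
This is an approximation: the NB is a model of convenience for
overdispersed non-negative intensities, not a generative claim.

## DMR consensus calling

Per variety (tissues pooled within condition), the engine runs TMM →
common + tagwise dispersion → exact test → BH within variety.  A tag is a
**consensus DMR** when (a) it is significant (q < 0.05) with the same
phase — direction of abundance change — in at least 4 of 5 varieties, (b)
no variety is significant with the opposite phase, and (c) it was observed
in every variety.  Rule (c) operationalizes the exclusion of
variety-specific sequence variants: true SNP detection between varieties
is not reconstructable from tag data alone, so presence in all varieties
is used as the practical surrogate.  The 4-of-5 default, together with the
strict no-opposite-phase rule, resolves the tension between "at least four
varieties" and "phase conserved across all genotypes": a tag may be
non-significant in one variety, but never discordant.  BH within variety
(rather than globally) matches per-variety reporting of significant
counts; both choices are exposed as arguments.

## msGBS read handling

A read is kept iff it starts with an exact sample barcode immediately
followed by the `CGG` remnant that *Msp*I digestion leaves; the barcode is
removed and the remainder truncated to 64 nt, so every tag carries the CGG
at its 5' end (the trimming convention is configurable).  Reads shorter
than 64 nt after the barcode are rejected rather than padded, avoiding
phantom tags.  No mismatches are tolerated anywhere, and barcode maps in
which one barcode prefixes another are rejected at load since exact-prefix
assignment would be ambiguous.  Tags seen in the negative water control
are removed, then tags present in fewer than three distinct samples
(inclusive bound), then the control column; the filter order is
configurable because the original order is not documented.  Rejection
counts (`bad_barcode`, `bad_cutsite`, `too_short`) always sum with the
retained count to the input count.

## Annotation

Consensus tags are located on the genome by exact matching of the 64-mer
and its reverse complement — at this length an exact hit is the stringent
end of a nucleotide BLAST, and users with their own alignments can supply
an external hit table.  Gene-model classification uses 0-based half-open
arithmetic internally (GFF3's 1-based inclusive coordinates are converted
on input): exon overlap beats intron, which beats the strand-aware 5 kb
flanks (inclusive at exactly 5000 bp from the TSS upstream or the TTS
downstream), and anything else is intergenic.  Among qualifying genes the
nearest wins, ties breaking by smaller distance then lexicographic gene
id.

## The synthetic experiment

`sim_config()` encodes the study design: 5 varieties × 2 propagation
systems × 3 tissues × 3 replicates, with one field mature-leaf cell of one
variety removed by default (87 samples) to exercise missing-data paths —
the published design had 86 of 90 samples but the identity of the missing
cells is not recoverable, so `missing_cells` is a parameter.  Defaults for
the msGBS track are 2,000 tags, 40 planted phase-consistent DMRs at |log2
fold change| 3, NB dispersion 0.2, and 50,000–100,000 expected reads per
sample (roughly 25–50 reads per tag — a desk-scale stand-in for the much
deeper published libraries chosen so that per-tag testing is neither
saturated nor hopeless).  MSAP defaults are 160 loci, 30
condition-responsive and 20 tissue-responsive, lognormal peak heights
(sdlog 0.4) and a 2 % amplification drop-out.

The generators record complete ground truth (states, phases, planted
genomic intervals, contaminant counts), and "absent" MSAP peaks emit no
record at all rather than low noise, keeping binary scoring unambiguous.
What the simulation does **not** emulate: sequencing errors inside the tag
body, adapter artefacts and chimeras, sizing drift between capillary runs,
correlated biological replicates, and genuine genetic polymorphism between
varieties.  Passing tests therefore demonstrate that the statistical
machinery is correct and powerful under its own model, not that real
libraries are free of those artefacts.

## Numerical choices and problem sizes

* Dispersion search bounded in $[10^{-6}, 10]$ on the log scale; flat or
  boundary likelihoods return the lower bound.
* The tagwise shared-likelihood curve is evaluated on an 81-point log
  grid and interpolated with a spline before per-tag optimization.
* Exact-test enumeration is linear in the total pseudo-count, which at
  the default simulated depth stays in the hundreds per tag.
* Verification sizes: AMOVA equals a brute-force oracle on random
  fixtures of up to 8 samples with exhaustively enumerated permutation
  p-values; the exact test matches a direct enumeration oracle for totals
  up to 200 and the exact binomial at dispersion 0; type-I error is
  checked on a 2,000-tag null at 3 vs 3; dispersion recovery at true
  values 0.05 and 0.2 (2,000 tags, 6 + 6) against bands of three
  empirical standard deviations; the end-to-end consensus experiment runs
  the full per-variety pipeline over 20 seeds at the default design and
  requires recall ≥ 0.9 and empirical false-discovery proportion ≤ 0.10.

## A compact worked run

```{r, eval = FALSE}
cfg <- pipeline_config(sim = sim_config(n_tags = 300, n_true_dmrs = 12,
                                        lib_size_range = c(15000, 25000),
                                        seed = 42))
tc <- simulate_tag_counts(cfg$sim)
track <- run_gbs_track(cfg, counts = tc$counts, metadata = tc$metadata)
track$summary                      # per-variety differential counts
sum(track$dmrs$consensus)          # consensus DMR calls
mean(tc$truth$true_dmr_ids %in% track$dmrs$tag[track$dmrs$consensus])
```

## Known limitations

* Exact matching cannot place tags containing real polymorphisms; the
  external-hit-table adapter exists for that reason.
* The NB treatment of peak heights ignores the continuous,
  heteroscedastic nature of fluorescence.
* PhiPT inherits the usual caveats of fixation-style indices on dominant
  (presence/absence) markers; it is a descriptive effect size, with
  inference carried entirely by the permutation test.
* Consensus calling assumes tissues can be pooled within condition; a
  tissue-stratified contrast is out of scope.
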