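---
title: "Genotype smoothing and phylogenetic evaluation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype smoothing and phylogenetic evaluation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `cellphylo`, the
parameters that matter, the choices made where the design was genuinely
open, and what the synthetic-data tests do and do not demonstrate.

## The beta-binomial genotype model

At a biallelic SNV in one cell we observe `r` reference and `a` alternate
reads. Treating each read as a Bernoulli draw with unknown alternate-allele
frequency *p*, the posterior of *p* under a uniform prior is
Beta(*a*+1, *r*+1). Genotypes correspond to regions of the frequency axis:
a homozygous-reference genotype produces alternate reads only through
technical noise, so its frequency lies in [0, θ); a homozygous-alternate
in (1−θ, 1]; a heterozygote in between. The genotype probabilities are the
posterior masses of these regions, computed with the regularized incomplete
beta function (`pbeta`), never by numeric quadrature — quadrature is used
only as the independent oracle in the test suite.

**θ (noise threshold, default 0.3, unitless, must lie in (0, 0.5)).**
θ encodes how many wrong-allele reads we tolerate before doubting a
homozygous genotype. It is global: per-site noise estimation is out of
scope. Its most visible consequence is the dropout prior: a zero-read
element gets (θ, 1−2θ, θ) = (0.3, 0.4, 0.3), and a single-read element can
never be called heterozygous (its H mass, 0.40, is always beaten by the
homozygous state on the side of the observed read, 0.51).

**Tie-breaking.** Exact probability ties are broken by the fixed precedence
H > R > A. A tie means the reads cannot separate the states; the
heterozygous call is the conservative middle ground, and determinism
matters more than the (measure-zero) choice itself.

## Smoothing across neighbouring cells

Most elements have 0–1 reads, so per-cell calls are unreliable. The
pipeline borrows information from genotypically similar cells:

1. **Profile sampling.** For each of `n_samplings` (default 100)
   iterations, one genotype per element is drawn from its (R, H, A)
   distribution. One profile is drawn per cell per iteration and shared
   across all pairs. The per-pair formulation — independent draws for every
   pair — has the same expectation but is quadratically more expensive;
   the shared-draw design reduces the whole step to three matrix
   cross-products per iteration.
2. **Similarity.** The score of a cell pair is the fraction of sites with
   equal sampled genotypes, averaged over iterations — a simple matching
   coefficient over sites (the quantity is sometimes loosely called a
   Jaccard index; we implement the "fraction of sites agreeing"
   definition literally). Dropout elements participate through their
   prior: similarity is defined over all sites, not only covered ones,
   which slightly shrinks all scores toward the chance level but keeps the
   score comparable across pairs with different coverage.
3. **kNN.** Each cell's K (default 10) highest-scoring other cells, ties
   broken by ascending cell index. The neighbour relation is directed and
   never symmetrized. K should stay below the size of the smallest clade
   of interest.
4. **Smoothing.** p̂ = (1−δ)·own + δ·(neighbour mean), with
   δ = K/(K+1) by default, which makes the smoothed distribution exactly
   the plain average of the cell with its K neighbours (an algebraic
   identity the tests assert). Smoothing is a convex combination, so
   probability triples stay on the simplex.

Similarity is computed on the post-coarse-filter site set, before the
top-N coverage cap: the coarse filters remove sites whose calls carry no
information (monomorphic, under-covered), which would otherwise dilute the
similarity signal.

## Site and cell filters

Filters run in a fixed order: pseudobulk candidate-variant support (total
≥ 20 reads, alternate ≥ 5 reads and ≥ 5% of total), per-cell coverage
(≥ 10,000 reads; boundary literal: exactly 10,000 is kept), coarse site
filters, then smoothing, then the top-1000-by-coverage cap. Choices made
where the published order of operations left room:

* The per-site coverage floor is interpreted as *total reads per site
  across cells* < 10 (lenient preset: 5), exposed as `min_site_reads`.
* The monomorphic fraction (default 0.90; lenient 0.80; subclone preset
  0.95) is computed on unsmoothed argmax calls among *covered* cells only —
  dropout cells say nothing about a site's informativeness. The boundary
  is strict: exactly 90% is kept, anything above is removed.
* The spacing filter removes *every* member of a cluster of sites within
  5 nt on the same chromosome, using |Δpos| ≤ 5 (configurable); clustered
  sites tend to reflect alignment artifacts rather than independent
  variants.
* Chromosome names are normalized ("chr1" ≡ "1"); only autosomes 1–22
  are kept by default, since sex chromosomes violate the diploid
  heterozygote model.

All filters are idempotent, and the presets (`default`, `lenient`,
`subclone`) bundle the documented threshold combinations.

## Sequence encoding and the fallback tree

Calls are encoded one site per column: R → reference base, A → alternate
base, H → the first base in the fixed order A < C < G < T that is neither —
a deterministic stand-in for an "arbitrary third base" that keeps the
encoding injective per site and the output byte-reproducible. MISSING
(unsmoothed mode only) encodes as N. The intended downstream engine is a
Bayesian sampler consuming the FASTA/NEXUS (a JSON sidecar records the
intended model: relaxed log-normal clock, GTR, Yule prior, ≥ 1e8 MCMC
iterations); that engine is external by design.

For self-contained evaluation the package builds a neighbour-joining tree
from N-masked Hamming distances, clamps negative branch lengths to zero
and midpoint-roots it. This fallback is a deterministic point estimate:
it lets every downstream statistic run at desk scale, but its branch
lengths are not calibrated times, and signal magnitudes computed on it are
comparable only across runs of the same harness, not with values from
posterior tree summaries.

## Evaluation statistics

**Pagel's λ** rescales the off-diagonal of the Brownian-motion covariance
C (shared root-to-MRCA path lengths). μ and σ² are profiled out
analytically; λ is optimized on [0, λ_max] with
λ_max = max(diag C)/max(offdiag C), which deliberately admits estimates
above 1. That bound does not by itself keep C(λ) positive definite on
non-ultrametric trees; the likelihood treats non-PD covariances as −∞
(Cholesky failure), so the effective search region is the PD frontier.
Significance is a likelihood-ratio test against λ = 0 on one degree of
freedom — the test construction is this package's convention, chosen for
its simplicity and calibration, not a claim about any particular earlier
implementation. Binary lineage labels are coded 0/1 and treated as
continuous; this mirrors common practice but is an approximation (a
threshold model would be the rigorous treatment) and is flagged as a
limitation.

**Blomberg's K** is the observed-to-Brownian-expected MSE ratio about the
phylogenetically corrected mean. On trees with clamped zero-length
branches C can be exactly singular (identical tips); a 1e-8 ridge keeps
the statistic defined there. On an equal-branch star tree K equals 1
exactly for any trait, which the tests use as a closed-form anchor.

**SES MPD** compares each group's mean pairwise cophenetic distance
against a null of tip-label permutations with group sizes fixed
(`picante::ses.mpd`, `taxa.labels` null, 999 permutations by default).
Negative z means phylogenetic clustering. A group containing every tip is
permutation-invariant; its z is defined as 0.

**Adjusted Rand index** uses the standard pair-counting chance correction
(`mclust`), verified in the tests against explicit pair enumeration.
Multiple-testing across traits uses Benjamini–Hochberg.

## The synthetic-data generator

The simulator emulates the post-variant-calling input of the pipeline:

* **Clades.** Cells are split into clades in configured proportions
  (default two clades, 50/50). The true tree is a balanced clade tree
  (star subtrees joined by unit internal branches) — sufficient for the
  signal statistics, and a declared simplification.
* **Genotypes.** A fraction of sites (default 0.1) carry a subclonal
  mutation: carrier clades are heterozygous, everyone else homozygous
  reference. This is the biologically typical configuration of a somatic
  point mutation in a diploid genome, and it is what makes the problem
  hard at low coverage: a single read cannot reveal a heterozygote, so
  clade structure is nearly invisible in unsmoothed calls. The remaining
  sites share one germline genotype across all cells (55% R / 25% H /
  20% A).
* **Coverage.** Total reads per element are negative-binomial
  (dispersion 0.5) with per-site log-normal means (sdlog 1), emulating
  expression-driven uneven coverage; dropout arises from low means, not a
  separate zero-inflation knob. Per-site means are rescaled so the
  expected zero fraction matches `target_sparsity` (default 0.65, the
  regime of a typical droplet genotyping matrix after site discovery);
  `target_sparsity = NA` skips the calibration for high-coverage limiting
  cases.
* **Reads.** Alternate reads are binomial with success probability ε for
  true R, 0.5 for true H, 1−ε for true A (sequencing error ε, default
  0.05).

What passing tests on this generator show: the pipeline's stages compose
correctly, smoothing recovers clade structure that unsmoothed calls miss,
and signal degrades in the expected directions under sparsity, call
corruption and shrinking subclones. What they do not show: performance on
real data, where allele-specific expression, RNA editing, alignment
artifacts, doublets and copy-number variation all violate the generative
model, and where the variant list itself is noisy.

## Robustness harness

`run_robustness_sweep()` stresses one factor at a time: neighbour count K,
number of selected sites, added sparsity (random zeroing of nonzero
elements), fraction of corrupted genotypes, and subclone frequency
(spiking a minor population into a major one at constant total cell
count). Corruption is injected *upstream of smoothing* at the probability
level (`flip_probabilities()` swaps the argmax mass of an element with a
random other genotype): moderate error rates are then absorbed by the
neighbourhood averaging while severe ones corrupt the neighbour graph
itself, which is the failure mode of interest. Injecting the same errors
*downstream* of smoothing instead produces trees whose shape changes so
much that λ magnitudes are no longer comparable across grid points (tip
depths grow, λ_max explodes), which is why the call-level
`flip_genotype_calls()` exists as a primitive but is not how the sweep
degrades data.

Clade-recovery clustering uses Ward linkage on the N-masked Hamming
distances; average linkage proved degenerate (chaining) on these
plateau-heavy distance matrices.

## Problem sizes and determinism

The test suite runs the full study conditions where they are cheap (the
smoothing-improvement experiment uses ten replicates of 400 cells × 500
sites at 65% sparsity; λ recovery uses 50 Brownian simulations on a
100-tip tree; SES MPD calibration uses 999 permutations) and reduced grids
for the sweep directions (two grid points per factor). Every stochastic
stage takes an explicit integer seed and is bit-reproducible given it; the
CLI writes a JSON run log (parameters, seed, config hash, package version)
next to each artifact.

## Known limitations

* The beta-binomial model ignores allele-specific expression and
  strand bias; θ is global.
* Binary traits are treated as continuous for λ.
* The NJ fallback is not a posterior summary; magnitudes of tree-based
  statistics are harness-internal.
* The simulator's balanced clade tree and independent-sites assumption
  understate real phylogenetic complexity (no nested subclones, no linked
  sites).
* The VCF reader accepts only biallelic SNVs; indels and multi-allelic
  records are counted and skipped.
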