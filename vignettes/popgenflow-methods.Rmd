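---
title: "Methods: divergence, gene flow and selection scans with PopGenFlow"
author: "PopGenFlow maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence, gene flow and selection scans with PopGenFlow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

PopGenFlow implements the downstream-of-VCF inference chain used in
resequencing studies of closely related plant lineages — for example a
species complex of wild and cultivated hazelnuts sampled across contrasting
habitats. This vignette documents the statistical models, the tunable
parameters, the synthetic-data generator that stands in for real
resequencing data, and the numerical and design choices a maintainer should
know about.

## The data model

The central object is the `VariantMatrix`: biallelic SNPs as a samples x
sites matrix of alternate-allele dosages (0/1/2, `NA` for a missing call)
with per-site chromosome, position, alleles and optional mean depth.
`readVcfMatrix()` builds it from a VCF (via vcfR), keeping only biallelic
single-nucleotide records; `writeVcfMatrix()` serializes back to VCF v4.2
and round-trips exactly. Coordinates are 1-based inclusive throughout and
interval work is delegated to GenomicRanges/IRanges, the native convention
of the Bioconductor stack this package is built on.

## Variant QC, LD pruning and effect classification

`filterVariants()` retains sites with minor allele frequency >= `min_maf`
(default 0.05, computed on non-missing allele copies), missing fraction <=
`max_missing` (default 0.20) and, when depth is present, mean depth within
`[1/3, 2]` times the across-site mean. The filter is idempotent, and
all-missing sites are dropped with a logged count.

`ldPrune()` mirrors the common `indep-pairwise 50 10 0.2` protocol: sliding
windows of 50 SNPs advanced by 10, removing the later member of any pair
with genotype-dosage r^2 above 0.2. Because the external tools leave the
exact removal order unstated, the rule here is fixed and documented: pairs
are scanned left to right within a window, windows are re-laid over the
surviving site sequence, and passes repeat until no removal occurs — which
guarantees that no within-window pair of the output exceeds the threshold.

`classifySnpEffects()` assigns each SNP exactly one class using the
most-severe rule across overlapping transcripts (stop_gain > stop_lost >
nonsynonymous > splice_site > synonymous > intronic > upstream/downstream >
intergenic). Coding changes are evaluated by splicing the CDS from the
genome, substituting the alternate base (reverse-complemented on minus
strands) and translating through the standard genetic code. Untranslated
gene-body positions (introns, non-coding exon parts) fall back to the
intronic class; upstream/downstream extend 5 kb from gene boundaries and
splice sites are the first/last 2 intronic bases — conventional values, both
overridable. Transcripts whose phase-adjusted CDS length is not a multiple
of three are skipped with a warning.

## Diversity, differentiation and LD decay

Per-site nucleotide diversity is the unbiased estimator
$\pi_s = 2 j (m - j) / (m (m - 1))$ for $j$ alternate copies among $m$
non-missing copies; window values sum $\pi_s$ and divide by the window span
in bp (100 kb windows, 10 kb steps by default). Normalizing by span rather
than by accessible sites matches the per-bp convention of the standard
windowed tools; the choice matters only where accessibility varies.

$F_{ST}$ is Weir & Cockerham's (1984) estimator from the per-site variance
components $a$ (among populations), $b$ (among individuals) and $c$ (within
individuals), aggregated per window as a ratio of sums
$\sum a / \sum (a+b+c)$. Raw values are reported without clamping at zero:
empirical top-quantile thresholds downstream operate on the raw
distribution, and clamping would distort them.

`ldDecay()` computes r^2 as the squared Pearson correlation of dosage over
pairwise-complete samples for all intra-chromosomal pairs up to 500 kb,
after an in-population MAF >= 0.05 / missing <= 0.2 screen. Binned means
(100 bp bins) are made monotone non-increasing by an isotonic fit before
the half-decay distance — the smallest distance at which the curve falls to
half its maximum — is read off; the smoothing prevents noise-induced early
crossings, and ties at exactly half the maximum resolve to the earlier
distance.

## ABBA-BABA and f4-ratio

For the fixed topology (((P1,P2)P3)O), sites are polarized by the outgroup
consensus; outgroup-polymorphic or missing sites are dropped. With derived
frequencies $p_1, p_2, p_3$,
$ABBA = \sum (1-p_1) p_2 p_3$, $BABA = \sum p_1 (1-p_2) p_3$ and
$D = (ABBA - BABA)/(ABBA + BABA)$ — the frequency-weighted form used by the
standard tooling. Significance comes from a delete-one block jackknife over
1-Mb physical blocks ($Z = D/SE$, two-sided normal p); fewer than 20
non-empty blocks draws an instability warning. The f4-ratio splits the P3
sample into two halves (first/second half in sample order, deterministic)
and estimates the admixture fraction as
$f_4(P3_a, O; P2, P1) / f_4(P3_a, O; P3_b, P1)$. On pulse-admixture
simulations this is mildly attenuated by the donor drift accrued after the
pulse; with recent pulses the bias is far below the sampling noise at the
problem sizes used here.

## Folded-SFS demographic inference

`buildFoldedSfs()` tallies complete-case sites into the joint
minor-allele-count spectrum, folded by the total minor allele; ties at
exactly half the copies resolve to the lexicographically smaller
configuration, fixed cells are masked, and both the observed and expected
spectra use the same convention, which is all the composite likelihood
requires.

The expected spectrum under a model is estimated by Monte Carlo: a
structured-coalescent engine (Rcpp) simulates seeded replicates under a
piecewise-constant demography — epochs with per-deme relative sizes,
backward migration rates in the `2 Nref m` convention, and end-of-epoch
lineage moves encoding population joins or admixture pulses — and averages
the branch length subtending each descendant configuration. Time is in
units of `2 Nref` generations; the expectation is scaled so that cell
counts are `theta` times the returned value, with
`theta = 4 Nref mu L`. The Monte-Carlo route replaces the diffusion PDE of
the classical tool; its accuracy is validated against the analytic
single-population spectrum ($E[\xi_i] \propto 1/i$, folded: proportions
8/11 and 3/11 at n = 4) in the test suite.

The objective is the Poisson composite log-likelihood
$\sum_c [o_c \ln(\theta e_c) - \theta e_c - \ln o_c!]$ over unmasked cells,
with `theta` profiled analytically ($\hat\theta = \sum o / \sum e$), so it
never enters the simplex; AIC counts the simplex parameters plus one for
`theta`. Expectation cells that are zero where the observation is positive
are floored at a configurable epsilon (default 1e-8) with a warning.

`fitModel()` runs multi-start Nelder-Mead on log-parameters (box bounds via
clamping with a penalty): each start multiplies the model defaults by
independent log-uniform factors in [1/3, 3] and runs at most `maxiter`
simplex iterations. The widely used protocol of 50 perturbed starts capped at 20 iterations
is honored as the default, but 20 iterations cannot converge in five or
more dimensions, so `maxiter` is an explicit argument and the package's own
experiments use 40-80. All evaluations share one simulation seed (common
random numbers), making the objective deterministic given `seed`.

Two numerical facts matter when comparing models. First, the Monte-Carlo
log-likelihood carries a seed- and replicate-count-dependent offset, so
`rescoreFit()` re-evaluates every candidate at its optimum on one shared
high-replicate expectation before `selectModel()` ranks by AIC (ties:
fewer parameters, then model id). Second, a practical fitting protocol uses
two rounds — a broad multi-start search followed by a narrow re-perturbation
around the incumbent — exactly as users of the diffusion-based tools do.

The model registry ships 17 named configurations over the five scenario
families (divergence with gene flow 1-4, ancient migration 5-7, secondary
contact 8-10, simultaneous split 11-14, hybrid origin 15-17). There is no
canonical parameter table for such a menu, so the registry's exact
parameterizations are this package's own: within each family the
configurations vary migration symmetry and epoch structure, split times are
parameterized as `T2` and `dT = T1 - T2` so nesting holds by construction,
and epoch boundaries of the ancient-migration/secondary-contact families
sit at `tfrac * T2`. The flagship secondary-contact configuration
(`m09_sc_adjacent_sym`: constant symmetric sister-pair flow, recent
adjacent contact, its own isolated-ancestor size) carries 7 simplex
parameters + profiled theta, i.e. k = 8. `convertUnits()` maps fits to
physical units via `Nref = theta / (4 mu L)` with the conventional
mutation rate 3.75e-8 per bp per generation and a 15-year generation time
as defaults for hazelnut-like trees, and reports migration both in `2 Nref m`
units and as the per-generation replacement fraction `m / (2 Nref)`.

## Selective-sweep calling

`xpclrScan()` is a simplified cross-population composite-likelihood scan.
At each grid point (100-bp steps by default; coarser grids are used in the
package's experiments purely for speed) the object-population allele counts
in a 0.05-cM window (at most 200 SNPs, nearest first; fewer than 5 gives a
missing score) are modelled either as neutral drift — count $k \sim$
Binomial$(n, q)$ with $q$ truncated-normal around the reference frequency
with variance $\omega p (1-p)$, $\omega$ estimated genome-wide by moments —
or as a sweep centred at the grid point: a SNP at genetic distance $d$
escapes with probability $c = 1 - e^{-d/\lambda}$ and otherwise rides the
swept haplotype to a boundary frequency (default 0.05 from the edge, since
sampled hard sweeps rarely hit exact fixation). The score is twice the
composite log-likelihood gain maximized over a small grid of sweep scales
$\lambda$, non-negative by construction. The original XP-CLR's LD-based SNP
down-weighting is deliberately omitted; the variant is validated by
planted-sweep power and neutral quietness, not by score equality with the
original implementation. The genetic map is uniform `cm_per_mb` (default 1)
unless a per-chromosome scale is supplied — ranking, and hence empirical
quantiles, are unaffected by the overall scale.

`callSweeps()` reconciles the three metrics on one grid: windowed FST,
ln(pi_ref/pi_obj), and the scan reduced to the window grid by
max-within-window. Each metric is thresholded at its empirical 95th
percentile (type-7 quantile, missing values excluded); windows flagged by
all three are merged (gap 0 bp) into maximal regions, and
`regionsToGenes()` reports genes overlapping a region by >= 1 bp.

## Niche overlap

`schoenerD()` and `hellingerI()` compare suitability rasters after joint
renormalization over the shared valid mask:
$D = 1 - \tfrac12 \sum |a - b|$ and $I = 1 - \tfrac12 \sum (\sqrt a -
\sqrt b)^2$, both in [0, 1] with 1 iff identical and 0 for disjoint
supports. The identity test pools the two species' occurrences, re-splits
them at random preserving sample sizes, and recomputes both statistics;
one-sided p-values carry the add-one correction, so they are never zero.
The suitability model is pluggable; the default is a Gaussian kernel
density in a fixed 2-D environmental projection. It deliberately replaces
maximum-entropy niche modelling, so observed D/I values are calibrated
against their own permutation null rather than compared with values
produced by MaxEnt surfaces. `pruneEnvCorrelated()` reproduces the standard
|r| > 0.75 redundancy screen with a documented greedy order (input order).

## The synthetic-data generator

`simulateGenotypes()` tiles a chromosome with independent non-recombining
loci (2 kb by default) and simulates each locus' genealogy under the full
structured demography, dropping infinite-sites mutations at
`theta_site / 2` per branch per unit time. This emulates a recombining
genome by inter-locus independence with complete intra-locus linkage: LD
therefore decays as a step at the locus scale rather than smoothly, window
statistics behave like averages of ~50 independent genealogies per 100-kb
window, and no intra-locus recombination events exist. Consequences worth
keeping in mind: LD half-decay distances from these simulations reflect the
locus length, not a recombination rate; and sweep scans see slightly
blockier background structure than real data. Everything downstream —
frequency spectra, D statistics, FST, window quantiles — depends only on
genealogy distributions that the tiled design reproduces correctly.

`plantSweep()` converts a random donor's genotypes in the region into a
pseudo-haplotype (seeded random phase at heterozygous sites) and makes a
`final_freq` fraction of the target population homozygous for it — the
footprint of a completed hard sweep without simulating selection forward in
time. `makeToyGenome()` writes a FASTA/GFF3 pair whose coding sequences are
built codon-wise (TGC repeats closed by TGA) so that each placed SNP's
effect class is known by construction, independent of any translation code
— the generator is the oracle for the classifier. `makeNicheFixture()`
draws two species' occurrences from environment-space Gaussians separated
by a controllable distance.

Default study conditions used across the package's experiments:
`theta_site = 0.003` (matching per-bp diversities of a few per thousand as
seen in outcrossing trees), 15-30 diploids per population, window grids of
100 kb / 10 kb, jackknife blocks of 0.1-1 Mb sized to keep >= 20 blocks,
and SFS sample sizes of 8 allele copies per population with spectra of
~120-150k SNPs. Simulated chromosome lengths (1-5 Mb per replicate, 20 Mb
of neutral sequence for false-positive rates) were chosen once as the
smallest sizes at which the targeted properties are statistically
meaningful.

## Numerical choices and degenerate inputs

- Quantiles are type-7 throughout; a degenerate (all-equal) score
  distribution flags everything with a warning rather than failing.
- The fold of the SFS resolves half-total ties lexicographically; the same
  rule is applied to data and expectation.
- `ldPrune` and `pruneEnvCorrelated` fix their greedy orders explicitly
  because the tools they mirror leave them unstated.
- Windows at chromosome ends are truncated and normalized by their actual
  span; windows below `min_sites` informative sites are `NA`, and `NA`
  windows propagate through ln pi-ratio and thresholding without being
  counted.
- Empty intersections, zero-SNP sweep regions, all-missing sites, zero
  biallelic records and zero-mutation simulations all return empty results
  with warnings, not errors.
- Stage summaries (`runStage()`) contain only deterministic content; timing
  goes to the message stream so seeded reruns are byte-identical.

## Known limitations

- No intra-locus recombination in the generator (see above); haplotype
  phase is neither simulated nor used.
- The XP-CLR variant's absolute scores are not comparable to the original
  implementation's; only ranks and empirical quantiles are used.
- The f4-ratio is the textbook estimator; normalizations that some
  downstream tools layer on top of it are out of scope.
- Monte-Carlo expected spectra make absolute log-likelihoods
  seed-dependent; always compare models through `rescoreFit()` on a common
  evaluation, and treat AIC differences smaller than the rescoring noise
  (a few units at 50k replicates) as ties.
- The identity test's observed D/I depend on the kernel-density suitability
  stand-in and are not comparable to values from maximum-entropy models;
  only the permutation calibration carries over.
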