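---
title: "Mapping a recessive dwarfing locus: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive dwarfing locus: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsarna)
```

# The problem

A dwarf, compact rapeseed line is crossed to a normal-architecture line and
the F1 is backcrossed to the dwarf (recurrent) parent for eight
generations, giving a BC~8~ population in which the genome is almost
entirely recurrent-parent except around loci kept segregating by
selection. Tall and dwarf plants from this population are pooled into two
bulks and resequenced; because the dwarf phenotype is recessive and
controlled by a major locus in this design, every dwarf plant is
homozygous for the recurrent allele at that locus while every tall plant
is heterozygous. Pooled allele frequencies therefore separate maximally at
the causal locus and nowhere else.

`bsarna` implements the full analysis around this design — the
bulked-segregant genome scan, a companion differential-expression stage,
hormone-panel comparisons, and the association of candidate intervals
with expression — plus a synthetic-data module that generates the whole
study from seed, so every stage is testable without any external data.

# The mapping statistic

For each biallelic SNP and each bulk, the SNP-index is the fraction of
reads carrying the maternal (recurrent-parent, "M") allele,

$$\mathrm{SNPindex} = \frac{M}{M + P},$$

and the scan statistic is the difference between bulks,

$$\Delta = \mathrm{SNPindex}_{dwarf} - \mathrm{SNPindex}_{tall}.$$

Under the major-recessive model the analytic expectations at the causal
locus are 1.0 in the dwarf bulk, 0.5 in the tall bulk, and hence
$\Delta = 0.5$; at unlinked segregating sites both bulks have expectation
$1 - h/2$ with the same heterozygote share $h$, so $\Delta \approx 0$.

## Site filters

Real pooled resequencing lists millions of parent-polymorphic sites of
very unequal quality. `filter_informative_snps()` keeps biallelic,
parent-polymorphic records whose per-bulk total depth lies in
[`min_depth`, `max_depth`] (defaults 10 and 200): the lower bound keeps
binomial sampling noise bounded, the upper removes collapsed repeats.
Sites with zero depth in a bulk are flagged missing and propagate as
missing — an undefined index is never imputed to 0.

## Smoothing

$\Delta$ is smoothed by loess — a tricube-weighted local *linear* fit on
physical position (degree 1, exact "direct" surface), fitted per
chromosome so no information leaks across chromosome boundaries. The span
defaults to 0.1 of the chromosome's SNPs. Local linear fits reproduce
constant and linear signals exactly, which makes the smoother easy to
validate; the package's tests also check the fitted values against an
independent tricube weighted-least-squares solve at every point to
1e-10. Chromosomes with fewer than five usable SNPs are skipped with a
warning rather than smoothed unreliably.

A known behaviour of any local-regression scan is edge bias: at the
boundary of the donor-segment block around the causal locus the smoother
averages high-$\Delta$ and zero-$\Delta$ sites, so the smoothed value at
a locus close to a block edge is pulled below its analytic expectation.
The package treats the median/mean over replicate simulations as the
meaningful summary of the smoothed statistic at the causal locus; across
100 default runs it sits within 0.02–0.04 of the analytic 0.5.

## Null thresholds

The significance envelope is obtained by simulation rather than theory,
in the style of the standard QTL-seq two-level sampling scheme, because
the null distribution of $\Delta$ mixes two noise sources: which
individuals enter each bulk, and which reads are sampled from the pool.
At a segregating backcross marker each bulk member is heterozygous with
probability 1/2; the simulation draws the heterozygote count per bulk
(Binomial), converts to a maternal-allele frequency, draws reads
(Binomial at the tabulated depth), and tabulates upper quantiles of
$\Delta$ per depth. Quantiles are regularised to be monotone
non-increasing in depth (suffix maximum), since deeper sequencing can
only tighten the null. Sites monomorphic in the population produce
$\Delta = 0$ exactly and never reach a threshold, which is why the
simulation conditions on segregation and does not depend on the
backcross generation number.

Each SNP is compared at the threshold for the *smaller* of its two bulk
depths, and the raw-$\Delta$ quantiles are applied to the *smoothed*
track. Both choices are deliberately conservative: smoothing removes
most read-level noise, so a raw-$\Delta$ envelope over-covers. The
package accepts this because the signal of interest ($\Delta = 0.5$) is
several times the 95% envelope (≈ 0.19 at 50×), while false intervals
under the null become vanishingly rare (0 of 100 null simulations in the
test suite). A sharper, anti-conservative alternative — simulating whole
null tracks and smoothing them — would triple the cost of every scan for
no gain in this regime.

## Interval calling

Candidate intervals are maximal runs of consecutive SNPs whose smoothed
$\Delta$ meets their threshold; runs separated by at most `merge_gap`
(100 kb) merge, and merged runs supported by fewer than `min_snps` (10)
SNPs are dropped. Endpoints are the first and last supporting SNP
positions, 1-based inclusive — conservative and exactly reproducible,
at the cost of never extending an interval beyond its outermost SNP.
Total spans are reported in Mb rounded half-up to two decimals, matching
the convention of interval tables in this literature (e.g. five A01
intervals of 6.33 + 0.03 + 0.02 + 0.02 + 0.01 = 6.41 Mb).

# The synthetic BC~8~ study

The generator's defaults are the study conditions, not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| generations | 8 | BC~8~ |
| n_plants | 965 | final population size |
| bulks | 36 / 40 | tall / dwarf bulk sizes |
| depths | 46× / 57× | mean pooled coverage per bulk |
| replicates | 3 + 3 | RNA samples per group |
| library_size | 1e6 | mapped fragments per RNA sample |
| dispersion | 0.05 | NB α in var = μ + αμ² |
| de_fraction | 0.1 | truly DE genes |
| lfc range | 1–3 | \|log2FC\| of DE genes, uniform |
| region_up_prob | 0.99 | up-in-dwarf probability inside the candidate region |
| hormone ratios | IAA 1.5, GA 0.6, ABA 0.7 | dwarf/tall class shifts |

Where the emulated study prints a value (population size, bulk sizes,
coverages, replicate structure, hormone class directions) the default is
that value. Where it does not, a single realistic choice was fixed:
two chromosomes of 23 and 25 Mb with markers every 100 kb stand in for
the focal chromosome and one control; 2 cM/Mb is a typical genome-wide
rate for a *Brassica* A-subgenome chromosome; the causal locus sits at
A01:3,000,000, inside the region where the candidate signal is expected;
gene abundances are lognormal (sdlog 1) over 2000 genes; hormone
replicate noise is lognormal with sdlog 0.15 and qPCR Ct noise Gaussian
with sd 0.3.

Meiosis follows the Haldane (no-interference) map function with a
constant cM/Mb rate — the simplest defensible model when no genetic map
is given. Recombination fractions between adjacent markers are
$r = (1 - e^{-2d/100})/2$; chromosomes assort independently. The
backcross chain selects a causal-locus carrier as each generation's
parent ("marker-assisted" retention, without which a recessive locus is
lost from a single lineage with probability $1 - (1/2)^n$), and the test
suite checks the two analytic signatures of this scheme: 1:1 segregation
at the causal locus with selection, and $(1/2)^n$ heterozygosity decay at
unlinked markers without it.

Phenotype is determined by the major recessive locus alone. The real
trait has a polygenic component (trait distributions in such populations
are continuous), but modelling it would make bulk membership probabilistic
and the analytic expectations above approximate; the generator therefore
uses the major-locus model, and the scan's robustness to misclassified
bulk members is *not* something the passing tests demonstrate. Likewise
pooled reads are ideal binomial draws: no sequencing error (configurable),
no mapping bias, no index hopping. Passing the recovery and calibration
criteria shows the statistics behave as designed under the stated model,
not that they survive every artefact of real pool-seq data.

# Differential expression

The DE stage is a fully specified, self-contained negative binomial Wald
test, so that every number it produces is reproducible from this package
alone:

* **Normalisation** — median-of-ratios size factors over genes with
  nonzero counts in all samples, used as computed (no rescaling).
* **Dispersion** — pooled method of moments,
  $\alpha = \max(0, (s^2 - \bar\mu)/\bar\mu^2)$, with $s^2$ the pooled
  within-group variance and $\bar\mu$ the mean of the two group means.
  With three replicates per group a per-gene $\alpha$ is extremely noisy;
  the truncation at 0 makes the test mildly conservative (empirical size
  ≈ 0.035 at nominal 0.05 on a Poisson null), which the calibration
  tests document rather than hide.
* **Effect and test** — log2FC = log2((μ_dwarf + 0.5)/(μ_tall + 0.5));
  the 0.5 pseudo-count keeps all-zero groups finite. Wald z on the ln
  scale with SE² = (1/n₁)(1/μ₁′ + α) + (1/n₂)(1/μ₂′ + α), two-sided
  normal p, Benjamini–Hochberg adjustment.
* **DEG rule** — \|log2FC\| ≥ 1 and padj ≤ 0.05, after excluding genes
  with FPKM < 1 in *any* sample. The "any" reading is the literal one of
  the filter rule this stage mirrors; since "in all samples" is the other
  defensible reading, the rule is configurable (`fpkm_filter_rule`).

DEG z-profiles (per-gene z-scores of log2(FPKM+1) across the six
samples) are clustered with Euclidean K-means, k = 6, k-means++ seeding,
best of 10 restarts by within-cluster SS. K-means labels are arbitrary,
so clusters are relabelled 1..k by decreasing mean (dwarf − tall) centre
contrast: low labels are up-in-dwarf clusters and the numbering is
deterministic under a fixed seed.

qPCR validation uses the 2^−ΔΔCt estimator against a constant reference
gene; concordance with the RNA-seq fold-changes is the squared Pearson
correlation of paired log2FCs. With zero simulated Ct noise the identity
R² = 1 holds exactly, which the tests assert.

# Hormone panels

Calibration curves are unweighted OLS lines (response on concentration);
1/x weighting is available for heteroscedastic responses but is not the
default, as no weighting scheme is implied by the emulated protocol.
Quantification inverts the line and floors negative concentrations at
zero with a below-LOQ flag. Class totals are sums of member compounds per
replicate; group comparison uses the Welch unequal-variance t-test with
Satterthwaite df (the robust choice at n = 3; the pooled-variance test is
available by flag) with `*` p < 0.05 and `**` p < 0.01. Fold-change
ranges pair replicates by index — the emulated report gives a fold range
without defining its pairing, and index pairing is the only
order-independent convention available from the published tables.

# Association

Genes belong to an interval if they overlap it by ≥ 1 bp (1-based
inclusive; `start_within` is available as the stricter variant). Overlap
is computed with GenomicRanges and cross-checked in the tests against a
brute-force all-pairs scan. Direction tallies and percentages (rounded
half-up to two decimals) reproduce the summary arithmetic of the emulated
study exactly: 542 of 1256 genes = 43.15%, 538 of 542 = 99.26%.
Over-representation uses the upper-tail hypergeometric distribution over
user-supplied gene sets with BH correction; the universe defaults to all
genes passing the FPKM filter. No live GO/KEGG lookup is performed.

# Numerical and degenerate-input choices

* SNP-index at zero depth is `NA`, never 0; `NA` deltas break runs during
  interval calling and are excluded from smoothing fits.
* Threshold quantiles use the default type-7 sample quantile.
* `round_half_up()` implements conventional half-up rounding (base R
  rounds half to even), used for all reported percentages and Mb spans.
* K-means ties (duplicate profiles) are handled by k-means++ falling back
  to uniform sampling when all distances are zero.
* `welch_t_test` returns t = 0, p = 1 for two identical zero-variance
  groups and errors when zero-variance groups have different means.
* Interval BED output is 0-based half-open per the BED standard;
  everything internal is 1-based inclusive.

# Problem sizes

The test suite and the acceptance script run the mapping study at its
full design size (965 plants, 480 markers, 100 replicate seeds — about
10 s per 100-seed study), the DE calibration at 2000 genes × 6 samples,
and Monte-Carlo checks at 10,000 draws, sizes at which the binomial
tolerances used in the assertions are decisive.

# Known limitations

* The generator's marker grid (100 kb) bounds interval-endpoint
  resolution; real SNP densities are ~100× higher.
* The conservative threshold envelope means power statements transfer to
  real data only qualitatively; with a weak QTL (Δ well below 0.5) the
  envelope's over-coverage would cost real power.
* The NB Wald test with moments dispersion is deliberately simple; it is
  not a replacement for shrinkage-based DE tools on real data, and the
  package makes no claim of reproducing any specific tool's DEG lists.
* Hormone quantification starts from peak areas; nothing upstream
  (chromatogram processing, RT alignment) is modelled.
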