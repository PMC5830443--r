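---
title: "Detecting domestication sweeps and regulatory enrichment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting domestication sweeps and regulatory enrichment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscape)
```

# The problem

Domestication leaves two complementary footprints in a genome. A
selective sweep removes variation around the selected site in the
domestic population while the wild relative keeps it, and it drags
allele frequencies apart between the two populations. `sweepscape`
implements the analytical chain that exploits both signals for a
domestic/wild pair of genome collections — quality control of called
SNPs, a windowed differentiation-and-diversity scan, comparative
transfer of regulatory annotation between genomes, overlap-enrichment
statistics, and a per-site allele-frequency-divergence analysis — plus a
synthetic-data module that generates inputs with the statistical
structure the analysis assumes.

# Models and procedures

## SNP quality control

`apply_qc()` applies seven filters in a fixed order with first-hit
attribution, so the per-rule removal counts plus the survivors always
partition the input: (i) per-sample read depth within [5×, 2× the
per-sample average]; (ii) mapping quality ≥ 30 and base quality ≥ 20;
(iii) sites within 5 bp of an indel; (iv) of any SNP pair closer than
4 bp, the lower-quality member; (v) tri-allelic sites; (vi) call rate
below 90 %; (vii) excess heterozygosity.

Two points were genuinely open and are resolved as follows. The depth
bounds are per sample, but a *site* passes or fails; we fail a site when
more than half of the samples are outside their depth window
(`depth_fail_fraction`, exposed as a parameter). The heterozygosity
filter is one-sided: "excess of heterozygosity" is the alternative of
interest (it flags paralogous collapse), so we use Levene's exact
conditional distribution of the heterozygote count given the allele
counts, pooled over populations, and reject when the upper tail
P(het ≥ observed) < 0.001. The cascade is idempotent because the
per-sample average depth is computed once and carried with the table.

## The sweep scan

Per-site differentiation is Weir & Cockerham's (1984) two-population
θ̂ = a/(a+b+c), evaluated from allele frequencies, sample sizes, and
observed heterozygosities. Sites monomorphic across both populations are
undefined and excluded from window means; negative θ̂ values are retained
(clipping would bias window averages upward). The test suite checks θ̂
against an independent evaluation through the ANOVA mean-squares
formulation on a thousand random genotype configurations, at 1e-12.

Windows are 20 kb with a 10 kb step, so consecutive bins half-overlap;
bins with fewer than 20 SNPs carry their SNP count but no statistics.
Window FST is the arithmetic mean of per-site θ̂ ("average of ratios"),
matching the framing of windowed-FST scans that average per-SNP values;
a ratio-of-averages mode (Σa/Σ(a+b+c)) is available behind
`fst_method` for users who prefer the asymptotically less biased
estimator.

Nucleotide diversity per bin is, by default, the sum over sites of the
unbiased expected heterozygosity 2p̂(1−p̂)·2n/(2n−1), divided by bin
width. A literal mode (`pi_method = "het_count"`: the count of sites
carrying at least one heterozygous genotype per bin width) is provided
because "the number of heterozygous SNP by bin size" admits both
readings; the default is the standard π that per-nucleotide diversity
percentages imply.

Outlier bins are called jointly: both the bin's FST and its
ln(π_wild/π_dom) must exceed the genome-wide mean by z·sd, with
z = Φ⁻¹(1−α). The default α = 0.001 is one account of the published
thresholds; the same cutoffs are elsewhere described as a
Bonferroni-style family level of 0.01. Because the two descriptions
conflict, α is a parameter and `call_outliers()` reports the *raw*
thresholds implied by the chosen α (the analogues of published cutoffs,
which are data-dependent), leaving the choice visible rather than baked
in. Wild-direction sweeps use the symmetric lower tail of the ratio.
Flagged bins within 50 kb merge by single linkage into regions
(`merge_regions()`, verified against a transitive-closure oracle), and
each region is annotated with its closest gene, ties broken toward the
smaller start coordinate.

## Comparative annotation transfer

`project_intervals()` is a chain-based projector with a minimum-match
criterion: an interval maps when at least `min_match` (default 0.1) of
its bases lie in aligned blocks of a single chain; the projection is the
span of the projected block intersections, so target-side deletions
shorten it. Intervals whose aligned bases split across chains are
rejected rather than stitched — the conservative default of liftOver-style
tools. "High-quality" reverse mapping is not a standard quantity; we
define it as the back-projection recovering at least 50 % of the source
interval on the same chromosome (`min_back_overlap`, configurable),
which is ordinary reciprocal-best practice. We deliberately do not
require one-to-one uniqueness beyond the single-chain rule; ambiguous
(split) back-projections are dropped, which the tests exercise with a
planted paralogous chain.

## Enrichment statistics

Recovery rates count query intervals overlapped by ≥ 1 bp and truncate
to integer percent for display (the exact fraction is retained).
Shuffle-null empirical p-values re-place the feature set uniformly at
random (`shuffle_features()`, length-preserving, non-overlapping,
genome-wide) and use p = (k+1)/(n+1) with k the number of the n
randomizations reaching the observed overlap; the +1 keeps p achievable
and strictly positive, the usual convention when the counting rule alone
is stated. The overlap statistic counts feature *intervals* hitting the
observed set, matching the recovery-rate framing; a base-pair mode
exists for users who prefer mass overlap.

Locus-overlap enrichment classifies every universe bin (all scan bins)
as hit/not-hit by a query feature class, crosses that with membership in
the reference (outlier) set, and applies a one-sided Fisher exact test,
BH-corrected across classes. The 2×2 construction is re-derived here
rather than delegated to an enrichment package, but the Fisher p itself
comes from `stats::fisher.test`; the suite checks it against direct
hypergeometric tail summation at 1e-12.

## Allele-frequency divergence

ΔAF = |AF_dom − AF_wild| over sites segregating in both populations.
Bins have width 0.1 over [0, 1] with a right-closed top bin so ΔAF = 1
is counted; the width is configurable since only the bin list, not the
width, is ever printed in this type of analysis. For feature class f and
bin b, M(f, b) = log2(p(f|b)/p(f)); cells in empty bins are undefined
(not zero), and observed-zero cells give −Inf, which the consistency
identity Σ_b N_b·2^{M(f,b)}·p(f) = n_f handles naturally. Deviation per
feature is tested by χ² against expected counts proportional to the
overall bin sizes (df = bins − 1). The exonic perturbation control
shifts exon-overlapping sites' ΔAF upward additively (a permutation mode
is also provided, since the control's exact mechanism is a design
choice) and re-runs the M-value table to quantify spillover into
physically linked classes.

# The synthetic-data generator

The generator defines the study conditions the package is tested under:
67 domestic and 17 wild diploid genomes on a 2 × 10 Mb layout
(≈ 2,000 overlapping scan bins), genome-wide π targets of 0.0016
(domestic) and 0.0020 (wild) per bp, and five planted 60-kb sweeps with
domestic diversity retention f_π = 0.05 and allele-frequency shift
δ = 0.8.

Each site carries a shared ancestral allele frequency drawn from a
neutral-like density ∝ 1/p truncated to [1/2N, 1 − 1/2N], plus
independent Gaussian drift noise per population (sd 0.13, clipped to
[0, 1]). The noise level was chosen once so that the between-population
allele-frequency correlation over shared sites lands in the
high-correlation regime (~0.75) that motivates treating most loci as
neutral; clipping additionally creates private variants in each
population. Rather than solving for the site density in closed form —
clipping makes that biased — the generator over-draws sites and
self-calibrates: it thins sites uniformly until the realized
expected-heterozygosity total matches the wild π target, then snaps a
computed fraction of sites to domestic monomorphism to hit the (lower)
domestic target. Sweeps are planted afterwards by direct AF manipulation
(shift toward the nearer fixation boundary by δ; thin polymorphism to
f_π), which gives exact control of effect size for power tests — a
forward or coalescent simulation would not. Genotypes are binomial draws
from the population AF; depth (Poisson, mean 12), qualities, indel
positions, 0.1 % tri-allelic flags and 2 % missingness provide the QC
annotations.

What the generator does *not* emulate: linkage disequilibrium beyond
window-level AF sharing, demographic history, recombination-rate
variation, and genotype-calling error correlated with depth. Passing
tests therefore demonstrate the correctness and power of the statistics
under idealized sampling noise, not robustness to the full error
structure of real resequencing data.

Feature geometry places non-overlapping gene bodies, promoter-like
states centred on the TSS, flanking states just outside, genic
enhancers inside gene bodies, distal enhancers 20–100 kb away, and
proximal/distal element classes; by construction proximal classes sit
closer to gene starts than distal enhancers, the property the
feature-level analyses rely on. Peak sets recover each predicted
element independently with a configurable probability (defaults 0.85
for promoter-mark and 0.71 for enhancer-mark peaks, the regime of the
recovery-rate analysis), jittered but guaranteed ≥ 1 bp of overlap,
plus uniformly placed decoys. Simulated chains alternate aligned blocks
with indels and come with their exact reciprocals, so the round-trip
identity on block-interior intervals is testable.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; VCF positions
  convert at the boundary and are retained for output. Chromosome names
  match exactly — no "chr" aliasing — so namespace mismatches surface as
  errors instead of empty results.
* Z-transforms error out on zero variance (e.g. constant windows)
  rather than returning all-NA flags.
* θ̂ is NA (never 0) for monomorphic-overall sites, sites with < 2
  called genotypes in either population, and a + b + c = 0.
* `closest_features()` reports NA (never 0) when the query chromosome
  has no subject intervals; ties break toward the smaller start.
* `shuffle_features()` re-proposes only conflicting intervals each
  round (keeping the earlier-indexed of each overlapping pair) and
  errors after a bounded number of rounds when the packing is
  infeasible; a single interval's placement is exactly uniform over all
  valid start positions.
* The QC close-pair rule resolves quality ties by keeping the
  earlier-positioned SNP, so the cascade is deterministic.

# Problem sizes

The default conditions above are the package's reference problem:
~205,000 simulated sites across 84 genomes, ~2,000 scan bins, 300
genes, 200–1000 shuffle randomizations. The full pipeline completes in
well under a minute on a single CPU at these sizes, and the test suite
scales its heavier property checks (oracle comparisons, uniformity
tests) to a few hundred replicates each.

# Known limitations

* The scan assumes two populations; the estimator is the two-population
  special case of the variance-components framework.
* Empirical overlap p-values inherit the granularity of n
  randomizations; with interval-count statistics and dense observed
  sets they are conservative under heavy ties (the base-pair mode
  mitigates this).
* The M-value table treats overlapping feature classes independently;
  for disjoint classes the table is a partition, otherwise columns can
  sum to more than the bin total by design.
* Split projections are rejected, not stitched; annotation that
  legitimately spans chain breaks is lost, mirroring the behaviour of
  the standard tool chain.
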