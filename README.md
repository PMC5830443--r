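# sweepscape

Selection-sweep scans and regulatory-feature enrichment for
two-population genome data.

`sweepscape` is an R package for geneticists studying domestication: it
takes diploid genotypes from a *domestic* and a *wild* population and
asks (1) which genomic regions show the joint signature of a selective
sweep — elevated between-population differentiation together with
depressed diversity in the domestic population — and (2) whether those
regions, and the most allele-frequency-divergent individual sites, are
enriched for regulatory genome features such as promoter and enhancer
chromatin states, proximal/distal elements, and experimentally observed
histone-mark peaks. A synthetic-data module generates genotypes,
annotation features, ChIP-seq-like peak sets and alignment chains with
the statistical structure the analysis assumes, so the entire pipeline
runs end to end with no external data.

## The statistics at the core

* **Per-site differentiation** is Weir & Cockerham's (1984)
  variance-components estimator θ̂ = a/(a+b+c), computed from observed
  allele frequencies, sample sizes and heterozygosities of the two
  populations. Fixed differences give θ̂ = 1 exactly; negative values are
  retained.
* **Windowed scan**: θ̂ is averaged, and nucleotide diversity π is
  computed per population, in 20-kb bins every 10 kb (bins with < 20 SNPs
  are masked). The direction statistic is ln(π_wild/π_domestic):
  positive values mark diversity loss in domestics.
* **Outlier calling** Z-transforms both bin statistics genome-wide and
  flags bins where *both* exceed the one-sided normal quantile for a
  configurable α (default 0.001, z > 3.09). Flagged bins within 50 kb
  merge into sweep regions, each annotated with its closest gene.
* **Comparative annotation** projects intervals through pairwise
  alignment chains, requiring ≥ `minMatch` (default 0.1) of an
  interval's bases in the aligned blocks of a single chain, and keeps
  only projections whose back-projection through the reciprocal chains
  recovers ≥ 50 % of the source interval.
* **Enrichment**: recovery rates of predicted elements against peak
  sets (integer-truncated percent), shuffle-null empirical p-values
  p = (k+1)/(n+1) over 1000 random re-placements, and one-sided
  Fisher-exact locus-overlap tests of feature classes within outlier
  bins against the universe of all bins, with Benjamini–Hochberg FDR.
* **Allele-frequency divergence**: per-site ΔAF = |AF_dom − AF_wild|
  over shared-segregating sites is binned (width 0.1), and each feature
  class's share per bin is compared with its genome-wide share as
  M = log2(p(f|b)/p(f)), with a per-feature χ² test and an exonic
  perturbation control for spillover between linked features.

## Worked example

```r
library(sweepscape)

cfg <- sim_config(seed = 1)          # 67 domestic + 17 wild genomes,
                                     # 2 x 10 Mb, five planted sweeps
v   <- simulate_variants(cfg)
qc  <- apply_qc(v)
print(qc$report)
#> QC cascade report
#>   depth            removed 0
#>   quality          removed 0
#>   near_indel       removed 216
#>   close_pair       removed 6337
#>   triallelic       removed 196
#>   call_rate        removed 10
#>   hwe_excess_het   removed 8
#>   input 205498 -> survivors 198731

w <- call_outliers(window_stats(qc$variants, cfg$layout))
attr(w, "thresholds")$fst        # 0.2585 : raw FST cutoff implied by alpha
sum(w$outlier, na.rm = TRUE)     # 25 flagged bins
regions <- merge_regions(w)      # 5 regions, one per planted sweep
regions$end - regions$start      # 60000 60000 60000 60000 60000

shared_polymorphism_summary(qc$variants)$pct_shared_of_domestic  # 68
af_correlation(qc$variants)$r    # 0.7485
```

The five planted sweeps are recovered exactly, with no false-positive
bins at α = 0.001; 68 % of domestic-segregating SNPs are shared with the
wild population and the between-population allele-frequency correlation
is ~0.75, matching the regime the generator is calibrated to emulate.

A configured end-to-end run (`run_pipeline(pipeline_config(seed = 1),
"out/")`, or `exec/sweepscape run --seed 1 --out out/`) executes
simulate → qc → scan → project → validate → enrich → deltaaf, writes
every table as TSV and every interval set as BED, and finishes with a
checksummed manifest; reruns with the same seed are byte-identical.

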