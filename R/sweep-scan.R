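#' Per-site Weir-Cockerham FST
#'
#' The two-population variance-components estimator theta-hat = a/(a+b+c)
#' of Weir & Cockerham (1984), computed per site from observed allele
#' frequencies, sample sizes and observed heterozygosities. Values can be
#' negative; fixed differences give exactly 1. Sites monomorphic across
#' both populations, or with fewer than two called diploid genotypes in
#' either population, are undefined (`NA`) and excluded from window means.
#'
#' @param v A [variant_table()].
#' @param components If `TRUE`, also return the per-site `a`, `b`, `c`
#'   variance components (needed for the ratio-of-averages window mode).
#' @return Numeric vector of theta per site, or (with `components`) a
#'   data.frame `theta`, `a`, `b`, `c`.
#' @export
site_fst <- function(v, components = FALSE) {
  gd <- v$geno[, v$pop == "domestic", drop = FALSE]
  gw <- v$geno[, v$pop == "wild", drop = FALSE]
  n1 <- rowSums(!is.na(gd)); n2 <- rowSums(!is.na(gw))
  p1 <- rowSums(gd, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(gw, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(gd == 1, na.rm = TRUE) / n1
  h2 <- rowSums(gw == 1, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  theta <- a / (a + b + cc)
  undef <- n1 < 2 | n2 < 2 | (a + b + cc) == 0 | !is.finite(theta)
  theta[undef] <- NA_real_
  if (!components) return(theta)
  a[undef] <- b[undef] <- cc[undef] <- NA_real_
  data.frame(theta = theta, a = a, b = b, c = cc)
}

## internal: per-site per-population diversity contribution
## unbiased: 2 p-hat (1 - p-hat) * 2n/(2n - 1) (expected heterozygosity)
## het_count: 1 if the population carries >= 1 heterozygous genotype
site_pi_terms <- function(v, method = c("unbiased", "het_count")) {
  method <- match.arg(method)
  out <- list()
  for (p in c("domestic", "wild")) {
    g <- v$geno[, v$pop == p, drop = FALSE]
    ncall <- rowSums(!is.na(g))
    if (method == "unbiased") {
      ph <- rowSums(g, na.rm = TRUE) / (2 * ncall)
      term <- 2 * ph * (1 - ph) * (2 * ncall) / (2 * ncall - 1)
      term[ncall < 1 | 2 * ncall - 1 <= 0] <- 0
    } else {
      term <- as.numeric(rowSums(g == 1, na.rm = TRUE) > 0)
      term[ncall < 1] <- 0
    }
    out[[p]] <- term
  }
  out
}

#' Sliding-window scan statistics
#'
#' Tiles each chromosome with bins of `bin_width` bp every `step` bp
#' (default 20 kb / 10 kb, so consecutive bins half-overlap) and computes
#' per bin: SNP count, mean per-site FST, per-population nucleotide
#' diversity per bp, and the log diversity ratio `ln(pi_wild /
#' pi_domestic)`. Bins with fewer than `min_snp` SNPs are masked: they keep
#' their SNP count but carry no statistics and can never be flagged.
#'
#' @param v A QC-passed [variant_table()].
#' @param layout A [genome_layout()].
#' @param bin_width,step Bin geometry in bp; `bin_width` must be a multiple
#'   of `step`.
#' @param min_snp Minimum SNPs for a bin to carry statistics (default 20).
#' @param pi_method `"unbiased"` (default): per-site unbiased expected
#'   heterozygosity summed over the bin, per bp. `"het_count"`: the count
#'   of sites with at least one heterozygous genotype per bp, a literal
#'   "heterozygous SNPs per bin size" reading.
#' @param fst_method `"site_mean"` (default): arithmetic mean of defined
#'   per-site theta. `"ratio_of_averages"`: sum(a)/sum(a+b+c) over the bin.
#' @return A `window_stats` data.frame: `chrom`, `start`, `end`, `n_snp`,
#'   `mean_fst`, `pi_domestic`, `pi_wild`, `ln_ratio`.
#' @export
window_stats <- function(v, layout, bin_width = 20000L, step = 10000L,
                         min_snp = 20L,
                         pi_method = c("unbiased", "het_count"),
                         fst_method = c("site_mean", "ratio_of_averages")) {
  pi_method <- match.arg(pi_method)
  fst_method <- match.arg(fst_method)
  if (bin_width %% step != 0)
    stop("bin_width must be a multiple of step")
  k <- bin_width %/% step
  bins <- data.table::rbindlist(lapply(seq_len(nrow(layout)), function(i) {
    L <- layout$length[i]
    if (L < bin_width) return(NULL)
    starts <- seq(0, L - bin_width, by = step)
    data.table::data.table(chrom = layout$chrom[i], start = starts,
                           end = starts + bin_width)
  }))
  fstc <- site_fst(v, components = TRUE)
  pit <- site_pi_terms(v, pi_method)
  sdt <- data.table::data.table(chrom = v$sites$chrom,
                                start0 = v$sites$start,
                                theta = fstc$theta, a = fstc$a,
                                abc = fstc$a + fstc$b + fstc$c,
                                pid = pit$domestic, piw = pit$wild)
  ## a site belongs to the k step-offset bins covering it
  per_bin <- data.table::rbindlist(lapply(seq_len(k) - 1L, function(off) {
    b <- (sdt$start0 %/% step - off) * step
    data.table::data.table(chrom = sdt$chrom, start = b,
                           sdt[, !"chrom"])
  }))
  agg <- per_bin[, list(n_snp = .N,
                        mean_fst = mean(theta[!is.na(theta)]),
                        sum_a = sum(a, na.rm = TRUE),
                        sum_abc = sum(abc, na.rm = TRUE),
                        pi_domestic = sum(pid) / bin_width,
                        pi_wild = sum(piw) / bin_width),
                 by = c("chrom", "start")]
  out <- merge(bins, agg, by = c("chrom", "start"), all.x = TRUE)
  out[is.na(n_snp), n_snp := 0L]
  if (fst_method == "ratio_of_averages")
    out[, mean_fst := ifelse(sum_abc > 0, sum_a / sum_abc, NA_real_)]
  out[, c("sum_a", "sum_abc") := NULL]
  out[n_snp < min_snp,
      c("mean_fst", "pi_domestic", "pi_wild") := NA_real_]
  out[, ln_ratio := ifelse(!is.na(pi_wild) & !is.na(pi_domestic) &
                             pi_wild > 0 & pi_domestic > 0,
                           log(pi_wild / pi_domestic), NA_real_)]
  out[!is.finite(mean_fst), mean_fst := NA_real_]
  data.table::setorderv(out, c("chrom", "start"))
  out <- as.data.frame(out)
  structure(out, class = c("window_stats", "data.frame"),
            bin_width = bin_width, step = step, min_snp = min_snp,
            pi_method = pi_method, fst_method = fst_method)
}

#' Joint Z-score outlier calling
#'
#' Z-transforms the bin-wise mean FST and log diversity ratio over all
#' unmasked bins and flags, at the one-sided normal quantile for `alpha`, a
#' bin as a domestic-direction outlier when *both* statistics exceed the
#' cutoff (high divergence and depressed domestic diversity), or as a
#' wild-direction outlier when FST is high and the ratio is symmetrically
#' low. The raw-statistic thresholds implied by `alpha` (the analogue of
#' the published FST > 0.156 and ln ratio > 0.672, which are
#' data-dependent) are attached as attribute `thresholds`.
#'
#' @param w A [window_stats()] table.
#' @param alpha One-sided tail probability (default 0.001; the published
#'   account describes the same cutoffs both as Z-test P < 0.001 and as a
#'   Bonferroni-adjusted family level of 0.01, so the level is exposed
#'   rather than fixed).
#' @return `w` with added columns `z_fst`, `z_ratio`, `outlier`,
#'   `direction` (`"domestic"`, `"wild"` or `NA`); attribute `thresholds`
#'   lists the Z cutoff and the raw equivalents.
#' @export
call_outliers <- function(w, alpha = 0.001) {
  stopifnot(inherits(w, "window_stats"), alpha > 0, alpha < 1)
  ok <- !is.na(w$mean_fst) & !is.na(w$ln_ratio)
  if (sum(ok) < 2)
    stop("need at least two unmasked bins to standardize")
  mf <- mean(w$mean_fst[ok]); sf <- stats::sd(w$mean_fst[ok])
  mr <- mean(w$ln_ratio[ok]); sr <- stats::sd(w$ln_ratio[ok])
  if (sf == 0 || sr == 0)
    stop("zero variance across bins; provide a larger input")
  zcut <- stats::qnorm(1 - alpha)
  w$z_fst <- (w$mean_fst - mf) / sf
  w$z_ratio <- (w$ln_ratio - mr) / sr
  dom <- ok & w$z_fst > zcut & w$z_ratio > zcut
  wld <- ok & w$z_fst > zcut & w$z_ratio < -zcut
  w$outlier <- dom | wld
  w$direction <- ifelse(dom, "domestic", ifelse(wld, "wild", NA))
  attr(w, "alpha") <- alpha
  attr(w, "thresholds") <- list(
    z = zcut,
    fst = mf + zcut * sf,
    ln_ratio = mr + zcut * sr,
    ln_ratio_wild = mr - zcut * sr)
  w
}

#' Merge flagged bins into sweep regions
#'
#' Single-linkage merge of outlier bins: bins on the same chromosome whose
#' gap is at most `gap` bp (50 kb by default) join the same region. The
#' region spans the minimum start to the maximum end of its members.
#'
#' @param w A flagged [call_outliers()] table.
#' @param gap Maximum merge gap in bp.
#' @param direction Which outlier direction to merge (default
#'   `"domestic"`).
#' @return data.frame of regions: `chrom`, `start`, `end`, `n_bins`,
#'   `peak_z_fst`.
#' @export
merge_regions <- function(w, gap = 50000L, direction = "domestic") {
  stopifnot(inherits(w, "window_stats"))
  if (is.null(w$outlier)) stop("run call_outliers() first")
  f <- w[w$outlier & !is.na(w$direction) & w$direction == direction, ,
         drop = FALSE]
  if (!nrow(f))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_bins = integer(),
                      peak_z_fst = numeric()))
  f <- f[order(f$chrom, f$start), ]
  new_chrom <- c(TRUE, f$chrom[-1] != f$chrom[-nrow(f)])
  ## running maximum end within a chromosome handles overlapping bins
  grp <- integer(nrow(f)); g <- 0L; reach <- -Inf
  for (i in seq_len(nrow(f))) {
    if (new_chrom[i] || f$start[i] - reach > gap) {
      g <- g + 1L
      reach <- f$end[i]
    } else reach <- max(reach, f$end[i])
    grp[i] <- g
  }
  z <- if (!is.null(f$z_fst)) f$z_fst else rep(NA_real_, nrow(f))
  out <- do.call(rbind, lapply(split(seq_len(nrow(f)), grp), function(i)
    data.frame(chrom = f$chrom[i[1]], start = min(f$start[i]),
               end = max(f$end[i]), n_bins = length(i),
               peak_z_fst = suppressWarnings(max(z[i], na.rm = TRUE)))))
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Assign the closest gene to each sweep region
#'
#' Distance is 0 when the region overlaps the gene body; ties at equal
#' distance go to the gene with the smaller start coordinate. Regions on a
#' chromosome without genes get `NA`.
#'
#' @param regions Output of [merge_regions()].
#' @param genes A [feature_set()] of gene bodies with names.
#' @return `regions` with added `closest_gene` and `gene_distance`.
#' @export
assign_genes <- function(regions, genes) {
  if (!nrow(genes)) stop("gene set is empty")
  if (!nrow(regions)) {
    regions$closest_gene <- character(0)
    regions$gene_distance <- numeric(0)
    return(regions)
  }
  rf <- feature_set(regions$chrom, regions$start, regions$end)
  cl <- closest_features(rf, genes)
  regions$closest_gene <- ifelse(is.na(cl$index), NA_character_,
                                 genes$name[cl$index])
  regions$gene_distance <- cl$distance
  regions
}

#' Shared and private polymorphism summary
#'
#' A site is "segregating" in a population when its allele frequency there
#' is strictly between 0 and 1, and "shared" when segregating in both.
#' Display percentages follow the integer-truncation convention of
#' [truncated_percent()].
#'
#' @param v A [variant_table()].
#' @return List of counts (`shared`, `domestic_private`, `wild_private`,
#'   `segregating_domestic`, `segregating_wild`) and display percentages
#'   (`pct_shared_of_domestic`, `pct_shared_of_wild`).
#' @export
shared_polymorphism_summary <- function(v) {
  af <- population_af(v)
  seg_d <- !is.na(af$af_domestic) & af$af_domestic > 0 & af$af_domestic < 1
  seg_w <- !is.na(af$af_wild) & af$af_wild > 0 & af$af_wild < 1
  shared <- sum(seg_d & seg_w)
  out <- list(shared = shared,
              domestic_private = sum(seg_d & !seg_w),
              wild_private = sum(seg_w & !seg_d),
              segregating_domestic = sum(seg_d),
              segregating_wild = sum(seg_w))
  out$pct_shared_of_domestic <-
    if (out$segregating_domestic > 0)
      truncated_percent(shared, out$segregating_domestic) else NA_integer_
  out$pct_shared_of_wild <-
    if (out$segregating_wild > 0)
      truncated_percent(shared, out$segregating_wild) else NA_integer_
  out
}

#' Between-population allele-frequency correlation
#'
#' Pearson product-moment correlation of per-site reference-allele
#' frequencies between the two populations, over sites segregating in
#' both.
#'
#' @param v A [variant_table()].
#' @return List with `r`, `n` (shared sites) and `p` (correlation test
#'   p-value); `r` is `NA` when fewer than 3 shared sites or zero
#'   variance.
#' @export
af_correlation <- function(v) {
  af <- population_af(v)
  seg <- !is.na(af$af_domestic) & !is.na(af$af_wild) &
    af$af_domestic > 0 & af$af_domestic < 1 &
    af$af_wild > 0 & af$af_wild < 1
  x <- 1 - af$af_domestic[seg]  # reference-allele frequency
  y <- 1 - af$af_wild[seg]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, n = length(x), p = NA_real_))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = length(x), p = ct$p.value)
}

#' Nucleotide diversity within feature classes
#'
#' Restricts the diversity estimator to sites overlapping each feature
#' class and normalizes by the class's merged interval length.
#'
#' @param v A [variant_table()].
#' @param features Named list of [feature_set()]s.
#' @param pi_method Passed to the per-site estimator (see
#'   [window_stats()]).
#' @return data.frame: `class`, `length` (merged bp), `n_snp`,
#'   `pi_domestic`, `pi_wild`. Empty classes give `NA` diversity.
#' @export
feature_pi <- function(v, features, pi_method = "unbiased") {
  pit <- site_pi_terms(v, pi_method)
  gs <- GenomicRanges::GRanges(v$sites$chrom,
                               IRanges::IRanges(v$sites$pos, width = 1))
  out <- lapply(names(features), function(nm) {
    f <- features[[nm]]
    if (!nrow(f))
      return(data.frame(class = nm, length = 0, n_snp = 0L,
                        pi_domestic = NA_real_, pi_wild = NA_real_))
    merged <- GenomicRanges::reduce(fs_granges(f))
    L <- sum(IRanges::width(merged))
    inside <- IRanges::overlapsAny(gs, merged)
    data.frame(class = nm, length = L, n_snp = sum(inside),
               pi_domestic = sum(pit$domestic[inside]) / L,
               pi_wild = sum(pit$wild[inside]) / L)
  })
  do.call(rbind, out)
}
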