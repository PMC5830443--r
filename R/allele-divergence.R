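#' Per-site allele-frequency divergence
#'
#' The absolute difference in alternate-allele frequency between the
#' domestic and wild populations, restricted to sites segregating in both
#' (0 < AF < 1 in each). Because the difference is absolute, the result is
#' invariant to swapping reference and alternate labels.
#'
#' @param v A [variant_table()].
#' @return data.frame with one row per shared-segregating site: `chrom`,
#'   `pos`, `start`, `af_domestic`, `af_wild`, `delta_af`, and
#'   `consequence` when the table carries labels.
#' @export
delta_af <- function(v) {
  af <- population_af(v)
  seg <- !is.na(af$af_domestic) & !is.na(af$af_wild) &
    af$af_domestic > 0 & af$af_domestic < 1 &
    af$af_wild > 0 & af$af_wild < 1
  out <- data.frame(chrom = v$sites$chrom[seg], pos = v$sites$pos[seg],
                    start = v$sites$start[seg],
                    af_domestic = af$af_domestic[seg],
                    af_wild = af$af_wild[seg],
                    delta_af = abs(af$af_domestic - af$af_wild)[seg],
                    stringsAsFactors = FALSE)
  if (!is.null(v$sites$consequence))
    out$consequence <- v$sites$consequence[seg]
  rownames(out) <- NULL
  out
}

## internal: bin index for delta-AF values; right-closed top bin so 1.0
## falls in the last bin
daf_bin_index <- function(delta, bin_width) {
  nb <- round(1 / bin_width)
  pmin(nb, floor(delta / bin_width) + 1L)
}

#' M-value table of feature enrichment across delta-AF bins
#'
#' Allocates shared-segregating SNPs into delta-AF bins (default width 0.1
#' over \[0, 1\], right-closed top bin) and, for each feature class,
#' compares the class's share of SNPs within each bin to its genome-wide
#' share: `M(f, b) = log2(p(f | b) / p(f))`. Positive M marks
#' over-representation of the class in that divergence bin. A per-feature
#' chi-squared statistic tests the deviation of the observed per-bin
#' counts from the expected split (total class count times the overall
#' bin proportions), df = bins - 1.
#'
#' Feature classes are interval sets (a SNP counts when it falls inside
#' any interval of the class); with `by_consequence = TRUE` the table also
#' includes one class per consequence label carried by the sites.
#'
#' @param daf Output of [delta_af()].
#' @param features Named list of [feature_set()]s (may be `NULL` when
#'   `by_consequence` is used).
#' @param bin_width Delta-AF bin width (default 0.1; 1/bin_width must be
#'   an integer).
#' @param by_consequence Also tabulate consequence labels as classes.
#' @return An `af_bin_table` list: `breaks`, `total` (SNPs per bin),
#'   `counts` (class x bin matrix), `M` (same shape; `NA` for empty bins,
#'   `-Inf` for observed-zero cells), and `chisq` (data.frame `feature`,
#'   `statistic`, `df`, `p`).
#' @export
mvalue_table <- function(daf, features = NULL, bin_width = 0.1,
                         by_consequence = FALSE) {
  nb <- round(1 / bin_width)
  if (abs(nb * bin_width - 1) > 1e-9)
    stop("1/bin_width must be an integer")
  if (!nrow(daf)) stop("no shared-segregating sites")
  bin <- daf_bin_index(daf$delta_af, bin_width)
  total <- tabulate(bin, nbins = nb)
  classes <- list()
  if (!is.null(features)) {
    gs <- GenomicRanges::GRanges(daf$chrom,
                                 IRanges::IRanges(daf$pos, width = 1))
    for (nm in names(features)) {
      f <- features[[nm]]
      classes[[nm]] <- if (nrow(f))
        IRanges::overlapsAny(gs, fs_granges(f)) else rep(FALSE, nrow(daf))
    }
  }
  if (by_consequence) {
    if (is.null(daf$consequence))
      stop("by_consequence requires a consequence column")
    for (nm in sort(unique(daf$consequence)))
      classes[[nm]] <- daf$consequence == nm
  }
  if (!length(classes)) stop("no feature classes to tabulate")
  counts <- t(vapply(classes, function(inside)
    tabulate(bin[inside], nbins = nb), numeric(nb)))
  breaks <- seq(0, 1, by = bin_width)
  colnames(counts) <- paste0("[", utils::head(breaks, -1), ",",
                             breaks[-1],
                             c(rep(")", nb - 1), "]"))
  N <- sum(total)
  pf <- rowSums(counts) / N
  pb <- total / N
  M <- log2(sweep(sweep(counts, 2, total, `/`), 1, pf, `/`))
  M[, total == 0] <- NA_real_
  chisq <- do.call(rbind, lapply(rownames(counts), function(nm) {
    obs <- counts[nm, total > 0]
    prop <- total[total > 0] / sum(total[total > 0])
    if (sum(obs) == 0)
      return(data.frame(feature = nm, statistic = NA_real_,
                        df = length(obs) - 1, p = NA_real_))
    ct <- suppressWarnings(stats::chisq.test(obs, p = prop))
    data.frame(feature = nm, statistic = unname(ct$statistic),
               df = unname(ct$parameter), p = ct$p.value)
  }))
  structure(list(breaks = breaks, total = total, counts = counts, M = M,
                 chisq = chisq, bin_width = bin_width),
            class = "af_bin_table")
}

#' @export
print.af_bin_table <- function(x, ...) {
  cat(sprintf("delta-AF bin table: %d SNPs, %d bins, %d feature class(es)\n",
              sum(x$total), length(x$total), nrow(x$counts)))
  print(round(x$M, 2))
  invisible(x)
}

#' Cross-tabulate high-divergence sites by consequence
#'
#' Lists and counts the sites above a delta-AF threshold by their
#' consequence class, the screen used to ask whether gene-inactivating
#' (splice/stop) or protein-altering mutations sit among the most
#' divergent loci.
#'
#' @param daf Output of [delta_af()] carrying a `consequence` column.
#' @param threshold Delta-AF cutoff (default 0.8, strictly greater-than).
#' @return List: `counts` (named integer vector per consequence class) and
#'   `sites` (the qualifying rows of `daf`).
#' @export
consequence_scan <- function(daf, threshold = 0.8) {
  if (is.null(daf$consequence))
    stop("consequence labels are required")
  hi <- daf[daf$delta_af > threshold, , drop = FALSE]
  counts <- table(hi$consequence)
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       sites = hi)
}

#' Perturb exonic allele-frequency divergence (control analysis)
#'
#' Artificially inflates the delta-AF of exon-overlapping sites and leaves
#' all other sites untouched, so that re-running [mvalue_table()] on the
#' perturbed table quantifies how much apparent enrichment spills over
#' into other, physically linked feature classes.
#'
#' @param daf Output of [delta_af()].
#' @param exons A [feature_set()] of exonic intervals.
#' @param delta Shift size in (0, 1\]: `"shift"` mode adds `delta` to the
#'   delta-AF of exonic sites (clipped at 1), so `delta = 1` puts every
#'   exonic site in the top bin.
#' @param seed Optional seed (used by `"permute"` mode).
#' @param mode `"shift"` (additive, default) or `"permute"`: randomly
#'   permutes the delta-AF values among exonic sites, breaking the
#'   site-value coupling while preserving the exonic distribution.
#' @return `daf` with the `delta_af` column perturbed; attribute
#'   `perturbed` flags the affected rows.
#' @export
perturb_exonic_af <- function(daf, exons, delta, seed = NULL,
                              mode = c("shift", "permute")) {
  mode <- match.arg(mode)
  stopifnot(delta >= 0, delta <= 1)
  gs <- GenomicRanges::GRanges(daf$chrom,
                               IRanges::IRanges(daf$pos, width = 1))
  inside <- if (nrow(exons))
    IRanges::overlapsAny(gs, fs_granges(exons)) else rep(FALSE, nrow(daf))
  out <- daf
  if (mode == "shift") {
    out$delta_af[inside] <- pmin(1, out$delta_af[inside] + delta)
  } else {
    with_seed(seed, {
      out$delta_af[inside] <- sample(out$delta_af[inside])
    })
  }
  attr(out, "perturbed") <- inside
  out
}
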