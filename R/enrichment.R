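#' Recovery rate of predicted elements
#'
#' The percentage of query intervals overlapped by at least one subject
#' interval (>= 1 bp), the statistic used to validate predicted promoters
#' and enhancers against experimental peak sets. The display value is
#' truncated to a whole percent; the exact fraction is retained.
#'
#' @param query A [feature_set()] of predicted elements (must be
#'   non-empty).
#' @param subject A [feature_set()] of observed elements (e.g. ChIP-seq
#'   peaks).
#' @return A `recovery_rate` list: `percent` (integer), `fraction`,
#'   `n_query`, `n_hit`.
#' @examples
#' q <- feature_set("chr1", c(0, 100), c(50, 150))
#' s <- feature_set("chr1", 40, 60)
#' recovery_rate(q, s)$percent  # 50
#' @export
recovery_rate <- function(query, subject) {
  if (!nrow(query)) stop("query set is empty")
  n_hit <- any_overlap(query, subject)
  structure(list(percent = truncated_percent(n_hit, nrow(query)),
                 fraction = n_hit / nrow(query),
                 n_query = nrow(query), n_hit = n_hit),
            class = "recovery_rate")
}

#' @export
print.recovery_rate <- function(x, ...) {
  cat(sprintf("recovery rate: %d%% (%d of %d query intervals)\n",
              x$percent, x$n_hit, x$n_query))
  invisible(x)
}

#' Shuffle-null empirical overlap p-value
#'
#' Compares the observed overlap between a feature set and an observed
#' (e.g. experimental) set against `n` random re-placements of the feature
#' set on the genome ([shuffle_features()]). The p-value is
#' `(k + 1) / (n + 1)` where `k` counts randomizations with overlap at
#' least the observed value; the +1 correction keeps the estimate
#' achievable and strictly positive.
#'
#' @param feature A [feature_set()] to randomize.
#' @param observed A fixed [feature_set()] to overlap against.
#' @param layout A [genome_layout()].
#' @param n Number of randomizations (default 1000).
#' @param seed Optional integer seed; the whole null is reproducible.
#' @param stat `"intervals"` (default): count of feature intervals hitting
#'   the observed set, matching the recovery-rate framing. `"bases"`:
#'   total overlapping bases between the merged sets.
#' @return An `empirical_overlap` list: `p`, `observed`, `k`, `n`,
#'   `null_mean`, `null_sd`.
#' @export
empirical_overlap_p <- function(feature, observed, layout, n = 1000L,
                                seed = NULL,
                                stat = c("intervals", "bases")) {
  stat <- match.arg(stat)
  ## total overlapping bases between the merged sets, via a coverage
  ## sweep over interval endpoints (kept in base R: this sits in the
  ## randomization hot loop)
  overlap_bases <- function(a, b) {
    tot <- 0
    for (ch in base::intersect(unique(a$chrom), unique(b$chrom))) {
      ai <- a$chrom == ch; bi <- b$chrom == ch
      ev <- rbind(
        cbind(c(a$start[ai], b$start[bi]), rep(c(1, 2), c(sum(ai), sum(bi)))),
        cbind(c(a$end[ai], b$end[bi]), rep(c(-1, -2), c(sum(ai), sum(bi)))))
      ## half-open intervals: at equal positions, process ends (negative
      ## codes) before starts so book-ended intervals do not overlap
      ev <- ev[order(ev[, 1], ev[, 2]), , drop = FALSE]
      deltaa <- ifelse(abs(ev[, 2]) == 1, sign(ev[, 2]), 0)
      deltab <- ifelse(abs(ev[, 2]) == 2, sign(ev[, 2]) , 0)
      ca <- cumsum(deltaa); cb <- cumsum(deltab)
      seg <- diff(ev[, 1])
      tot <- tot + sum(seg[ca[-length(ca)] > 0 & cb[-length(cb)] > 0])
    }
    tot
  }
  measure <- function(fs) {
    if (stat == "intervals") any_overlap(fs, observed)
    else overlap_bases(fs, observed)
  }
  obs <- measure(feature)
  with_seed(seed, {
    null <- vapply(seq_len(n), function(i)
      measure(shuffle_features(feature, layout)), numeric(1))
    k <- sum(null >= obs)
    structure(list(p = (k + 1) / (n + 1), observed = obs, k = k, n = n,
                   null_mean = mean(null), null_sd = stats::sd(null)),
              class = "empirical_overlap")
  })
}

#' @export
print.empirical_overlap <- function(x, ...) {
  cat(sprintf(paste0("empirical overlap: observed %s vs null %.2f +/- ",
                     "%.2f (n = %d) -> p = %.4g\n"),
              format(x$observed), x$null_mean, x$null_sd, x$n, x$p))
  invisible(x)
}

#' Locus-overlap enrichment of feature classes in outlier bins
#'
#' For each query feature class, classifies every universe bin as a "hit"
#' when it overlaps at least one query interval, builds the 2x2 table
#' against membership in the reference (outlier) bin set, and tests
#' enrichment with a one-sided Fisher exact test; Benjamini-Hochberg FDR
#' is applied across query sets. The universe is all scan bins; the
#' reference set must be a subset of the universe by interval identity.
#'
#' @param querysets Named list of [feature_set()]s (all non-empty).
#' @param reference A [feature_set()] of outlier bins.
#' @param universe A [feature_set()] of all bins.
#' @return An `enrichment_table` data.frame, one row per query set:
#'   contingency counts `a` (reference & hit), `b` (reference, no hit),
#'   `c` (non-reference & hit), `d` (rest), `odds_ratio` (sample OR,
#'   degenerate tables flagged), one-sided `p`, BH `q`, `neg_log10_p`.
#' @export
locus_overlap_enrichment <- function(querysets, reference, universe) {
  stopifnot(is.list(querysets), length(querysets) > 0)
  if (is.null(names(querysets)) || any(!nzchar(names(querysets))))
    stop("querysets must be a named list")
  key <- function(fs) paste(fs$chrom, fs$start, fs$end)
  ref_idx <- match(key(reference), key(universe))
  if (anyNA(ref_idx))
    stop("reference bins are not a subset of the universe")
  is_ref <- seq_len(nrow(universe)) %in% ref_idx
  gu <- fs_granges(universe)
  rows <- lapply(names(querysets), function(nm) {
    q <- querysets[[nm]]
    if (!nrow(q)) stop("query set '", nm, "' is empty")
    hit <- IRanges::overlapsAny(gu, fs_granges(q))
    a <- sum(is_ref & hit); b <- sum(is_ref & !hit)
    cc <- sum(!is_ref & hit); d <- sum(!is_ref & !hit)
    degenerate <- (b == 0 && d == 0) || (a == 0 && cc == 0)
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                            alternative = "greater")$p.value
    or <- (a * d) / (b * cc)
    data.frame(feature = nm, a = a, b = b, c = cc, d = d,
               odds_ratio = or, p = p, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$neg_log10_p <- -log10(out$p)
  rownames(out) <- NULL
  structure(out, class = c("enrichment_table", "data.frame"),
            universe_size = nrow(universe),
            significance_q = 0.05)
}
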