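#' QC parameter set
#'
#' Thresholds for the post-calling SNP filter cascade, applied in a fixed
#' order with per-rule accounting: (i) per-sample read depth inside
#' `[min_depth, max_depth_factor x sample mean]`; (ii) minimum mapping and
#' base quality; (iii) proximity to an indel; (iv) of any SNP pair closer
#' than `pair_radius`, drop the lower-quality one; (v) drop tri-allelic
#' sites; (vi) drop sites called in fewer than `1 - max_missing` of
#' samples; (vii) drop sites with a one-sided exact-test excess of
#' heterozygosity at `hwe_p`.
#'
#' @param min_depth Minimum per-sample depth (default 5x).
#' @param max_depth_factor Maximum depth as a multiple of the per-sample
#'   average (default 2).
#' @param depth_fail_fraction A site fails the depth rule when more than
#'   this fraction of samples is outside the depth window. The depth bounds
#'   are applied per sample; this aggregation choice is exposed because the
#'   per-site semantics of a per-sample window are otherwise ambiguous.
#' @param min_mq,min_bq Minimum mapping / base quality (site-level).
#' @param indel_radius Exclusion radius around indels, bp.
#' @param pair_radius SNP pairs separated by fewer than this many bp
#'   trigger rule (iv).
#' @param max_missing Maximum fraction of missing calls (default 0.10,
#'   i.e. a 90% call-rate floor).
#' @param hwe_p One-sided exact-test p-value threshold for heterozygote
#'   excess, pooled over populations.
#' @return A `qc_params` list.
#' @export
qc_params <- function(min_depth = 5, max_depth_factor = 2,
                      depth_fail_fraction = 0.5,
                      min_mq = 30, min_bq = 20,
                      indel_radius = 5L, pair_radius = 4L,
                      max_missing = 0.10, hwe_p = 0.001) {
  stopifnot(min_depth > 0, max_depth_factor > 0, min_mq > 0, min_bq > 0,
            indel_radius == as.integer(indel_radius), indel_radius >= 0,
            pair_radius == as.integer(pair_radius), pair_radius >= 0,
            max_missing >= 0, max_missing < 1, hwe_p > 0)
  structure(list(min_depth = min_depth,
                 max_depth_factor = max_depth_factor,
                 depth_fail_fraction = depth_fail_fraction,
                 min_mq = min_mq, min_bq = min_bq,
                 indel_radius = as.integer(indel_radius),
                 pair_radius = as.integer(pair_radius),
                 max_missing = max_missing, hwe_p = hwe_p),
            class = "qc_params")
}

#' Exact one-sided test for heterozygote excess
#'
#' Levene's conditional distribution of the heterozygote count given the
#' allele counts, enumerated directly in log space; the p-value is the
#' upper tail `P(het >= observed)`, i.e. one-sided toward heterozygote
#' excess.
#'
#' @param n_het Observed heterozygote count.
#' @param n_alt Alternate allele count.
#' @param n_ind Called diploid individuals.
#' @return p-value in (0, 1\].
#' @export
hwe_excess_p <- function(n_het, n_alt, n_ind) {
  if (n_ind == 0) return(1)
  n_rare <- min(n_alt, 2 * n_ind - n_alt)
  if (n_rare == 0) return(1)
  h <- seq(n_rare %% 2, n_rare, by = 2)
  logp <- lgamma(n_ind + 1) -
    lgamma((n_rare - h) / 2 + 1) - lgamma(h + 1) -
    lgamma(n_ind - (n_rare + h) / 2 + 1) +
    h * log(2) +
    lgamma(n_rare + 1) + lgamma(2 * n_ind - n_rare + 1) -
    lgamma(2 * n_ind + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sum(p[h >= n_het])
}

## internal: vectorized, cached excess-het p over sites
hwe_excess_p_sites <- function(n_het, n_alt, n_ind) {
  key <- paste(n_het, n_alt, n_ind)
  u <- !duplicated(key)
  pu <- mapply(hwe_excess_p, n_het[u], n_alt[u], n_ind[u])
  names(pu) <- key[u]
  unname(pu[key])
}

#' Apply the SNP QC cascade
#'
#' Applies the seven filters of [qc_params()] in their fixed order, with
#' first-hit attribution: each removed site is charged to the first rule
#' that rejects it, so the per-rule counts plus the survivors partition the
#' input. The cascade is idempotent.
#'
#' @param v A [variant_table()]. Rules (i)-(iii) require the depth matrix,
#'   `mq`/`bq` site columns and indel positions respectively; a missing
#'   annotation is an error naming the rule that needs it.
#' @param params A [qc_params()].
#' @return List with `variants` (the surviving [variant_table()]) and
#'   `report` (a `qc_report`: per-rule removed counts and survivor count).
#' @export
apply_qc <- function(v, params = qc_params()) {
  stopifnot(inherits(v, "variant_table"), inherits(params, "qc_params"))
  ns <- n_sites(v)
  rules <- c("depth", "quality", "near_indel", "close_pair",
             "triallelic", "call_rate", "hwe_excess_het")
  removed <- stats::setNames(integer(length(rules)), rules)
  alive <- rep(TRUE, ns)

  kill <- function(rule, idx) {
    idx <- idx[alive[idx]]
    removed[[rule]] <<- removed[[rule]] + length(idx)
    alive[idx] <<- FALSE
  }

  ## (i) per-sample depth window; the per-sample average is a property of
  ## the sequencing run, so it is computed once and carried with the table
  ## (this also makes the cascade idempotent)
  if (is.null(v$depth))
    stop("depth rule (i) requires a per-sample depth matrix")
  smean <- attr(v, "sample_mean_depth") %||%
    colMeans(v$depth, na.rm = TRUE)
  ## column-wise pass keeps peak memory at one column, not one matrix copy
  nfail <- integer(ns)
  for (j in seq_len(ncol(v$depth))) {
    d <- v$depth[, j]
    f <- is.na(d) | d < params$min_depth |
      d > params$max_depth_factor * smean[j]
    nfail <- nfail + f
  }
  kill("depth",
       which(nfail / ncol(v$depth) > params$depth_fail_fraction))

  ## (ii) mapping / base quality
  if (is.null(v$sites$mq) || is.null(v$sites$bq))
    stop("quality rule (ii) requires site columns 'mq' and 'bq'")
  kill("quality", which(v$sites$mq < params$min_mq |
                          v$sites$bq < params$min_bq))

  ## (iii) within indel_radius of an indel
  if (is.null(v$indels))
    stop("indel-proximity rule (iii) requires indel positions ",
         "(set indels = data.frame(chrom, pos))")
  if (nrow(v$indels)) {
    gs <- GenomicRanges::GRanges(v$sites$chrom,
                                 IRanges::IRanges(v$sites$pos, width = 1))
    gi <- GenomicRanges::GRanges(
      v$indels$chrom,
      IRanges::IRanges(pmax(1, v$indels$pos - params$indel_radius),
                       v$indels$pos + params$indel_radius))
    kill("near_indel",
         which(IRanges::overlapsAny(gs, gi)))
  }

  ## (iv) close pairs: drop the lower-quality member
  if (is.null(v$sites$qual))
    stop("close-pair rule (iv) requires a site 'qual' column")
  repeat {
    idx <- which(alive)
    o <- idx[order(v$sites$chrom[idx], v$sites$pos[idx])]
    same <- v$sites$chrom[o[-1]] == v$sites$chrom[o[-length(o)]]
    gap <- diff(v$sites$pos[o])
    pair <- which(same & gap < params$pair_radius)
    if (!length(pair)) break
    left <- o[pair]; right <- o[pair + 1]
    ql <- v$sites$qual[left]; qr <- v$sites$qual[right]
    victim <- ifelse(ql < qr, left, right)  # tie keeps the earlier site
    kill("close_pair", unique(victim))
  }

  ## (v) tri-allelic
  kill("triallelic", which(v$sites$multiallelic))

  ## (vi) call rate
  callrate <- rowMeans(!is.na(v$geno))
  kill("call_rate", which(callrate < 1 - params$max_missing))

  ## (vii) excess heterozygosity (exact, pooled over populations)
  idx <- which(alive)
  n_ind <- rowSums(!is.na(v$geno[idx, , drop = FALSE]))
  n_alt <- rowSums(v$geno[idx, , drop = FALSE], na.rm = TRUE)
  n_het <- rowSums(v$geno[idx, , drop = FALSE] == 1, na.rm = TRUE)
  ## cheap prefilter: only sites with more heterozygotes than expected can
  ## have a small upper-tail p
  p_hat <- n_alt / (2 * n_ind)
  exp_het <- 2 * p_hat * (1 - p_hat) * n_ind
  test <- which(n_het > exp_het)
  if (length(test)) {
    p <- hwe_excess_p_sites(n_het[test], n_alt[test], n_ind[test])
    kill("hwe_excess_het", idx[test[p < params$hwe_p]])
  }

  report <- structure(list(removed = removed,
                           input = ns, survivors = sum(alive)),
                      class = "qc_report")
  stopifnot(sum(removed) + report$survivors == ns)
  out <- subset_sites(v, alive)
  attr(out, "sample_mean_depth") <- smean
  list(variants = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC cascade report\n")
  for (r in names(x$removed))
    cat(sprintf("  %-16s removed %d\n", r, x$removed[[r]]))
  cat(sprintf("  input %d -> survivors %d\n", x$input, x$survivors))
  invisible(x)
}

#' Write a QC report as TSV
#' @param report A `qc_report` from [apply_qc()].
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  d <- data.frame(rule = c(names(report$removed), "survivors"),
                  count = c(unname(report$removed), report$survivors))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
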