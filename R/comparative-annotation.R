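## internal: per-chain block coordinate table, with minus-strand target
## blocks converted to forward-frame coordinates
chain_block_table <- function(chains) {
  data.table::rbindlist(lapply(seq_along(chains), function(ci) {
    ch <- chains[[ci]]
    b <- ch$blocks
    s_start <- ch$s_start + c(0, cumsum(b$size + b$ds))[seq_len(nrow(b))]
    t_start <- ch$t_start + c(0, cumsum(b$size + b$dt))[seq_len(nrow(b))]
    s_end <- s_start + b$size
    t_end <- t_start + b$size
    rev <- !is.null(ch$t_strand) && ch$t_strand == "-"
    if (rev) {
      fw_start <- ch$t_size - t_end
      fw_end <- ch$t_size - t_start
      t_start <- fw_start; t_end <- fw_end
    }
    data.table::data.table(chain = ci, s_chrom = ch$s_chrom,
                           s_start = s_start, s_end = s_end,
                           t_chrom = ch$t_chrom,
                           t_start = t_start, t_end = t_end,
                           reversed = rev, score = ch$score)
  }))
}

#' Project intervals through alignment chains
#'
#' Chain-based coordinate projection with a minimum-match criterion, the
#' mechanism behind liftOver-style cross-species annotation transfer. An
#' interval maps when at least `min_match` of its bases lie in the aligned
#' blocks of a single chain; the projected interval is the span of the
#' projected block intersections on the target genome (so bases deleted on
#' the target shorten the projection). Intervals whose aligned bases are
#' split across more than one chain are rejected with status `"split"`
#' rather than stitched. Minus-strand chains flip coordinates into the
#' forward frame of the target.
#'
#' @param x A [feature_set()] on the chains' source genome.
#' @param chains A `chain_set` from [read_chain()] or [simulate_chain()].
#' @param min_match Minimum fraction of interval bases inside aligned
#'   blocks of the chosen chain (default 0.1).
#' @return A `projection_result` data.frame, one row per input interval:
#'   source coordinates, `status` (`mapped`, `split`, `below_minmatch`,
#'   `unmapped`), matched-base `fraction`, and target coordinates
#'   (`t_chrom`, `t_start`, `t_end`; `NA` unless mapped).
#' @export
project_intervals <- function(x, chains, min_match = 0.1) {
  stopifnot(inherits(x, "feature_set"), inherits(chains, "chain_set"),
            min_match >= 0, min_match <= 1)
  n <- nrow(x)
  out <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                    status = rep("unmapped", n),
                    fraction = rep(0, n),
                    t_chrom = rep(NA_character_, n),
                    t_start = rep(NA_real_, n),
                    t_end = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (!n || !length(chains)) {
    class(out) <- c("projection_result", "data.frame")
    return(out)
  }
  bt <- chain_block_table(chains)
  gq <- GenomicRanges::GRanges(x$chrom,
                               IRanges::IRanges(x$start + 1, x$end))
  gb <- GenomicRanges::GRanges(bt$s_chrom,
                               IRanges::IRanges(bt$s_start + 1, bt$s_end))
  h <- GenomicRanges::findOverlaps(gq, gb)
  qi <- S4Vectors::queryHits(h); bi <- S4Vectors::subjectHits(h)
  if (!length(qi)) {
    class(out) <- c("projection_result", "data.frame")
    return(out)
  }
  ov_start <- pmax(x$start[qi], bt$s_start[bi])
  ov_end <- pmin(x$end[qi], bt$s_end[bi])
  ## project each overlapped block portion onto the target
  rev <- bt$reversed[bi]
  p_start <- ifelse(rev,
                    bt$t_start[bi] + (bt$s_end[bi] - ov_end),
                    bt$t_start[bi] + (ov_start - bt$s_start[bi]))
  p_end <- p_start + (ov_end - ov_start)
  hits <- data.table::data.table(q = qi, chain = bt$chain[bi],
                                 matched = ov_end - ov_start,
                                 p_start = p_start, p_end = p_end,
                                 t_chrom = bt$t_chrom[bi],
                                 score = bt$score[bi])
  per_chain <- hits[, list(matched = sum(matched),
                           p_start = min(p_start), p_end = max(p_end),
                           t_chrom = t_chrom[1], score = score[1]),
                    by = c("q", "chain")]
  nchain <- per_chain[, list(k = .N), by = "q"]
  split_q <- nchain$q[nchain$k > 1]
  out$status[split_q] <- "split"
  single <- per_chain[!per_chain$q %in% split_q, ]
  if (nrow(single)) {
    frac <- single$matched / (x$end[single$q] - x$start[single$q])
    out$fraction[single$q] <- frac
    ok <- frac >= min_match & frac > 0
    mq <- single$q[ok]
    out$status[mq] <- "mapped"
    out$status[single$q[!ok]] <- "below_minmatch"
    out$t_chrom[mq] <- single$t_chrom[ok]
    out$t_start[mq] <- single$p_start[ok]
    out$t_end[mq] <- single$p_end[ok]
  }
  class(out) <- c("projection_result", "data.frame")
  out
}

#' Extract the mapped intervals of a projection as a feature set
#'
#' @param pr A `projection_result` from [project_intervals()].
#' @param class Feature class for the returned set (defaults to
#'   `"projected"`).
#' @return A [feature_set()] of the target-genome intervals of rows with
#'   status `mapped`, in row order; attribute `source_row` records the
#'   originating row of `pr`.
#' @export
projected_features <- function(pr, class = "projected") {
  stopifnot(inherits(pr, "projection_result"))
  i <- which(pr$status == "mapped")
  fs <- feature_set(pr$t_chrom[i], pr$t_start[i], pr$t_end[i],
                    class = class)
  attr(fs, "source_row") <- i
  fs
}

#' Reciprocal-mapping filter
#'
#' Keeps a projected interval only when its back-projection through the
#' reciprocal chains lands on the original interval: same chromosome and
#' at least `min_back_overlap` of the source interval's length recovered.
#' This is the bidirectional ("reciprocal liftOver") criterion that guards
#' against paralogous or ambiguous mappings.
#'
#' @param forward A `projection_result` for the source intervals.
#' @param backward A `projection_result` obtained by projecting
#'   `projected_features(forward)` through the reciprocal chains; rows
#'   correspond, in order, to the `mapped` rows of `forward`.
#' @param min_back_overlap Minimum fraction of the source interval covered
#'   by the back-projection (default 0.5).
#' @return The retained target intervals as a [feature_set()]; attribute
#'   `source_row` gives their rows in `forward`.
#' @export
reciprocal_filter <- function(forward, backward, min_back_overlap = 0.5) {
  stopifnot(inherits(forward, "projection_result"),
            inherits(backward, "projection_result"))
  fwd_i <- which(forward$status == "mapped")
  if (nrow(backward) != length(fwd_i))
    stop("backward must have one row per mapped forward interval")
  if (!length(fwd_i))
    return(feature_set(character(), numeric(), numeric(),
                       class = "reciprocal"))
  src_start <- forward$start[fwd_i]
  src_end <- forward$end[fwd_i]
  src_chrom <- forward$chrom[fwd_i]
  back_ok <- backward$status == "mapped" &
    !is.na(backward$t_chrom) & backward$t_chrom == src_chrom
  ov <- pmax(0, pmin(backward$t_end, src_end) -
               pmax(backward$t_start, src_start))
  keep <- back_ok & ov >= min_back_overlap * (src_end - src_start)
  keep[is.na(keep)] <- FALSE
  fs <- feature_set(forward$t_chrom[fwd_i][keep],
                    forward$t_start[fwd_i][keep],
                    forward$t_end[fwd_i][keep],
                    class = "reciprocal")
  attr(fs, "source_row") <- fwd_i[keep]
  fs
}

#' One-call reciprocal projection
#'
#' Convenience wrapper: forward projection, back-projection of the mapped
#' intervals through the reciprocal chains, and the [reciprocal_filter()].
#'
#' @param x A [feature_set()] on the source genome.
#' @param chains_fwd,chains_bwd Forward and reciprocal `chain_set`s.
#' @param min_match Minimum matched-base fraction for both directions.
#' @param min_back_overlap See [reciprocal_filter()].
#' @return List: `forward` and `backward` `projection_result`s and
#'   `retained` (the filtered target [feature_set()]).
#' @export
reciprocal_project <- function(x, chains_fwd, chains_bwd, min_match = 0.1,
                               min_back_overlap = 0.5) {
  fwd <- project_intervals(x, chains_fwd, min_match)
  mapped <- projected_features(fwd)
  bwd <- project_intervals(mapped, chains_bwd, min_match)
  list(forward = fwd, backward = bwd,
       retained = reciprocal_filter(fwd, bwd, min_back_overlap))
}
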