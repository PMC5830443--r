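#' Genome layout
#'
#' A genome layout is the ordered table of chromosome names and lengths that
#' every interval container is validated against, and the sampling space for
#' [shuffle_features()]. Coordinates throughout the package are 0-based,
#' half-open; VCF positions are converted at the boundary.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in bp (> 0).
#' @return A `genome_layout` object (data.frame with columns `chrom`,
#'   `length`).
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (length(chrom) != base::length(length))
    stop("chrom and length differ in length")
  if (any(!is.finite(length)) || any(length <= 0))
    stop("chromosome lengths must be positive")
  structure(data.frame(chrom = chrom, length = length,
                       stringsAsFactors = FALSE),
            class = c("genome_layout", "data.frame"))
}

#' @rdname genome_layout
#' @param path Path to a two-column TSV (`chrom<TAB>length`, no header).
#' @export
read_genome_layout <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "length"))
  genome_layout(d$chrom, d$length)
}

#' @rdname genome_layout
#' @param layout A `genome_layout`.
#' @export
write_genome_layout <- function(layout, path) {
  stopifnot(inherits(layout, "genome_layout"))
  utils::write.table(
    data.frame(layout$chrom, format(layout$length, scientific = FALSE,
                                    trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Total genome length
#' @param layout A `genome_layout`.
#' @return Total length in bp.
#' @export
genome_size <- function(layout) sum(layout$length)

#' Feature sets: named collections of genomic intervals
#'
#' A `feature_set` holds intervals of one feature class (a chromatin state
#' such as `TssA` or `Enh`, a gene-model part such as `CDS`, a ChIP-seq peak
#' set, a set of scan bins, ...). Intervals are 0-based half-open. Intervals
#' may overlap within a set.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 0-based half-open.
#' @param name Optional per-interval names.
#' @param strand Optional strand (`+`, `-` or `.`).
#' @param class Feature class label for the whole set (e.g. `"TssA"`).
#' @param source Source tag: one of `"roadmap_state"`, `"encode_mark"`,
#'   `"gene_model"`, `"chipseq_peak"`, `"sweep_bin"`, or `NA`.
#' @param layout Optional `genome_layout`; when given, intervals are checked
#'   to lie within chromosome bounds.
#' @return A `feature_set` (data.frame with columns `chrom`, `start`, `end`,
#'   `name`, `strand`; attributes `feature_class` and `source_tag`).
#' @examples
#' feature_set("chr1", 100, 200, class = "TssA")
#' @export
feature_set <- function(chrom, start, end, name = NULL, strand = NULL,
                        class = "feature", source = NA_character_,
                        layout = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(start)
  if (length(chrom) == 1L && n > 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(end) != n)
    stop("chrom, start, end must have equal length")
  if (n && any(start < 0)) stop("negative start coordinate")
  if (n && any(start >= end)) stop("interval with start >= end")
  if (is.null(name)) name <- rep(NA_character_, n)
  if (is.null(strand)) strand <- rep(".", n)
  strand <- as.character(strand)
  if (n && !all(strand %in% c("+", "-", ".")))
    stop("strand must be one of +, -, .")
  x <- data.frame(chrom = chrom, start = start, end = end,
                  name = as.character(name), strand = strand,
                  stringsAsFactors = FALSE)
  x <- structure(x, class = c("feature_set", "data.frame"),
                 feature_class = class, source_tag = source)
  if (!is.null(layout)) validate_features(x, layout)
  x
}

#' @rdname feature_set
#' @param x A `feature_set`.
#' @export
feature_class <- function(x) attr(x, "feature_class")

#' Validate a feature set against a genome layout
#'
#' Checks that every interval lies on a known chromosome and within its
#' bounds. Called by constructors when a layout is supplied.
#'
#' @param x A `feature_set`.
#' @param layout A `genome_layout`.
#' @return `x`, invisibly; errors otherwise.
#' @export
validate_features <- function(x, layout) {
  i <- match(x$chrom, layout$chrom)
  if (anyNA(i)) {
    bad <- unique(x$chrom[is.na(i)])
    stop("chromosome(s) not in layout: ", paste(bad, collapse = ", "))
  }
  if (any(x$end > layout$length[i]))
    stop("interval(s) extend beyond chromosome length")
  invisible(x)
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set '%s' (%s): %d interval(s)\n",
              attr(x, "feature_class"),
              ifelse(is.na(attr(x, "source_tag")), "untagged",
                     attr(x, "source_tag")),
              nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

## internal: feature_set -> GRanges (1-based closed)
fs_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
}

## internal: restore data.frame rows as a feature_set keeping attributes
fs_subset <- function(x, i) {
  out <- as.data.frame(x)[i, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("feature_set", "data.frame"),
            feature_class = attr(x, "feature_class"),
            source_tag = attr(x, "source_tag"))
}

## internal: run expr with a private RNG stream, restoring caller state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read / write BED files
#'
#' BED3+ dialect, 0-based half-open, tab separated. Columns beyond the sixth
#' are ignored on read. Round trips are lossless for coordinates, names and
#' strand.
#'
#' @param path File path.
#' @param class_name Feature class label to attach to the returned set
#'   (defaults to the file's base name).
#' @param source Source tag for the returned set.
#' @return `read_bed`: a [feature_set()]. `write_bed`: `path`, invisibly.
#' @export
read_bed <- function(path, class_name = NULL, source = NA_character_) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keep <- !grepl("^(track|browser|#)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (is.null(class_name))
    class_name <- sub("\\.bed$", "", basename(path))
  if (!length(lines))
    return(feature_set(character(), integer(), integer(),
                       class = class_name, source = source))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED line ", lineno[which(nf < 3)[1]], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("BED line ", lineno[which(is.na(start) | is.na(end))[1]],
         ": non-numeric coordinate")
  if (any(start < 0))
    stop("BED line ", lineno[which(start < 0)[1]], ": negative start")
  if (any(start >= end))
    stop("BED line ", lineno[which(start >= end)[1]], ": start >= end")
  name <- ifelse(nf >= 4, vapply(fields, function(f)
    if (length(f) >= 4) f[[4]] else NA_character_, ""), NA_character_)
  strand <- ifelse(nf >= 6, vapply(fields, function(f)
    if (length(f) >= 6) f[[6]] else ".", ""), ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  name[name == "."] <- NA_character_
  feature_set(chrom, start, end, name = name, strand = strand,
              class = class_name, source = source)
}

#' @rdname read_bed
#' @param x A [feature_set()].
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "feature_set"))
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
  has_name <- any(!is.na(x$name))
  has_strand <- any(x$strand != ".")
  cols <- list(x$chrom, fmt(x$start), fmt(x$end))
  if (has_name || has_strand)
    cols <- c(cols, list(ifelse(is.na(x$name), ".", x$name)))
  if (has_strand) cols <- c(cols, list("0", x$strand))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write UCSC chain files
#'
#' Parses pairwise alignment chains. The chain header's target (`tName`)
#' side is treated as the projection *source* and the query (`qName`) side
#' as the projection *target*, matching how liftOver-style tools consume
#' chains. Block arithmetic is validated: aligned block sizes plus gaps must
#' tile the source and target spans exactly.
#'
#' @param path Chain file path.
#' @return A `chain_set`: a list of chains, each a list with fields
#'   `score`, `id`, `s_chrom`, `s_size`, `s_start`, `s_end`, `t_chrom`,
#'   `t_size`, `t_strand`, `t_start`, `t_end` and `blocks`
#'   (data.frame `size`, `ds` source gap, `dt` target gap). Minus-strand
#'   target coordinates are kept in the chain's reversed frame, as in the
#'   file.
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  chains <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(lines[i]) || grepl("^#", lines[i])) { i <- i + 1L; next }
    h <- strsplit(lines[i], "[ \t]+")[[1]]
    if (h[1] != "chain" || length(h) < 12)
      stop("malformed chain header at line ", i)
    ch <- list(score = as.numeric(h[2]),
               s_chrom = h[3], s_size = as.numeric(h[4]),
               s_strand = h[5],
               s_start = as.numeric(h[6]), s_end = as.numeric(h[7]),
               t_chrom = h[8], t_size = as.numeric(h[9]),
               t_strand = h[10],
               t_start = as.numeric(h[11]), t_end = as.numeric(h[12]),
               id = if (length(h) >= 13) h[13] else NA_character_)
    if (ch$s_strand != "+")
      stop("chain ", ch$id, ": source strand must be +")
    i <- i + 1L
    size <- ds <- dt <- numeric()
    repeat {
      if (i > n) stop("truncated chain file: chain ", ch$id,
                      " has no terminating block line")
      f <- suppressWarnings(as.numeric(strsplit(lines[i], "[ \t]+")[[1]]))
      if (anyNA(f)) stop("malformed block line ", i)
      if (length(f) == 1) {
        size <- c(size, f[1]); ds <- c(ds, 0); dt <- c(dt, 0)
        i <- i + 1L
        break
      } else if (length(f) == 3) {
        size <- c(size, f[1]); ds <- c(ds, f[2]); dt <- c(dt, f[3])
        i <- i + 1L
      } else stop("malformed block line ", i)
    }
    if (any(size < 0) || any(ds < 0) || any(dt < 0))
      stop("chain ", ch$id, ": negative block size or gap")
    ch$blocks <- data.frame(size = size, ds = ds, dt = dt)
    if (sum(size) + sum(ds) != ch$s_end - ch$s_start)
      stop("chain ", ch$id, ": blocks do not tile the source span")
    if (sum(size) + sum(dt) != ch$t_end - ch$t_start)
      stop("chain ", ch$id, ": blocks do not tile the target span")
    chains[[length(chains) + 1L]] <- ch
  }
  structure(chains, class = "chain_set")
}

#' @rdname read_chain
#' @param x A `chain_set`.
#' @export
write_chain <- function(x, path) {
  stopifnot(inherits(x, "chain_set"))
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
  out <- character()
  for (ch in x) {
    out <- c(out, paste("chain", fmt(ch$score), ch$s_chrom, fmt(ch$s_size),
                        "+", fmt(ch$s_start), fmt(ch$s_end),
                        ch$t_chrom, fmt(ch$t_size), ch$t_strand,
                        fmt(ch$t_start), fmt(ch$t_end),
                        if (is.na(ch$id)) "1" else ch$id))
    b <- ch$blocks
    k <- nrow(b)
    if (k > 1)
      out <- c(out, paste(fmt(b$size[-k]), fmt(b$ds[-k]), fmt(b$dt[-k])))
    out <- c(out, fmt(b$size[k]), "")
  }
  writeLines(out, path)
  invisible(path)
}

#' @export
print.chain_set <- function(x, ...) {
  cat(sprintf("chain_set: %d chain(s)\n", length(x)))
  invisible(x)
}

## internal: check the two sets live in the same chromosome namespace
check_namespace <- function(a, b) {
  if (nrow(a) && nrow(b) &&
      !length(base::intersect(unique(a$chrom), unique(b$chrom))))
    stop("feature sets share no chromosome names; ",
         "mismatched chromosome namespaces?")
}

#' Pairwise interval intersection
#'
#' Reports every overlapping pair between two feature sets, with the
#' overlapping sub-interval and its width.
#'
#' @param a,b [feature_set()]s on the same layout.
#' @return data.frame with columns `query` (row index in `a`), `subject`
#'   (row index in `b`), `chrom`, `start`, `end`, `width` of the overlap.
#' @examples
#' a <- feature_set("chr1", 0, 10)
#' b <- feature_set("chr1", 5, 15)
#' intersect_features(a, b)$width  # 5
#' @export
intersect_features <- function(a, b) {
  check_namespace(a, b)
  ga <- fs_granges(a); gb <- fs_granges(b)
  h <- GenomicRanges::findOverlaps(ga, gb)
  qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
  os <- pmax(a$start[qi], b$start[si])
  oe <- pmin(a$end[qi], b$end[si])
  data.frame(query = qi, subject = si, chrom = a$chrom[qi],
             start = os, end = oe, width = oe - os,
             stringsAsFactors = FALSE)
}

## internal: logical vector, does each a-interval overlap any b-interval?
## sort + running-maximum scan; avoids S4 construction cost in hot loops
overlaps_any_fast <- function(a, b) {
  out <- logical(nrow(a))
  if (!nrow(a) || !nrow(b)) return(out)
  for (ch in unique(a$chrom)) {
    ai <- which(a$chrom == ch)
    bi <- which(b$chrom == ch)
    if (!length(bi)) next
    o <- order(b$start[bi])
    bs <- b$start[bi][o]
    cummax_end <- cummax(b$end[bi][o])
    ## candidate: last b with start < a$end
    k <- findInterval(a$end[ai] - 1e-9, bs)
    hit <- k > 0 & ifelse(k > 0, cummax_end[pmax(k, 1)], 0) > a$start[ai]
    out[ai] <- hit
  }
  out
}

#' Count query intervals touching a subject set
#'
#' @param a,b [feature_set()]s on the same layout.
#' @return Number of intervals in `a` overlapping at least one interval of
#'   `b` by >= 1 bp.
#' @export
any_overlap <- function(a, b) {
  check_namespace(a, b)
  sum(overlaps_any_fast(a, b))
}

#' Closest interval and signed distance
#'
#' For each interval of `a`, finds the nearest interval of `b` on the same
#' chromosome. Distance is 0 when the intervals overlap (or are book-ended),
#' otherwise the gap in bp; the sign is positive when the nearest `b`
#' interval lies downstream (higher coordinates) of `a` and negative when
#' upstream. Ties at equal distance are broken toward the `b` interval with
#' the smaller start. Queries on chromosomes with no `b` interval get `NA`
#' (undefined), never 0.
#'
#' @param a,b [feature_set()]s on the same layout.
#' @return data.frame with columns `index` (row in `b` or `NA`), `distance`
#'   (absolute, bp), `signed_distance`.
#' @export
closest_features <- function(a, b) {
  check_namespace(a, b)
  n <- nrow(a)
  out <- data.frame(index = rep(NA_integer_, n),
                    distance = rep(NA_real_, n),
                    signed_distance = rep(NA_real_, n))
  if (!n || !nrow(b)) return(out)
  ga <- fs_granges(a); gb <- fs_granges(b)
  h <- GenomicRanges::distanceToNearest(ga, gb, select = "all",
                                        ignore.strand = TRUE)
  if (!length(h)) return(out)
  qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
  d <- S4Vectors::mcols(h)$distance
  ## tie-break: smallest subject start among equal-distance hits
  ord <- order(qi, d, b$start[si], si)
  first <- !duplicated(qi[ord])
  qi <- qi[ord][first]; si <- si[ord][first]; d <- d[ord][first]
  sign <- ifelse(b$end[si] <= a$start[qi], -1,
                 ifelse(b$start[si] >= a$end[qi], 1, 0))
  out$index[qi] <- si
  out$distance[qi] <- d
  out$signed_distance[qi] <- sign * d
  out
}

#' Randomly re-place intervals on the genome
#'
#' Places the same multiset of interval lengths uniformly at random across
#' the genome (any chromosome long enough), with no overlap among the placed
#' intervals. This is the randomization behind shuffle-null empirical
#' p-values.
#'
#' @param x A [feature_set()] giving the lengths to place.
#' @param layout A [genome_layout()].
#' @param seed Optional integer; fixed seed gives a deterministic placement
#'   without disturbing the caller's RNG state.
#' @param max_iter Re-proposal rounds before declaring the packing
#'   infeasible.
#' @return A [feature_set()] with the same lengths, shuffled placement.
#' @export
shuffle_features <- function(x, layout, seed = NULL, max_iter = 200L) {
  stopifnot(inherits(x, "feature_set"), inherits(layout, "genome_layout"))
  len <- x$end - x$start
  if (sum(len) >= genome_size(layout))
    stop("total feature length exceeds genome length; cannot shuffle")
  if (any(len > max(layout$length)))
    stop("an interval is longer than every chromosome")
  with_seed(seed, {
    n <- length(len)
    chrom <- character(n); start <- numeric(n)
    redo <- seq_len(n)
    ## propose all pending intervals at once, keep the non-conflicting ones
    for (iter in seq_len(max_iter)) {
      m <- length(redo)
      ## valid start count per (interval, chromosome)
      valid <- outer(len[redo], layout$length,
                     function(l, L) pmax(0, L - l + 1))
      tot <- rowSums(valid)
      u <- floor(stats::runif(m) * tot)  # 0-based position in start space
      cum <- cbind(0, matrix(t(apply(valid, 1, cumsum)), nrow = m))
      ci <- apply(u >= cum[, -ncol(cum), drop = FALSE] &
                    u < cum[, -1, drop = FALSE], 1, which.max)
      chrom[redo] <- layout$chrom[ci]
      start[redo] <- u - cum[cbind(seq_len(m), ci)]
      if (n == 1L) {
        return(feature_set(chrom, start, start + len, name = x$name,
                           class = attr(x, "feature_class"),
                           source = attr(x, "source_tag")))
      }
      ## self-overlap detection by a sorted sweep: within each chromosome
      ## an interval conflicts when it starts before the running maximum
      ## end of the intervals placed before it in sort order
      o <- order(chrom, start)
      sc <- chrom[o]; ss <- start[o]; se <- (start + len)[o]
      cm <- stats::ave(se, sc, FUN = cummax)  # running max end per chrom
      same <- c(FALSE, sc[-1] == sc[-n])
      conflict <- o[same & ss < c(-Inf, cm[-n])]
      if (!length(conflict)) {
        fs <- feature_set(chrom, start, start + len, name = x$name,
                          class = attr(x, "feature_class"),
                          source = attr(x, "source_tag"))
        return(fs)
      }
      redo <- conflict
    }
    stop("could not place intervals without overlap after ", max_iter,
         " rounds; packing infeasible?")
  })
}

#' Integer-truncated display percentage
#'
#' The display convention for recovery rates and shared-polymorphism
#' percentages: the exact fraction is truncated (not rounded) to a whole
#' percent.
#'
#' @param numerator,denominator Counts.
#' @return Integer percent, `floor(100 * numerator / denominator)`.
#' @examples
#' truncated_percent(13767, 16098)  # 85
#' @export
truncated_percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  as.integer(floor(100 * numerator / denominator))
}
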