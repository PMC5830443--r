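#' Variant tables
#'
#' The central container for per-site biallelic genotypes of the two
#' labelled populations (domestic and wild), with the per-site annotations
#' the QC cascade consumes. Positions are stored both 1-based (`pos`, as in
#' VCF) and 0-based half-open (`start`) for interval work.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based); optional
#'   `ref`, `alt`, `qual`, `mq`, `bq`, `multiallelic` (logical),
#'   `consequence`.
#' @param geno Integer matrix, sites x samples, counting alternate alleles
#'   (0, 1, 2; `NA` = missing call).
#' @param pop Factor or character of length `ncol(geno)` with levels
#'   `domestic` and `wild`.
#' @param depth Optional integer matrix of per-sample read depth,
#'   sites x samples.
#' @param indels Optional data.frame (`chrom`, `pos`, 1-based) of indel
#'   positions for the indel-proximity filter.
#' @param samples Optional sample names (default from `colnames(geno)`).
#' @return A `variant_table` object.
#' @export
variant_table <- function(sites, geno, pop, depth = NULL, indels = NULL,
                          samples = NULL) {
  geno <- as.matrix(geno)
  if (nrow(sites) != nrow(geno))
    stop("sites and genotype matrix differ in row count")
  pop <- factor(as.character(pop), levels = c("domestic", "wild"))
  if (anyNA(pop))
    stop("population labels must be 'domestic' or 'wild'")
  if (length(pop) != ncol(geno))
    stop("one population label per sample required")
  if (is.null(samples))
    samples <- colnames(geno) %||% paste0("S", seq_len(ncol(geno)))
  colnames(geno) <- samples
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.numeric(sites$pos)
  sites$start <- sites$pos - 1
  if (is.null(sites$multiallelic)) sites$multiallelic <- FALSE
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!all(dim(depth) == dim(geno)))
      stop("depth matrix must match genotype matrix dimensions")
  }
  structure(list(sites = sites, geno = geno, depth = depth,
                 pop = pop, samples = samples,
                 indels = indels),
            class = "variant_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf(paste0("variant_table: %d site(s), %d sample(s) ",
                     "(%d domestic, %d wild)\n"),
              nrow(x$sites), length(x$pop),
              sum(x$pop == "domestic"), sum(x$pop == "wild")))
  if (!is.null(x$indels))
    cat(sprintf("  %d indel position(s) carried for QC\n", nrow(x$indels)))
  invisible(x)
}

#' Number of sites in a variant table
#' @param v A [variant_table()].
#' @export
n_sites <- function(v) nrow(v$sites)

#' Subset a variant table by site index
#' @param v A [variant_table()].
#' @param i Integer or logical site index.
#' @return A [variant_table()] with the selected sites.
#' @export
subset_sites <- function(v, i) {
  out <- v
  out$sites <- v$sites[i, , drop = FALSE]
  rownames(out$sites) <- NULL
  out$geno <- v$geno[i, , drop = FALSE]
  if (!is.null(v$depth)) out$depth <- v$depth[i, , drop = FALSE]
  if (!is.null(attr(v, "truth"))) {
    tr <- attr(v, "truth")[i, , drop = FALSE]
    rownames(tr) <- NULL
    attr(out, "truth") <- tr
  }
  out
}

#' Read a VCF into a variant table
#'
#' Parses a VCF 4.x with per-sample GT (and DP when present) via `vcfR`.
#' SNP records are retained; records whose REF/ALT alleles are not all
#' single bases are set aside as indel positions for the QC cascade.
#' Multi-allelic SNP records (ALT with a comma) are kept but flagged
#' `multiallelic`, so the QC stage can remove them with attribution rather
#' than losing them silently. Malformed GT fields become missing calls and
#' their count is reported.
#'
#' @param path VCF path (plain text or bgzip).
#' @param population_map Named character vector mapping every sample name in
#'   the VCF to `"domestic"` or `"wild"`. A sample absent from the map is an
#'   error.
#' @return A [variant_table()].
#' @export
read_vcf <- function(path, population_map) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  missing <- setdiff(samples, names(population_map))
  if (length(missing))
    stop("sample(s) missing from population_map: ",
         paste(missing, collapse = ", "))
  pop <- as.character(population_map[samples])
  alt1 <- sub(",.*", "", fix$ALT)
  is_snp <- nchar(fix$REF) == 1 & nchar(alt1) == 1 & alt1 != "." &
    fix$REF != "."
  gt <- vcfR::extract.gt(vcf, element = "GT")
  allele_count <- function(g) {
    out <- rep(NA_integer_, length(g))
    g <- sub("\\|", "/", g)
    ok <- grepl("^[0-9.]/[0-9.]$", g) & !grepl("\\.", g)
    parts <- strsplit(g[ok], "/", fixed = TRUE)
    a1 <- as.integer(vapply(parts, `[[`, "", 1L))
    a2 <- as.integer(vapply(parts, `[[`, "", 2L))
    out[ok] <- (a1 > 0) + (a2 > 0)
    miss <- grepl("^\\./\\.$|^\\.$", g) | is.na(g)
    attr(out, "malformed") <- sum(!ok & !miss)
    out
  }
  malformed <- 0L
  geno <- matrix(NA_integer_, nrow(gt), ncol(gt),
                 dimnames = dimnames(gt))
  for (j in seq_len(ncol(gt))) {
    col <- allele_count(gt[, j])
    malformed <- malformed + attr(col, "malformed")
    geno[, j] <- col
  }
  if (malformed > 0)
    message("read_vcf: ", malformed,
            " malformed GT field(s) treated as missing")
  dp <- NULL
  if (any(grepl("DP", vcf@gt[, "FORMAT"])))
    dp <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  info_num <- function(key) {
    x <- suppressWarnings(vcfR::extract.info(vcf, element = key,
                                             as.numeric = TRUE))
    if (all(is.na(x))) NULL else x
  }
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  sites <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                      ref = fix$REF, alt = fix$ALT, qual = qual,
                      multiallelic = grepl(",", fix$ALT),
                      stringsAsFactors = FALSE)
  mq <- info_num("MQ"); bq <- info_num("BQ")
  if (!is.null(mq)) sites$mq <- mq
  if (!is.null(bq)) sites$bq <- bq
  csq <- suppressWarnings(vcfR::extract.info(vcf, element = "CSQ"))
  if (!all(is.na(csq))) sites$consequence <- csq
  indels <- sites[!is_snp, c("chrom", "pos")]
  rownames(indels) <- NULL
  variant_table(sites[is_snp, , drop = FALSE],
                geno[is_snp, , drop = FALSE], pop,
                depth = if (!is.null(dp)) dp[is_snp, , drop = FALSE],
                indels = if (nrow(indels)) indels)
}

#' Write a variant table as VCF
#'
#' Emits a plain-text VCF 4.2 with GT (and DP when depth is present) per
#' sample, `MQ`/`BQ`/`CSQ` INFO fields when available, and indel positions
#' as 2-bp deletion records so that [read_vcf()] round-trips the QC
#' annotations. Genotypes are written unphased.
#'
#' @param v A [variant_table()].
#' @param path Output path.
#' @param layout Optional [genome_layout()] for contig header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(v, path, layout = NULL) {
  s <- v$sites
  n <- nrow(s)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=sweepscape",
           '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
           '##INFO=<ID=BQ,Number=1,Type=Float,Description="RMS base quality">',
           '##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence class">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  if (!is.null(layout))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", layout$chrom,
                          as.integer(layout$length)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", v$samples),
                      collapse = "\t"))
  gt_str <- matrix("./.", n, ncol(v$geno))
  gt_str[v$geno == 0] <- "0/0"
  gt_str[v$geno == 1] <- "0/1"
  gt_str[v$geno == 2] <- "1/1"
  has_dp <- !is.null(v$depth)
  if (has_dp) {
    samp <- matrix(paste(gt_str, ifelse(is.na(v$depth), ".", v$depth),
                         sep = ":"), n, ncol(v$geno))
  } else samp <- gt_str
  info <- rep("", n)
  add_info <- function(info, key, val) {
    if (is.null(val)) return(info)
    piece <- ifelse(is.na(val), "", paste0(key, "=", val))
    ifelse(nzchar(info) & nzchar(piece), paste(info, piece, sep = ";"),
           paste0(info, piece))
  }
  info <- add_info(info, "MQ", if (!is.null(s$mq)) round(s$mq, 2))
  info <- add_info(info, "BQ", if (!is.null(s$bq)) round(s$bq, 2))
  info <- add_info(info, "CSQ", s$consequence)
  info[!nzchar(info)] <- "."
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  samp_cols <- lapply(seq_len(ncol(samp)), function(j) samp[, j])
  samp_str <- do.call(paste, c(samp_cols, sep = "\t"))
  lines <- paste(s$chrom, fmt(s$pos), ".",
                 s$ref %||% "A", s$alt %||% "T",
                 ifelse(is.na(s$qual %||% rep(NA, n)), ".",
                        fmt(round(s$qual %||% rep(NA, n), 1))),
                 "PASS", info,
                 if (has_dp) "GT:DP" else "GT",
                 samp_str,
                 sep = "\t")
  if (!is.null(v$indels) && nrow(v$indels)) {
    filler <- paste(rep(if (has_dp) "0/0:10" else "0/0",
                        length(v$samples)), collapse = "\t")
    ind <- paste(v$indels$chrom, fmt(v$indels$pos), ".", "AT", "A", "50",
                 "PASS", ".", if (has_dp) "GT:DP" else "GT", filler,
                 sep = "\t")
    lines <- c(lines, ind)
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Per-population allele frequencies
#'
#' Alternate-allele frequency per site for each population: alternate allele
#' count over called allele count, missing genotypes excluded from the
#' denominator. A population with no called genotype at a site is undefined
#' (`NA`) there.
#'
#' @param v A [variant_table()].
#' @return data.frame with columns `af_domestic`, `af_wild`,
#'   `n_domestic`, `n_wild` (called diploid individuals).
#' @export
population_af <- function(v) {
  out <- list()
  for (p in c("domestic", "wild")) {
    g <- v$geno[, v$pop == p, drop = FALSE]
    ncall <- rowSums(!is.na(g))
    af <- rowSums(g, na.rm = TRUE) / (2 * ncall)
    af[ncall == 0] <- NA_real_
    out[[paste0("af_", p)]] <- af
    out[[paste0("n_", p)]] <- ncall
  }
  as.data.frame(out)
}
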