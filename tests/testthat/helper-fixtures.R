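# Fixtures built in code, shared across test files. Expensive objects are
# cached for the duration of the run.

ss_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = ss_cache))
    assign(key, expr, envir = ss_cache)
  get(key, envir = ss_cache)
}

## the default study-condition scan, shared by the heavier tests; only
## the light objects are cached (the genotype matrices are large)
default_sim <- function() cached("default_sim", {
  cfg <- sim_config(seed = 1L)
  v <- simulate_variants(cfg)
  qc <- apply_qc(v)
  rm(v)
  w <- call_outliers(window_stats(qc$variants, cfg$layout))
  out <- list(cfg = cfg, report = qc$report, windows = w)
  rm(qc); gc(verbose = FALSE)
  out
})

## a small variant table with explicit genotypes; all QC annotations clean
## unless overridden
toy_variants <- function(geno, pop, chrom = NULL, pos = NULL,
                         qual = NULL, mq = NULL, bq = NULL,
                         depth = NULL, indels = NULL,
                         multiallelic = NULL, consequence = NULL) {
  geno <- as.matrix(geno)
  ns <- nrow(geno)
  sites <- data.frame(
    chrom = chrom %||% rep("chr1", ns),
    pos = pos %||% seq(1000, by = 1000, length.out = ns),
    ref = "A", alt = "T",
    qual = qual %||% rep(60, ns),
    mq = mq %||% rep(50, ns),
    bq = bq %||% rep(35, ns),
    multiallelic = multiallelic %||% rep(FALSE, ns))
  if (!is.null(consequence)) sites$consequence <- consequence
  variant_table(sites, geno, pop,
                depth = depth %||% matrix(10, ns, ncol(geno)),
                indels = indels %||%
                  data.frame(chrom = character(), pos = numeric()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## 20-site QC fixture: rules (i)-(vii) each remove exactly one site.
## 24 samples so that call-rate and HWE violations are unambiguous.
qc_fixture <- function() {
  k <- 24
  ns <- 20
  pop <- rep(c("domestic", "wild"), c(16, 8))
  ## clean background: moderate-frequency sites, HWE-ish genotypes
  set.seed(42)
  geno <- matrix(rbinom(ns * k, 2, 0.3), ns, k)
  depth <- matrix(10, ns, k)
  qual <- rep(60, ns)
  mq <- rep(50, ns); bq <- rep(35, ns)
  multi <- rep(FALSE, ns)
  pos <- seq(10000, by = 10000, length.out = ns)

  ## (i) site 1: depth 1x in every sample
  depth[1, ] <- 1
  ## (ii) site 2: mapping quality 10
  mq[2] <- 10
  ## (iii) site 3: an indel 2 bp away
  indels <- data.frame(chrom = "chr1", pos = pos[3] + 2)
  ## (iv) sites 4 and 5 are 3 bp apart; site 5 has the lower quality
  pos[5] <- pos[4] + 3
  qual[5] <- 40
  ## (v) site 6: tri-allelic
  multi[6] <- TRUE
  ## (vi) site 7: called in 20/24 samples (83% < 90%)
  geno7 <- geno[7, ]; geno7[1:4] <- NA; geno <- rbind(geno[1:6, ],
                                                      geno7,
                                                      geno[8:ns, ])
  ## (vii) site 8: every sample heterozygous (extreme het excess)
  geno[8, ] <- 1L

  ## pos stays strictly increasing (site 5 sits between sites 4 and 6)
  toy_variants(geno, pop, pos = pos, qual = qual, mq = mq,
               bq = bq, depth = depth, indels = indels,
               multiallelic = multi)
}

## builds a query/subject pair in which exactly n_hit of n_query query
## intervals overlap the subject set
counted_overlap_sets <- function(n_query, n_hit, width = 100L) {
  gap <- 10L * width
  starts <- seq(0, by = gap, length.out = n_query)
  q <- feature_set("chr1", starts, starts + width, class = "query")
  s <- feature_set("chr1", starts[seq_len(n_hit)] + width %/% 2,
                   starts[seq_len(n_hit)] + width %/% 2 + width,
                   class = "subject")
  list(query = q, subject = s)
}

## random feature sets for property tests
random_features <- function(n, layout, max_len = 5000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ci <- sample.int(nrow(layout), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n) * (layout$length[ci] - len))
  feature_set(layout$chrom[ci], start, start + len)
}
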