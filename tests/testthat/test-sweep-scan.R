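make_site <- function(g1, g2) {
  toy_variants(matrix(c(g1, g2), nrow = 1),
               rep(c("domestic", "wild"), c(length(g1), length(g2))))
}

test_that("theta is exactly 1 for fixed differences and matches the ANOVA oracle", {
  v <- make_site(rep(0L, 10), rep(2L, 10))
  expect_identical(site_fst(v), 1)

  ## hand case: pop1 AA,AA,Aa,Aa (p = 0.75 alt-coded 2,2,1,1), pop2 mirrored
  g1 <- c(2L, 2L, 1L, 1L); g2 <- c(0L, 0L, 1L, 1L)
  v <- make_site(g1, g2)
  expect_equal(site_fst(v), wc_theta_anova(g1, g2), tolerance = 1e-12)

  ## identical genotype arrays in both populations: theta <= 0
  set.seed(5)
  for (i in 1:20) {
    g <- rbinom(8, 2, runif(1, 0.2, 0.8))
    if (length(unique(g)) == 1) next
    v <- make_site(g, g)
    th <- site_fst(v)
    expect_equal(th, wc_theta_anova(g, g), tolerance = 1e-12)
    expect_lte(th, 1e-12)
  }

  ## random configurations, including missing data
  set.seed(17)
  for (i in 1:200) {
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    g1 <- rbinom(n1, 2, runif(1)); g2 <- rbinom(n2, 2, runif(1))
    v <- make_site(g1, g2)
    expected <- wc_theta_anova(g1, g2)
    got <- site_fst(v)
    if (is.na(expected)) expect_true(is.na(got))
    else expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("theta is undefined for monomorphic or single-population sites", {
  expect_true(is.na(site_fst(make_site(rep(0L, 5), rep(0L, 5)))))
  expect_true(is.na(site_fst(make_site(c(1L, NA), rep(1L, 5)))))
})

test_that("window statistics aggregate sites correctly", {
  ## three sites with theta 0.1, 0.2, 0.6 cannot be dialed in directly;
  ## instead check the mean against per-site values on simulated data
  cfg <- sim_config(layout = genome_layout("chr1", 1e5), sweeps = list(),
                    seed = 23L, indel_rate = 0, triallelic_rate = 0)
  v <- simulate_variants(cfg)
  w <- window_stats(v, cfg$layout, bin_width = 20000, step = 20000,
                    min_snp = 1)
  th <- site_fst(v)
  bin1 <- v$sites$start >= 0 & v$sites$start < 20000
  expect_equal(w$mean_fst[1], mean(th[bin1], na.rm = TRUE))
  expect_equal(w$n_snp[1], sum(bin1))

  ## overlapping bins: every interior site is counted by two bins
  w2 <- window_stats(v, cfg$layout, bin_width = 20000, step = 10000,
                     min_snp = 1)
  expect_equal(sum(w2$n_snp),
               2 * n_sites(v) - sum(v$sites$start < 10000) -
                 sum(v$sites$start >= 9e4))

  ## a bin with fewer than min_snp SNPs is masked but keeps its count
  w3 <- window_stats(v, cfg$layout, min_snp = 1e6)
  expect_true(all(is.na(w3$mean_fst)))
  expect_true(all(w3$n_snp > 0))
})

test_that("pi estimator modes differ as documented", {
  g <- matrix(c(1L, 1L, 0L, 0L,
                2L, 0L, 2L, 0L), 2, 4, byrow = TRUE)
  v <- toy_variants(g, rep(c("domestic", "wild"), each = 2),
                    pos = c(100, 200))
  lay <- genome_layout("chr1", 1000)
  wu <- window_stats(v, lay, bin_width = 1000, step = 1000, min_snp = 1)
  wh <- window_stats(v, lay, bin_width = 1000, step = 1000, min_snp = 1,
                     pi_method = "het_count")
  ## site 1: both pops het at p = 0.5 -> unbiased 2*0.5*0.5*4/3 = 2/3
  ## site 2: p = 0.5, no hets -> unbiased 2/3, literal count 0
  expect_equal(wu$pi_domestic, (2 / 3 + 2 / 3) / 1000)
  expect_equal(wh$pi_domestic, 1 / 1000)
})

test_that("outlier calling uses joint Z thresholds and reports raw cutoffs", {
  w <- default_sim()$windows
  th <- attr(w, "thresholds")
  expect_equal(th$z, qnorm(0.999), tolerance = 1e-12)
  ok <- !is.na(w$mean_fst) & !is.na(w$ln_ratio)
  ## flagged bins exceed both raw thresholds
  fl <- w$outlier & ok & w$direction == "domestic"
  expect_true(all(w$mean_fst[which(fl)] > th$fst))
  expect_true(all(w$ln_ratio[which(fl)] > th$ln_ratio))
  ## unflagged unmasked bins fail at least one
  un <- ok & !w$outlier
  expect_true(all(w$mean_fst[un] <= th$fst | w$ln_ratio[un] <= th$ln_ratio |
                    w$ln_ratio[un] <= th$ln_ratio_wild))
})

test_that("outlier flags are invariant under affine rescaling", {
  w <- default_sim()$windows
  w2 <- w
  w2$mean_fst <- 3 * w2$mean_fst + 0.5
  w2$ln_ratio <- 0.2 * w2$ln_ratio - 1
  attr(w2, "class") <- attr(w, "class")
  f1 <- call_outliers(w[setdiff(names(w), c("z_fst", "z_ratio",
                                            "outlier", "direction"))],
                      0.001)
  f2 <- call_outliers(w2[setdiff(names(w2), c("z_fst", "z_ratio",
                                              "outlier", "direction"))],
                      0.001)
  expect_equal(f1$outlier, f2$outlier)
  expect_equal(f1$direction, f2$direction)
})

test_that("degenerate inputs to outlier calling are rejected", {
  v <- qc_fixture()
  w <- window_stats(v, genome_layout("chr1", 2e5), min_snp = 1)
  w$mean_fst[] <- 0.1
  w$ln_ratio[] <- 0.2
  expect_error(call_outliers(w), "zero variance")
})

test_that("region merging matches the transitive-closure oracle", {
  w0 <- default_sim()$windows
  tmpl <- w0[1:200, ]
  set.seed(41)
  for (i in 1:100) {
    f <- tmpl
    f$outlier <- runif(200) < 0.08
    f$direction <- ifelse(f$outlier, "domestic", NA)
    got <- merge_regions(f, gap = 50000)
    bf <- bf_merge(f[f$outlier, c("chrom", "start", "end")], 50000)
    expect_equal(got$chrom, bf$chrom)
    expect_equal(got$start, bf$start)
    expect_equal(got$end, bf$end)
  }
  ## two flagged bins 60 kb apart stay separate; overlapping neighbours fuse
  f <- tmpl
  f$outlier <- FALSE
  f$direction <- NA
  i1 <- which(f$chrom == f$chrom[1] & f$start == 100000)
  i2 <- which(f$chrom == f$chrom[1] & f$start == 200000)
  f$outlier[c(i1, i2)] <- TRUE
  f$direction[c(i1, i2)] <- "domestic"
  expect_equal(nrow(merge_regions(f, gap = 50000)), 2)  # 80 kb gap
  f$outlier[i2] <- FALSE; f$direction[i2] <- NA
  i3 <- which(f$chrom == f$chrom[1] & f$start == 110000)
  f$outlier[i3] <- TRUE; f$direction[i3] <- "domestic"
  m <- merge_regions(f, gap = 50000)
  expect_equal(nrow(m), 1)  # overlapping step-neighbours fuse
  expect_equal(m$end[1] - m$start[1], 30000)
})

test_that("closest-gene assignment handles overlap, gaps and empty chromosomes", {
  regions <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                        start = c(1000, 5000, 0),
                        end = c(2000, 6000, 500))
  genes <- feature_set("chr1", c(1500, 6500), c(1600, 7000),
                       name = c("A", "B"), class = "gene")
  got <- assign_genes(regions, genes)
  expect_equal(got$closest_gene, c("A", "B", NA))
  expect_equal(got$gene_distance, c(0, 500, NA))
  expect_error(assign_genes(regions, feature_set(character(), numeric(),
                                                 numeric())), "empty")
})

test_that("shared polymorphism counts match a hand count", {
  ## 10 sites: 4 shared, 3 domestic-private, 2 wild-private, 1 fixed in
  ## both populations
  gd <- rbind(c(1, 1), c(1, 0), c(2, 1), c(0, 1),   # segregating dom
              c(1, 1), c(0, 2), c(1, 0),            # segregating dom
              c(0, 0), c(2, 2),                     # monomorphic dom
              c(2, 2))
  gw <- rbind(c(1, 0), c(1, 1), c(0, 1), c(1, 2),   # segregating wild
              c(0, 0), c(2, 2), c(0, 0),            # monomorphic wild
              c(1, 1), c(1, 0),                     # segregating wild
              c(0, 0))
  v <- toy_variants(cbind(gd, gw), rep(c("domestic", "wild"), each = 2))
  s <- shared_polymorphism_summary(v)
  expect_equal(s$shared, 4)
  expect_equal(s$domestic_private, 3)
  expect_equal(s$wild_private, 2)
  expect_equal(s$pct_shared_of_domestic, truncated_percent(4, 7))
})

test_that("AF correlation has the right fixed points", {
  gd <- rbind(c(0, 1), c(1, 1), c(1, 2), c(2, 1), c(0, 1))
  v1 <- toy_variants(cbind(gd, gd), rep(c("domestic", "wild"), each = 2))
  expect_equal(af_correlation(v1)$r, 1)
  ga <- 2 - gd  # mirrored frequencies
  v2 <- toy_variants(cbind(gd, ga), rep(c("domestic", "wild"), each = 2))
  expect_equal(af_correlation(v2)$r, -1)
})

test_that("feature-restricted diversity is length-weighted and consistent", {
  cfg <- sim_config(layout = genome_layout("chr1", 2e5), sweeps = list(),
                    seed = 29L)
  v <- simulate_variants(cfg)
  whole <- feature_set("chr1", 0, 2e5, class = "all")
  halves <- list(
    left = feature_set("chr1", 0, 1e5, class = "left"),
    right = feature_set("chr1", 1e5, 2e5, class = "right"),
    all = whole)
  fp <- feature_pi(v, halves)
  ## identical-feature split reproduces the genome value
  w <- window_stats(v, cfg$layout, bin_width = 2e5, step = 2e5,
                    min_snp = 1)
  expect_equal(fp$pi_domestic[fp$class == "all"], w$pi_domestic)
  ## disjoint halves average (length-weighted) to the genome value
  lw <- (fp$pi_domestic[1] * 1e5 + fp$pi_domestic[2] * 1e5) / 2e5
  expect_equal(lw, w$pi_domestic)
})
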