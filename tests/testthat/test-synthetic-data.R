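test_that("variant generator is seed-deterministic and hits diversity targets", {
  cfg <- sim_config(layout = genome_layout("chr1", 5e6), sweeps = list(),
                    seed = 7L)
  v1 <- simulate_variants(cfg)
  v2 <- simulate_variants(cfg)
  expect_identical(v1$geno, v2$geno)
  expect_identical(v1$sites, v2$sites)

  w <- window_stats(v1, cfg$layout)
  expect_lt(abs(mean(w$pi_domestic, na.rm = TRUE) - cfg$pi_domestic),
            0.15 * cfg$pi_domestic)
  expect_lt(abs(mean(w$pi_wild, na.rm = TRUE) - cfg$pi_wild),
            0.15 * cfg$pi_wild)
})

test_that("overlapping sweep windows are rejected", {
  expect_error(sim_config(sweeps = list(
    sweep_spec("chr1", 1e6, 1.1e6), sweep_spec("chr1", 1.05e6, 1.2e6))),
    "overlap")
})

test_that("a planted sweep dominates the genome-wide tails", {
  cfg <- sim_config(layout = genome_layout("chr1", 5e6),
                    sweeps = list(sweep_spec("chr1", 2e6, 2.06e6,
                                             f_pi = 0.05, delta = 0.8)),
                    seed = 11L)
  v <- simulate_variants(cfg)
  w <- window_stats(v, cfg$layout)
  inside <- w$start >= 2e6 & w$end <= 2.06e6 & !is.na(w$mean_fst)
  q999_fst <- quantile(w$mean_fst[!inside], 0.999, na.rm = TRUE)
  q999_lnr <- quantile(w$ln_ratio[!inside], 0.999, na.rm = TRUE)
  expect_true(all(w$mean_fst[inside] > q999_fst))
  expect_true(all(w$ln_ratio[inside] > q999_lnr))
})

test_that("AF correlation matches the analytic attenuation at small noise", {
  sd <- 0.05
  cfg <- sim_config(layout = genome_layout("chr1", 5e6), sweeps = list(),
                    af_noise_sd = sd, loss_wild = 0, seed = 13L)
  v <- simulate_variants(cfg)
  got <- af_correlation(v)$r
  ## attenuation of corr(p_d, p_w) by drift noise plus binomial sampling
  ## noise of the realized allele frequencies
  a <- 1 / (2 * (cfg$n_domestic + cfg$n_wild))
  C <- 1 / log((1 - a) / a)
  Ep <- C * (1 - 2 * a)
  Ep2 <- C * ((1 - a)^2 - a^2) / 2
  v0 <- Ep2 - Ep^2
  epq <- Ep - Ep2
  vd <- epq / (2 * cfg$n_domestic)
  vw <- epq / (2 * cfg$n_wild)
  pred <- v0 / sqrt((v0 + sd^2 + vd) * (v0 + sd^2 + vw))
  expect_lt(abs(got - pred), 0.05)
})

test_that("feature geometry puts proximal classes nearer the TSS", {
  cfg <- sim_config(seed = 3L)
  f1 <- simulate_features(cfg)
  f2 <- simulate_features(cfg)
  expect_identical(f1$TssA$start, f2$TssA$start)
  tss <- ifelse(f1$gene$strand == "-", f1$gene$end, f1$gene$start)
  tssfs <- feature_set(f1$gene$chrom, tss, tss + 1)
  d_tssa <- median(closest_features(f1$TssA, tssfs)$distance,
                   na.rm = TRUE)
  d_enh <- median(closest_features(f1$Enh, tssfs)$distance,
                  na.rm = TRUE)
  expect_lt(d_tssa, d_enh)
  d_prox <- median(closest_features(f1$proximal, tssfs)$distance,
                   na.rm = TRUE)
  d_dist <- median(closest_features(f1$distal, tssfs)$distance,
                   na.rm = TRUE)
  expect_lt(d_prox, d_dist)

  f0 <- simulate_features(sim_config(n_genes = 0))
  expect_equal(nrow(f0$gene), 0)
  expect_equal(nrow(f0$TssA), 0)
})

test_that("peak recovery fraction is controlled", {
  lay <- genome_layout("chr1", 1e8)  # sparse: incidental overlap is rare
  pred <- random_features(2000, lay, max_len = 1000, seed = 21)
  expect_equal(recovery_rate(
    pred, simulate_peaks(pred, 1, 0, lay, seed = 1))$percent, 100L)
  p0 <- simulate_peaks(pred, 0, 0, lay, seed = 1)
  expect_equal(nrow(p0), 0)

  pk <- simulate_peaks(pred, 0.85, 0, lay, seed = 2)
  frac <- recovery_rate(pred, pk)$fraction
  ci <- qbinom(c(0.005, 0.995), 2000, 0.85) / 2000
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("simulated chains compose to the identity on block interiors", {
  lay <- genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
  ## zero indel rate: exact identity
  ch0 <- simulate_chain(lay, indel_rate = 0, seed = 1)
  fs <- random_features(50, lay, seed = 2)
  pr <- project_intervals(fs, ch0$forward)
  expect_true(all(pr$status == "mapped"))
  expect_equal(pr$t_start, fs$start)
  expect_equal(pr$t_end, fs$end)

  ## indels shift coordinates; round trip through the reciprocal chains
  ch <- simulate_chain(lay, indel_rate = 2e-5, seed = 3)
  rp <- reciprocal_project(fs, ch$forward, ch$backward, min_match = 0.1)
  back <- rp$backward
  ok <- back$status == "mapped"
  expect_gt(mean(ok), 0.8)
  src <- rp$forward[rp$forward$status == "mapped", ]
  ## intervals wholly inside aligned blocks return exactly
  exact <- ok & back$t_start == src$start & back$t_end == src$end
  expect_gt(mean(exact), 0.5)

  ## a single 100 bp deletion in the target shifts downstream coordinates
  del <- structure(list(list(
    score = 9900, s_chrom = "chr1", s_size = 1e4, s_strand = "+",
    s_start = 0, s_end = 1e4, t_chrom = "chr1", t_size = 9900,
    t_strand = "+", t_start = 0, t_end = 9900, id = "1",
    blocks = data.frame(size = c(5000, 4900), ds = c(100, 0),
                        dt = c(0, 0)))), class = "chain_set")
  down <- project_intervals(feature_set("chr1", 6000, 6500), del)
  expect_equal(down$t_start, 5900)
  expect_equal(down$t_end, 6400)
})

test_that("VCF round-trips genotypes, annotations and indels", {
  cfg <- sim_config(layout = genome_layout("chr1", 2e5), sweeps = list(),
                    n_genes = 0, seed = 5L)
  v <- simulate_variants(cfg)
  tf <- tempfile(fileext = ".vcf")
  write_vcf(v, tf, cfg$layout)
  pops <- setNames(as.character(v$pop), v$samples)
  back <- read_vcf(tf, pops)
  expect_equal(back$sites$pos, v$sites$pos)
  expect_equal(unname(back$geno), unname(v$geno))
  expect_equal(back$sites$mq, v$sites$mq, tolerance = 0.01)
  expect_equal(back$sites$consequence, v$sites$consequence)
  expect_equal(back$indels$pos, v$indels$pos)
  expect_equal(as.character(back$pop), as.character(v$pop))

  expect_error(read_vcf(tf, pops[-1]), "missing from population_map")
})

test_that("multi-allelic VCF records are kept but flagged", {
  tf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", "s1", "s2", sep = "\t"),
               "chr1\t100\t.\tG\tA\t50\tPASS\t.\tGT\t0/1\t0/0",
               "chr1\t200\t.\tC\tA,T\t50\tPASS\t.\tGT\t0/1\t1/1",
               "chr1\t300\t.\tT\tG\t50\tPASS\t.\tGT\t./.\t0/1"), tf)
  v <- read_vcf(tf, c(s1 = "domestic", s2 = "wild"))
  expect_equal(n_sites(v), 3)
  expect_equal(v$sites$multiallelic, c(FALSE, TRUE, FALSE))
  expect_true(is.na(v$geno[3, 1]))
})
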