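identity_chain <- function(chrom = "chr1", L = 1e5, t_chrom = chrom) {
  structure(list(list(
    score = L, s_chrom = chrom, s_size = L, s_strand = "+",
    s_start = 0, s_end = L, t_chrom = t_chrom, t_size = L,
    t_strand = "+", t_start = 0, t_end = L, id = "1",
    blocks = data.frame(size = L, ds = 0, dt = 0))),
    class = "chain_set")
}

## one chain with arbitrary blocks, for oracle comparisons
blocky_chain <- function(size, ds, dt, s_chrom = "chr1",
                         t_chrom = "chrB", t_strand = "+") {
  sL <- sum(size) + sum(ds); tL <- sum(size) + sum(dt)
  structure(list(list(
    score = sum(size), s_chrom = s_chrom, s_size = sL, s_strand = "+",
    s_start = 0, s_end = sL, t_chrom = t_chrom, t_size = tL,
    t_strand = t_strand,
    t_start = 0, t_end = tL, id = "1",
    blocks = data.frame(size = size, ds = ds, dt = dt))),
    class = "chain_set")
}

test_that("identity chains give identity mappings with fraction 1", {
  ch <- identity_chain()
  fs <- random_features(100, genome_layout("chr1", 1e5), seed = 2)
  pr <- project_intervals(fs, ch)
  expect_true(all(pr$status == "mapped"))
  expect_true(all(pr$fraction == 1))
  expect_equal(pr$t_start, fs$start)
  expect_equal(pr$t_end, fs$end)
})

test_that("minMatch gates mapping and is monotone", {
  ## 1000 bp interval with only 50 of its bases in blocks (5%)
  ch <- blocky_chain(size = c(50, 1000), ds = c(2000, 0), dt = c(0, 0))
  iv <- feature_set("chr1", 0, 1000)
  low <- project_intervals(iv, ch, min_match = 0.1)
  expect_equal(low$status, "below_minmatch")
  expect_equal(low$fraction, 0.05)
  ok <- project_intervals(iv, ch, min_match = 0.04)
  expect_equal(ok$status, "mapped")

  ## monotonicity: raising minMatch never increases the mapped set
  set.seed(9)
  lay <- genome_layout("chr1", 1e5)
  sim <- simulate_chain(lay, indel_rate = 5e-4, mean_indel = 400,
                        seed = 4)
  fs <- random_features(200, lay, max_len = 3000, seed = 5)
  mapped <- vapply(c(0, 0.1, 0.3, 0.6, 0.9, 1), function(mm)
    sum(project_intervals(fs, sim$forward, mm)$status == "mapped"),
    numeric(1))
  expect_true(all(diff(mapped) <= 0))
})

test_that("projected spans agree with the per-base oracle", {
  ## interval straddling a 100 bp target-side deletion
  ch <- blocky_chain(size = c(500, 500), ds = c(100, 0), dt = c(0, 0))
  iv <- feature_set("chr1", 300, 800)
  pr <- project_intervals(iv, ch)
  expect_equal(pr$status, "mapped")
  expect_equal(pr$t_end - pr$t_start,
               (800 - 300) - 100)  # 100 deleted bases
  bf <- bf_project_base(c(300, 800), ch[[1]])
  expect_equal(c(pr$t_start, pr$t_end), bf[1:2])
  expect_equal(pr$fraction, bf[3] / 500)

  ## random chains vs the oracle
  set.seed(13)
  for (i in 1:20) {
    nb <- sample(2:5, 1)
    ch <- blocky_chain(size = sample(50:500, nb),
                       ds = c(sample(0:300, nb - 1), 0),
                       dt = c(sample(0:300, nb - 1), 0))
    sL <- ch[[1]]$s_size
    a <- sample.int(sL - 10, 1); b <- a + sample.int(min(500, sL - a), 1)
    pr <- project_intervals(feature_set("chr1", a, b), ch, min_match = 0)
    bf <- bf_project_base(c(a, b), ch[[1]])
    if (is.null(bf)) {
      expect_true(pr$status %in% c("unmapped", "below_minmatch"))
    } else {
      expect_equal(c(pr$t_start, pr$t_end), bf[1:2])
    }
  }
})

test_that("minus-strand chains flip coordinates", {
  ch <- blocky_chain(size = 100, ds = 0, dt = 0, t_strand = "-")
  ch[[1]]$t_size <- 1000
  ch[[1]]$t_start <- 0; ch[[1]]$t_end <- 100  # reversed frame
  pr <- project_intervals(feature_set("chr1", 10, 20), ch)
  expect_equal(pr$status, "mapped")
  expect_equal(c(pr$t_start, pr$t_end), c(980, 990))
  bf <- bf_project_base(c(10, 20), ch[[1]])
  expect_equal(c(pr$t_start, pr$t_end), bf[1:2])
})

test_that("intervals split across chains are rejected", {
  two <- structure(c(blocky_chain(size = 500, ds = 0, dt = 0),
                     blocky_chain(size = 400, ds = 0, dt = 0)),
                   class = "chain_set")
  two[[2]]$s_start <- 600; two[[2]]$s_end <- 1000
  two[[2]]$s_size <- 1000
  two[[2]]$t_chrom <- "chrC"
  pr <- project_intervals(feature_set("chr1", 400, 700), two)
  expect_equal(pr$status, "split")
})

test_that("reciprocal filter keeps round trips and drops strays", {
  ch <- identity_chain()
  fs <- random_features(50, genome_layout("chr1", 1e5), seed = 6)
  rp <- reciprocal_project(fs, ch, ch)
  expect_equal(nrow(rp$retained), 50)

  ## back-projection to a different chromosome is dropped: the forward
  ## chain sends chr1 to chrB, but the backward chain returns chrB to chrX
  fwd <- identity_chain(t_chrom = "chrB")
  bwd <- identity_chain(chrom = "chrB", t_chrom = "chrX")
  rp2 <- reciprocal_project(fs, fwd, bwd)
  expect_equal(nrow(rp2$retained), 0)

  ## planted paralogy: the backward direction carries a second chain over
  ## the same target span, so every back-projection is ambiguous (split)
  bwd2 <- structure(c(identity_chain(chrom = "chrB", t_chrom = "chr1"),
                      identity_chain(chrom = "chrB", t_chrom = "chr2")),
                    class = "chain_set")
  rp3 <- reciprocal_project(fs, fwd, bwd2)
  expect_true(all(rp3$backward$status == "split"))
  expect_equal(nrow(rp3$retained), 0)
})

test_that("projection agrees with rtracklayer liftOver on shared ground", {
  sim <- simulate_chain(genome_layout("chr1", 5e4), indel_rate = 1e-3,
                        mean_indel = 50, seed = 8)
  tf <- tempfile(fileext = ".chain")
  write_chain(sim$forward, tf)
  ch <- rtracklayer::import.chain(tf)
  fs <- random_features(100, genome_layout("chr1", 5e4), max_len = 40,
                        seed = 9)
  ours <- project_intervals(fs, sim$forward, min_match = 1)
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(fs$start + 1, fs$end))
  lo <- rtracklayer::liftOver(gr, ch)
  n_lo <- S4Vectors::elementNROWS(lo)
  ## where liftOver returns a single unbroken interval and we mapped with
  ## full match, the coordinates must agree exactly
  both <- which(ours$status == "mapped" & n_lo == 1)
  expect_gt(length(both), 10)
  lo1 <- unlist(lo[both])
  expect_equal(ours$t_start[both],
               as.numeric(GenomicRanges::start(lo1) - 1))
  expect_equal(ours$t_end[both], as.numeric(GenomicRanges::end(lo1)))
})
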