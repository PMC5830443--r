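test_that("population allele frequencies are hand-countable", {
  ## 3 sites x (2 domestic + 2 wild)
  geno <- rbind(c(1, 1, 1, 1),       # all het -> 0.5 / 0.5
                c(0, 0, 0, 0),       # fixed ref -> 0
                c(2, 1, 0, NA))      # dom 3/4, wild 0/2
  v <- toy_variants(geno, c("domestic", "domestic", "wild", "wild"))
  af <- population_af(v)
  expect_equal(af$af_domestic, c(0.5, 0, 0.75))
  expect_equal(af$af_wild, c(0.5, 0, 0))
  expect_equal(af$n_wild[3], 1)
})

test_that("delta AF is restricted to shared-segregating sites and symmetric", {
  geno <- rbind(c(1, 1, 1, 1),   # shared, dAF 0
                c(2, 2, 1, 1),   # dom fixed -> excluded
                c(2, 1, 0, 1))   # dom 0.75, wild 0.25 -> 0.5
  v <- toy_variants(geno, c("domestic", "domestic", "wild", "wild"))
  d <- delta_af(v)
  expect_equal(nrow(d), 2)
  expect_equal(d$delta_af, c(0, 0.5))
  ## allele-label swap leaves delta unchanged
  v2 <- v; v2$geno <- 2L - v$geno
  expect_equal(delta_af(v2)$delta_af, d$delta_af)
})

## a delta-AF table with prescribed bin membership and feature geometry:
## sites at known positions, delta values set directly
manual_daf <- function(delta, pos = NULL, chrom = "chr1",
                       consequence = NULL) {
  d <- data.frame(chrom = chrom,
                  pos = pos %||% seq(1000, by = 1000,
                                     length.out = length(delta)),
                  stringsAsFactors = FALSE)
  d$start <- d$pos - 1
  d$af_domestic <- NA_real_; d$af_wild <- NA_real_
  d$delta_af <- delta
  if (!is.null(consequence)) d$consequence <- consequence
  d
}

test_that("M-values match the hand contingency and chi-squared summation", {
  ## two bins of 100 SNPs each; the feature holds 10 of the first and 30
  ## of the second
  delta <- c(runif(100, 0, 0.49), runif(100, 0.51, 1))
  daf <- manual_daf(delta)
  infeat <- c(seq_len(10), 100 + seq_len(30))
  feat <- feature_set("chr1", daf$start[infeat], daf$start[infeat] + 1,
                      class = "f")
  mv <- mvalue_table(daf, list(f = feat), bin_width = 0.5)
  expect_equal(unname(mv$total), c(100, 100))
  expect_equal(unname(mv$counts["f", ]), c(10, 30))
  expect_equal(unname(mv$M["f", ]),
               c(log2((10 / 100) / (40 / 200)),
                 log2((30 / 100) / (40 / 200))))
  expect_equal(unname(mv$M["f", ]), c(-1, log2(1.5)))
  ## chi-squared by direct summation: expected (20, 20)
  expect_equal(mv$chisq$statistic,
               (10 - 20)^2 / 20 + (30 - 20)^2 / 20)
  expect_equal(mv$chisq$df, 1)
})

test_that("proportionally distributed features have M identically 0", {
  delta <- rep(c(0.05, 0.15, 0.25, 0.35), each = 50)
  daf <- manual_daf(delta)
  ## feature takes every 5th site in every bin: p(f|b) = p(f) everywhere
  infeat <- which(seq_along(delta) %% 5 == 0)
  feat <- feature_set("chr1", daf$start[infeat], daf$start[infeat] + 1)
  mv <- mvalue_table(daf, list(f = feat), bin_width = 0.1)
  nz <- mv$total > 0
  expect_equal(unname(mv$M["f", nz]), rep(0, sum(nz)))
})

test_that("the M-value consistency identity holds", {
  set.seed(37)
  delta <- runif(2000)
  daf <- manual_daf(delta)
  classes <- list()
  for (nm in c("x", "y")) {
    pick <- sample(2000, 600)
    classes[[nm]] <- feature_set("chr1", daf$start[pick],
                                 daf$start[pick] + 1)
  }
  mv <- mvalue_table(daf, classes)
  N <- sum(mv$total)
  for (nm in rownames(mv$counts)) {
    pf <- sum(mv$counts[nm, ]) / N
    lhs <- sum(mv$total * 2^mv$M[nm, ] * pf, na.rm = TRUE)
    expect_lt(abs(lhs - sum(mv$counts[nm, ])), 1e-9)
  }
})

test_that("M shrinks toward 0 under uniform random feature placement", {
  set.seed(41)
  delta <- runif(20000)
  daf <- manual_daf(delta)
  pick <- sample(20000, 10000)
  feat <- feature_set("chr1", daf$start[pick], daf$start[pick] + 1)
  mv <- mvalue_table(daf, list(f = feat))
  expect_lt(max(abs(mv$M["f", ])), 0.15)
})

test_that("bins partition disjoint classes and sum to the site count", {
  delta <- runif(500)
  daf <- manual_daf(delta,
                    consequence = sample(c("missense", "synonymous",
                                           "intron"), 500, TRUE))
  mv <- mvalue_table(daf, features = NULL, by_consequence = TRUE)
  expect_equal(sum(mv$total), 500)
  expect_equal(unname(colSums(mv$counts)), unname(mv$total))
})

test_that("consequence scan recovers planted high-divergence sites", {
  cons <- rep("intergenic", 50)
  cons[17] <- "splice"
  delta <- runif(50, 0, 0.5)
  delta[17] <- 0.85
  daf <- manual_daf(delta, consequence = cons)
  cs <- consequence_scan(daf, 0.8)
  expect_equal(cs$counts, c(splice = 1L))
  expect_equal(cs$sites$pos, daf$pos[17])
  expect_equal(nrow(consequence_scan(daf, 1.01)$sites), 0)
  expect_equal(nrow(consequence_scan(daf, -0.1)$sites), 50)
  expect_error(consequence_scan(manual_daf(delta), 0.8), "consequence")
})

test_that("exonic perturbation shifts only exonic sites and spills locally", {
  delta <- runif(400, 0, 0.3)
  daf <- manual_daf(delta)
  exons <- feature_set("chr1", daf$start[1:100], daf$start[1:100] + 1)
  ## delta = 0 is the identity
  expect_equal(perturb_exonic_af(daf, exons, 0)$delta_af, daf$delta_af)
  ## delta = 1 puts every exonic site in the top bin
  p1 <- perturb_exonic_af(daf, exons, 1)
  expect_true(all(p1$delta_af[1:100] == 1))
  expect_equal(p1$delta_af[101:400], daf$delta_af[101:400])

  ## spillover: an interleaved class inherits the shift, a distal one not.
  ## exon sites sit at 1 kb spacing; the interleaved class covers windows
  ## around them, the distal class covers sites far away
  interleaved <- feature_set("chr1", daf$start[1:100] - 10,
                             daf$start[1:100] + 10)
  distal <- feature_set("chr1", daf$start[301:400],
                        daf$start[301:400] + 1)
  mv <- mvalue_table(perturb_exonic_af(daf, exons, 1),
                     list(near = interleaved, far = distal))
  top <- ncol(mv$M)
  spill_near <- mv$counts["near", top]
  spill_far <- mv$counts["far", top]
  expect_gt(spill_near, spill_far)
})
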