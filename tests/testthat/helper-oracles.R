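# Independent oracles used across the suite. Each deliberately takes a
# different route than the implementation it checks.

## all-pairs interval overlap scan (checks intersect_features/any_overlap)
bf_overlap_pairs <- function(a, b) {
  hits <- 0L
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    touched <- FALSE
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        touched <- TRUE
        pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
    if (touched) hits <- hits + 1L
  }
  list(n_query_hit = hits,
       pairs = if (length(pairs)) do.call(rbind, pairs)
       else matrix(integer(), 0, 2))
}

## exhaustive nearest-interval scan (checks closest_features)
bf_closest <- function(a, b) {
  n <- nrow(a)
  idx <- rep(NA_integer_, n); dist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    best <- Inf; bi <- NA_integer_
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      d <- max(0, max(a$start[i], b$start[j]) -
                 min(a$end[i], b$end[j]))
      if (d < best || (d == best && !is.na(bi) &&
                       b$start[j] < b$start[bi])) {
        best <- d; bi <- j
      }
    }
    if (!is.na(bi)) { idx[i] <- bi; dist[i] <- best }
  }
  data.frame(index = idx, distance = dist)
}

## Weir-Cockerham theta via the ANOVA mean-squares route (independent of
## the closed-form a/b/c evaluation in site_fst)
wc_theta_anova <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2 || n2 < 2) return(NA_real_)
  N <- n1 + n2; r <- 2
  p1 <- mean(g1) / 2; p2 <- mean(g2) / 2
  pbar <- (n1 * p1 + n2 * p2) / N
  MSP <- (2 * n1 * (p1 - pbar)^2 + 2 * n2 * (p2 - pbar)^2) / (r - 1)
  ssi <- sum(2 * (g1 / 2 - p1)^2) + sum(2 * (g2 / 2 - p2)^2)
  MSI <- ssi / (N - r)
  MSG <- sum(c(g1, g2) == 1) * 0.5 / N
  nc <- (N - (n1^2 + n2^2) / N) / (r - 1)
  a <- (MSP - MSI) / (2 * nc)
  b <- (MSI - MSG) / 2
  cc <- MSG
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

## hypergeometric tail by direct summation (checks the Fisher p)
bf_fisher_greater <- function(a, b, cc, d) {
  m <- a + b          # reference bins
  n <- cc + d         # non-reference bins
  k <- a + cc         # hit bins
  hi <- min(m, k)
  sum(vapply(a:hi, function(x)
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)),
    numeric(1)))
}

## single-linkage merge via explicit transitive closure (checks
## merge_regions)
bf_merge <- function(bins, gap) {
  n <- nrow(bins)
  if (!n) return(data.frame(chrom = character(), start = numeric(),
                            end = numeric()))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n))
    for (j in seq_len(n)) {
      if (i == j || bins$chrom[i] != bins$chrom[j]) next
      g <- max(bins$start[i], bins$start[j]) -
        min(bins$end[i], bins$end[j])
      if (g <= gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  root <- vapply(seq_len(n), find, integer(1))
  out <- do.call(rbind, lapply(unique(root), function(r) {
    i <- which(root == r)
    data.frame(chrom = bins$chrom[i[1]], start = min(bins$start[i]),
               end = max(bins$end[i]))
  }))
  out[order(out$chrom, out$start), , drop = FALSE]
}

## base-by-base chain projection (checks project_intervals spans)
bf_project_base <- function(interval, chain) {
  b <- chain$blocks
  s <- chain$s_start; t <- chain$t_start
  mapped <- numeric()
  for (k in seq_len(nrow(b))) {
    for (off in seq_len(b$size[k]) - 1) {
      sp <- s + off
      if (sp >= interval[1] && sp < interval[2]) {
        tp <- t + off
        if (!is.null(chain$t_strand) && chain$t_strand == "-")
          tp <- chain$t_size - 1 - tp
        mapped <- c(mapped, tp)
      }
    }
    s <- s + b$size[k] + b$ds[k]
    t <- t + b$size[k] + b$dt[k]
  }
  if (!length(mapped)) return(NULL)
  c(min(mapped), max(mapped) + 1, length(mapped))
}

## permutation oracle for the heterozygote-excess tail probability:
## randomly pair alleles into diploids and count heterozygotes
mc_hwe_excess <- function(n_het_obs, n_alt, n_ind, reps = 20000) {
  alleles <- c(rep(1L, n_alt), rep(0L, 2 * n_ind - n_alt))
  hits <- 0L
  for (i in seq_len(reps)) {
    a <- sample(alleles)
    h <- sum(a[seq(1, 2 * n_ind, 2)] != a[seq(2, 2 * n_ind, 2)])
    if (h >= n_het_obs) hits <- hits + 1L
  }
  hits / reps
}
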