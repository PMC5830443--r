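#' Sweep specification for the simulator
#'
#' Describes one planted selective sweep: inside the window the domestic
#' population's allele frequencies are pushed toward fixation by `delta`
#' and its polymorphism is thinned so that only a fraction `f_pi` of sites
#' stay polymorphic, emulating the diversity loss and divergence gain of a
#' domestication sweep.
#'
#' @param chrom,start,end Window coordinates (0-based half-open).
#' @param f_pi Domestic diversity retention factor in (0, 1]; 0.05 keeps 5%
#'   of within-window domestic polymorphism.
#' @param delta Allele-frequency shift toward fixation in \[0, 1\] applied to
#'   domestic AF inside the window.
#' @return A `sweep_spec` list.
#' @export
sweep_spec <- function(chrom, start, end, f_pi = 0.05, delta = 0.8) {
  stopifnot(start >= 0, end > start, f_pi > 0, f_pi <= 1,
            delta >= 0, delta <= 1)
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 f_pi = f_pi, delta = delta), class = "sweep_spec")
}

#' Default simulated genome layout
#'
#' Two 10-Mb chromosomes: large enough for ~2,000 overlapping 20-kb scan
#' bins, small enough to simulate in seconds.
#' @return A [genome_layout()].
#' @export
default_layout <- function() genome_layout(c("chr1", "chr2"), c(1e7, 1e7))

#' Default planted sweeps
#' @param f_pi,delta Effect sizes passed to every sweep.
#' @return List of five [sweep_spec()]s, 60-kb windows spread over the
#'   default layout.
#' @export
default_sweeps <- function(f_pi = 0.05, delta = 0.8) {
  list(sweep_spec("chr1", 1.00e6, 1.06e6, f_pi, delta),
       sweep_spec("chr1", 3.50e6, 3.56e6, f_pi, delta),
       sweep_spec("chr1", 6.20e6, 6.26e6, f_pi, delta),
       sweep_spec("chr2", 2.40e6, 2.46e6, f_pi, delta),
       sweep_spec("chr2", 7.80e6, 7.86e6, f_pi, delta))
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults reproduce
#' the study conditions the pipeline is meant for: 67 domestic and 17 wild
#' diploid genomes, genome-wide nucleotide diversity near 0.0016 (domestic)
#' and 0.0020 (wild) per bp, strongly correlated allele frequencies between
#' the populations, and five planted domestication sweeps.
#'
#' @param layout A [genome_layout()].
#' @param n_domestic,n_wild Diploid sample counts (>= 2).
#' @param pi_domestic,pi_wild Target per-bp nucleotide diversity, in
#'   (0, 0.01).
#' @param sweeps List of [sweep_spec()]s; windows must not overlap.
#' @param af_noise_sd SD of the bounded Gaussian drift noise added to the
#'   shared ancestral allele frequency in each population.
#' @param loss_wild Fraction of sites snapped to monomorphism in the wild
#'   population (creates domestic-private variants).
#' @param mean_depth Mean per-sample read depth (Poisson).
#' @param missing_rate Per-genotype missing-call probability.
#' @param triallelic_rate Fraction of sites flagged multi-allelic.
#' @param indel_rate Indel positions per bp.
#' @param consequence_probs Named probabilities for the consequence label
#'   attached to every site.
#' @param n_genes Gene count for [simulate_features()].
#' @param seed Integer master seed; every generator derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(layout = default_layout(),
                       n_domestic = 67, n_wild = 17,
                       pi_domestic = 0.0016, pi_wild = 0.0020,
                       sweeps = default_sweeps(),
                       af_noise_sd = 0.13,
                       loss_wild = 0.08,
                       mean_depth = 12,
                       missing_rate = 0.02,
                       triallelic_rate = 0.001,
                       indel_rate = 1e-4,
                       consequence_probs = c(intergenic = 0.60,
                                             intron = 0.30,
                                             synonymous = 0.05,
                                             missense = 0.045,
                                             splice = 0.005),
                       n_genes = 300,
                       seed = 1L) {
  stopifnot(inherits(layout, "genome_layout"),
            n_domestic >= 2, n_wild >= 2,
            pi_domestic > 0, pi_domestic < 0.01,
            pi_wild > 0, pi_wild < 0.01,
            af_noise_sd >= 0, loss_wild >= 0, loss_wild < 1)
  consequence_probs <- consequence_probs / sum(consequence_probs)
  ## sweep windows must lie on the layout and not overlap one another
  if (length(sweeps)) {
    sw <- do.call(rbind, lapply(sweeps, function(s)
      data.frame(chrom = s$chrom, start = s$start, end = s$end)))
    fs <- feature_set(sw$chrom, sw$start, sw$end, layout = layout)
    h <- intersect_features(fs, fs)
    if (any(h$query != h$subject))
      stop("sweep windows overlap each other")
  }
  structure(list(layout = layout, n_domestic = n_domestic, n_wild = n_wild,
                 pi_domestic = pi_domestic, pi_wild = pi_wild,
                 sweeps = sweeps, af_noise_sd = af_noise_sd,
                 loss_wild = loss_wild, mean_depth = mean_depth,
                 missing_rate = missing_rate,
                 triallelic_rate = triallelic_rate,
                 indel_rate = indel_rate,
                 consequence_probs = consequence_probs,
                 n_genes = n_genes, seed = as.integer(seed)),
            class = "sim_config")
}

## internal: ancestral AF from a neutral-like density proportional to 1/p,
## truncated to [a, 1 - a] with a = 1/(2N); sampled by inverse CDF
r_ancestral_af <- function(n, n_chrom) {
  a <- 1 / n_chrom
  a * ((1 - a) / a)^stats::runif(n)
}

## internal: snap allele frequencies to the nearest fixation boundary
snap_af <- function(p) ifelse(p >= 0.5, 1, 0)

#' Simulate two-population genotypes
#'
#' Sites are placed by a Poisson process; each site carries a shared
#' ancestral allele frequency drawn from a neutral-like `1/p` density plus
#' independent bounded Gaussian drift noise per population (clipped to
#' \[0, 1\]), which yields the high between-population AF correlation the
#' analysis assumes. The generator self-calibrates: sites are over-drawn,
#' then uniformly thinned so the realized expected-heterozygosity total
#' matches the wild diversity target, and a computed fraction of sites is
#' snapped to domestic monomorphism to match the domestic target. Inside
#' each [sweep_spec()] window, domestic AF is shifted toward fixation by
#' `delta` and domestic polymorphism is thinned to `f_pi`. Genotypes are
#' binomial draws from the population AF.
#'
#' @param cfg A [sim_config()].
#' @return A [variant_table()] with depth/quality/indel annotations for QC.
#'   The attribute `truth` records the population allele frequencies each
#'   site was generated from, for parameter-recovery tests.
#' @export
simulate_variants <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    lay <- cfg$layout
    G <- genome_size(lay)
    n_chrom_tot <- 2 * (cfg$n_domestic + cfg$n_wild)
    a <- 1 / n_chrom_tot
    e_het0 <- (1 - 2 * a) / log((1 - a) / a)  # E[2p(1-p)] under the 1/p law
    lambda0 <- 1.4 * cfg$pi_wild / (e_het0 * (1 - cfg$loss_wild))

    chrom <- character(); pos <- numeric()
    for (i in seq_len(nrow(lay))) {
      k <- stats::rpois(1, lambda0 * lay$length[i])
      p <- sort(sample.int(lay$length[i], k))
      chrom <- c(chrom, rep(lay$chrom[i], k))
      pos <- c(pos, p)
    }
    ns <- length(pos)
    p0 <- r_ancestral_af(ns, n_chrom_tot)
    p_w <- pmin(1, pmax(0, p0 + stats::rnorm(ns, 0, cfg$af_noise_sd)))
    p_d <- pmin(1, pmax(0, p0 + stats::rnorm(ns, 0, cfg$af_noise_sd)))
    lost_w <- stats::runif(ns) < cfg$loss_wild
    p_w[lost_w] <- snap_af(p_w[lost_w])

    ## calibration pass 1: thin sites so wild diversity hits its target
    s_w <- sum(2 * p_w * (1 - p_w))
    q <- min(1, cfg$pi_wild * G / s_w)
    keep <- stats::runif(ns) < q
    chrom <- chrom[keep]; pos <- pos[keep]
    p_w <- p_w[keep]; p_d <- p_d[keep]
    ns <- length(pos)

    ## calibration pass 2: snap domestic AF at a computed rate so domestic
    ## diversity hits its (lower) target
    s_d <- sum(2 * p_d * (1 - p_d))
    loss_dom <- max(0, 1 - cfg$pi_domestic * G / s_d)
    lost_d <- stats::runif(ns) < loss_dom
    p_d[lost_d] <- snap_af(p_d[lost_d])

    ## plant sweeps: domestic AF toward fixation, polymorphism thinned
    for (sw in cfg$sweeps) {
      idx <- which(chrom == sw$chrom & pos > sw$start & pos <= sw$end)
      if (!length(idx)) next
      b <- snap_af(p_d[idx])
      p_d[idx] <- p_d[idx] + sw$delta * (b - p_d[idx])
      fixed <- stats::runif(length(idx)) >= sw$f_pi
      p_d[idx][fixed] <- b[fixed]
    }

    nd <- cfg$n_domestic; nw <- cfg$n_wild
    geno <- cbind(
      matrix(stats::rbinom(ns * nd, 2, p_d), ns, nd),
      matrix(stats::rbinom(ns * nw, 2, p_w), ns, nw))
    colnames(geno) <- c(sprintf("dom%02d", seq_len(nd)),
                        sprintf("wld%02d", seq_len(nw)))
    if (cfg$missing_rate > 0)
      geno[stats::runif(length(geno)) < cfg$missing_rate] <- NA_integer_
    depth <- matrix(stats::rpois(ns * (nd + nw), cfg$mean_depth),
                    ns, nd + nw, dimnames = dimnames(geno))

    sites <- data.frame(
      chrom = chrom, pos = pos,
      ref = sample(c("A", "C", "G", "T"), ns, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), ns, replace = TRUE),
      qual = pmax(1, round(stats::rnorm(ns, 60, 15), 1)),
      mq = round(pmin(60, stats::rnorm(ns, 50, 4)), 1),
      bq = round(pmax(2, stats::rnorm(ns, 35, 3)), 1),
      multiallelic = stats::runif(ns) < cfg$triallelic_rate,
      consequence = sample(names(cfg$consequence_probs), ns,
                           replace = TRUE, prob = cfg$consequence_probs),
      stringsAsFactors = FALSE)
    ## avoid ref == alt in the emitted VCF
    same <- sites$ref == sites$alt
    sites$alt[same] <- chartr("ACGT", "TGCA", sites$ref[same])

    indels <- NULL
    if (cfg$indel_rate > 0) {
      ic <- character(); ip <- numeric()
      for (i in seq_len(nrow(lay))) {
        k <- stats::rpois(1, cfg$indel_rate * lay$length[i])
        ic <- c(ic, rep(lay$chrom[i], k))
        ip <- c(ip, sort(sample.int(lay$length[i], k)))
      }
      indels <- data.frame(chrom = ic, pos = ip, stringsAsFactors = FALSE)
    }

    v <- variant_table(sites, geno,
                       pop = rep(c("domestic", "wild"), c(nd, nw)),
                       depth = depth, indels = indels)
    attr(v, "layout") <- lay
    attr(v, "truth") <- data.frame(p_domestic = p_d, p_wild = p_w)
    v
  })
}

## internal: clip an interval to a chromosome, dropping it if degenerate
clip_intervals <- function(chrom, start, end, layout) {
  L <- layout$length[match(chrom, layout$chrom)]
  start <- pmax(0, start); end <- pmin(L, end)
  ok <- !is.na(L) & start < end
  data.frame(chrom = chrom[ok], start = start[ok], end = end[ok],
             stringsAsFactors = FALSE)
}

#' Simulate annotation feature sets
#'
#' Places non-overlapping gene bodies, then derives gene-model parts (CDS,
#' intron, UTR), promoter-like chromatin states at gene starts (TssA,
#' TxFlnk), transcription states over gene bodies (Tx), genic and distal
#' enhancers (EnhG, Enh), and proximal/distal element classes. Geometry
#' guarantees the property the analysis relies on: proximal classes sit
#' closer to gene starts than distal enhancers.
#'
#' @param cfg A [sim_config()].
#' @return Named list of [feature_set()]s: `gene`, `CDS`, `intron`, `UTR`,
#'   `TssA`, `TxFlnk`, `Tx`, `EnhG`, `Enh`, `proximal`, `distal`.
#' @export
simulate_features <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lay <- cfg$layout
  empty <- function(class, source)
    feature_set(character(), numeric(), numeric(), class = class,
                source = source)
  if (cfg$n_genes == 0) {
    return(list(gene = empty("gene", "gene_model"),
                CDS = empty("CDS", "gene_model"),
                intron = empty("intron", "gene_model"),
                UTR = empty("UTR", "gene_model"),
                TssA = empty("TssA", "roadmap_state"),
                TxFlnk = empty("TxFlnk", "roadmap_state"),
                Tx = empty("Tx", "roadmap_state"),
                EnhG = empty("EnhG", "roadmap_state"),
                Enh = empty("Enh", "roadmap_state"),
                proximal = empty("proximal", "encode_mark"),
                distal = empty("distal", "encode_mark")))
  }
  with_seed(cfg$seed + 1L, {
    ng <- cfg$n_genes
    glen <- round(stats::runif(ng, 5e3, 3e4))
    proto <- feature_set(rep(lay$chrom[1], ng), seq(0, by = 1, length = ng),
                         seq(0, by = 1, length = ng) + glen,
                         class = "gene", source = "gene_model")
    genes <- shuffle_features(proto, lay)
    genes$name <- sprintf("GENE%04d", seq_len(ng))
    genes$strand <- sample(c("+", "-"), ng, replace = TRUE)
    tss <- ifelse(genes$strand == "-", genes$end, genes$start)

    cds <- utr <- intr <- list()
    for (i in seq_len(ng)) {
      g0 <- genes$start[i]; g1 <- genes$end[i]
      k <- sample(3:8, 1)
      ex_start <- round(seq(g0 + 200, g1 - 350, length.out = k))
      ex_end <- pmin(ex_start + 150, g1 - 200)
      cds[[i]] <- data.frame(chrom = genes$chrom[i], start = ex_start,
                             end = ex_end, gene = genes$name[i])
      intr[[i]] <- data.frame(chrom = genes$chrom[i],
                              start = ex_end[-k], end = ex_start[-1],
                              gene = genes$name[i])
      utr[[i]] <- data.frame(chrom = rep(genes$chrom[i], 2),
                             start = c(g0, g1 - 200),
                             end = c(g0 + 200, g1),
                             gene = genes$name[i])
    }
    bind <- function(l) do.call(rbind, l)
    mk <- function(d, class, source) {
      d <- clip_intervals(d$chrom, d$start, d$end, lay)
      feature_set(d$chrom, d$start, d$end, class = class, source = source,
                  layout = lay)
    }
    ## promoter-like state centred on the TSS; flanking state just outside
    tssa <- clip_intervals(genes$chrom, tss - 500, tss + 500, lay)
    txflnk <- clip_intervals(genes$chrom,
                             ifelse(genes$strand == "-", tss + 500,
                                    tss - 2500),
                             ifelse(genes$strand == "-", tss + 2500,
                                    tss - 500), lay)
    ## distal enhancers 20-100 kb from the TSS on a random side
    side <- sample(c(-1, 1), ng, replace = TRUE)
    off <- round(stats::runif(ng, 2e4, 1e5))
    ewid <- round(stats::runif(ng, 500, 2000))
    enh <- clip_intervals(genes$chrom, tss + side * off,
                          tss + side * off + ewid, lay)
    ## genic enhancers inside gene bodies
    gpos <- round(genes$start + (genes$end - genes$start) *
                    stats::runif(ng, 0.3, 0.7))
    enhg <- clip_intervals(genes$chrom, gpos, gpos + 500, lay)
    ## ENCODE-like proximal (<= 2 kb from TSS) and distal (~50 kb) elements
    prox <- clip_intervals(genes$chrom, tss - 2000, tss - 1000, lay)
    dside <- sample(c(-1, 1), ng, replace = TRUE)
    doff <- round(stats::runif(ng, 3e4, 8e4))
    dist <- clip_intervals(genes$chrom, tss + dside * doff,
                           tss + dside * doff + 800, lay)
    list(gene = genes,
         CDS = mk(bind(cds), "CDS", "gene_model"),
         intron = mk(bind(intr), "intron", "gene_model"),
         UTR = mk(bind(utr), "UTR", "gene_model"),
         TssA = mk(tssa, "TssA", "roadmap_state"),
         TxFlnk = mk(txflnk, "TxFlnk", "roadmap_state"),
         Tx = feature_set(genes$chrom, genes$start, genes$end,
                          class = "Tx", source = "roadmap_state"),
         EnhG = mk(enhg, "EnhG", "roadmap_state"),
         Enh = mk(enh, "Enh", "roadmap_state"),
         proximal = mk(prox, "proximal", "encode_mark"),
         distal = mk(dist, "distal", "encode_mark"))
  })
}

#' Simulate ChIP-seq-like peak sets with a controlled recovery fraction
#'
#' Each predicted interval is "recovered" independently with probability
#' `recovery`: a peak is placed over it (jittered but guaranteed to keep at
#' least 1 bp of overlap). `n_noise` decoy peaks are placed uniformly at
#' random. The measured [recovery_rate()] of the predicted set against the
#' returned peaks converges to `recovery` as the set grows.
#'
#' @param predicted A [feature_set()] of predicted elements.
#' @param recovery Probability in \[0, 1\] that a predicted element is
#'   recovered.
#' @param n_noise Number of decoy peaks.
#' @param layout A [genome_layout()] (needed to place decoys).
#' @param seed Optional integer seed.
#' @param class Feature class of the returned peak set.
#' @return A [feature_set()] of peaks (source tag `chipseq_peak`).
#' @export
simulate_peaks <- function(predicted, recovery, n_noise = 0,
                           layout = NULL, seed = NULL, class = "peak") {
  stopifnot(recovery >= 0, recovery <= 1)
  if (n_noise > 0 && is.null(layout))
    stop("layout required to place decoy peaks")
  with_seed(seed, {
    hit <- stats::runif(nrow(predicted)) < recovery
    p <- predicted[hit, , drop = FALSE]
    w <- p$end - p$start
    shift <- round(stats::runif(length(w), -0.4, 0.4) * w)
    chrom <- p$chrom; start <- pmax(0, p$start + shift); end <- start + w
    if (n_noise > 0) {
      wmed <- max(200, stats::median(predicted$end - predicted$start))
      decoys <- shuffle_features(
        feature_set(rep(layout$chrom[1], n_noise),
                    seq_len(n_noise) - 1, seq_len(n_noise) - 1 + wmed),
        layout)
      chrom <- c(chrom, decoys$chrom)
      start <- c(start, decoys$start)
      end <- c(end, decoys$end)
    }
    if (!is.null(layout)) {
      d <- clip_intervals(chrom, start, end, layout)
      chrom <- d$chrom; start <- d$start; end <- d$end
    }
    feature_set(chrom, start, end, class = class, source = "chipseq_peak")
  })
}

#' Simulate reciprocal alignment chains between two genome versions
#'
#' Walks each chromosome of `layout`, alternating aligned blocks with
#' insertions and deletions at rate `indel_rate` per bp, to produce a
#' second genome layout and the pairwise alignment chains in both
#' directions. Composing the forward and backward projections is the
#' identity for intervals fully inside aligned blocks.
#'
#' @param layout Source [genome_layout()].
#' @param indel_rate Expected indel events per bp (0 gives identity
#'   chains).
#' @param mean_indel Mean indel length (geometric).
#' @param seed Optional integer seed.
#' @return List with `forward` (source to target `chain_set`), `backward`
#'   (target to source), and `target_layout`.
#' @export
simulate_chain <- function(layout, indel_rate = 1e-5, mean_indel = 100,
                           seed = NULL) {
  with_seed(seed, {
    fwd <- list(); bwd <- list()
    t_len <- numeric(nrow(layout))
    for (i in seq_len(nrow(layout))) {
      L <- layout$length[i]
      if (indel_rate <= 0) {
        size <- L; ds <- 0; dt <- 0
      } else {
        size <- ds <- dt <- numeric()
        pos <- 0
        while (pos < L) {
          blk <- min(L - pos, 1 + stats::rgeom(1, indel_rate))
          pos <- pos + blk
          if (pos >= L) {
            size <- c(size, blk); ds <- c(ds, 0); dt <- c(dt, 0)
          } else {
            ilen <- 1 + stats::rgeom(1, 1 / mean_indel)
            if (stats::runif(1) < 0.5) {      # deletion in target
              ilen <- min(ilen, L - pos - 1)
              size <- c(size, blk); ds <- c(ds, ilen); dt <- c(dt, 0)
              pos <- pos + ilen
            } else {                           # insertion in target
              size <- c(size, blk); ds <- c(ds, 0); dt <- c(dt, ilen)
            }
          }
        }
      }
      Lt <- sum(size) + sum(dt)
      t_len[i] <- Lt
      fwd[[i]] <- list(score = sum(size), s_chrom = layout$chrom[i],
                       s_size = L, s_strand = "+", s_start = 0, s_end = L,
                       t_chrom = layout$chrom[i], t_size = Lt,
                       t_strand = "+", t_start = 0, t_end = Lt,
                       id = as.character(i),
                       blocks = data.frame(size = size, ds = ds, dt = dt))
      bwd[[i]] <- list(score = sum(size), s_chrom = layout$chrom[i],
                       s_size = Lt, s_strand = "+", s_start = 0,
                       s_end = Lt,
                       t_chrom = layout$chrom[i], t_size = L,
                       t_strand = "+", t_start = 0, t_end = L,
                       id = as.character(i),
                       blocks = data.frame(size = size, ds = dt, dt = ds))
    }
    list(forward = structure(fwd, class = "chain_set"),
         backward = structure(bwd, class = "chain_set"),
         target_layout = genome_layout(layout$chrom, t_len))
  })
}
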