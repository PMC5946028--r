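# Synthetic-data generator: genomes, miRNA loci with pri-miRNA host
# transcripts, Pol2-like peaks, mRNA and mature-miRNA quantifications with
# replicates, plus emitted ground truth (latent transcription rate T and
# processing efficiency E) so recovery is checkable.
#
# Generative model (all noise multiplicative lognormal):
#   log T_i ~ Normal(mu_group, sd_logT)         latent transcription rate
#   E_i     ~ Beta(group shapes)                processing efficiency in [0,1]
#   M_i     = T_i * E_i * eps_i                 mature miRNA, log eps ~ N(0, sigma_bio)
#   A_i     = T_i * eta_i                       host mRNA,    log eta ~ N(0, sigma_bio)
#   replicate j observes log values + Normal(0, sigma_meas)
#   peaks: one over the stem-loop plus extras across the pri-miRNA span,
#          with uneven lognormal shares summing (noisily) to T_i
# The "late" group (family number >= cutoff) has higher transcription but
# near-zero efficiency, emulating later-annotated miRBase entries that are
# strongly transcribed yet barely matured.

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is designed around:
#' 600 early + 900 late loci, pri-miRNA lengths lognormal with a 41 kb
#' median (human-like; use `pri_length_median = 36000` for a mouse-like
#' genome), late-group transcription above early, late-group processing
#' efficiency near zero, and measurement noise placing replicate-replicate
#' rank correlations in the high-reproducibility band of well-run
#' consortium data (~0.84-0.98).
#'
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param n_early,n_late Locus counts per group.
#' @param number_cutoff Family-number boundary used when assigning names:
#'   early loci get numbers below it, late loci at or above.
#' @param pri_length_median,pri_length_sdlog Lognormal pri-miRNA length
#'   distribution (bp; median and log-scale sd).
#' @param pre_length Pre-miRNA (stem-loop) length in bp.
#' @param mu_logT_early,mu_logT_late,sd_logT Group log-means and common
#'   log-sd of the latent transcription rate.
#' @param eff_early,eff_late Beta shape pairs for processing efficiency.
#' @param const_efficiency If non-NULL, a fixed efficiency for every locus
#'   (overrides the Beta draws; used for noise-free limits).
#' @param sigma_bio,sigma_meas Biological and per-replicate measurement
#'   noise (log-scale sd).
#' @param peaks_lambda Poisson rate for extra peaks per locus; every locus
#'   additionally gets one peak over the stem-loop region itself, so
#'   occupancy is detectable at any window.
#' @param sigma_share Log-scale sd of the uneven per-peak shares of the
#'   locus's total signal.
#' @param sigma_peak Log-scale sd of extra per-peak signal noise.
#' @param n_replicates Replicate measurements per observable.
#' @param n_decoy_peaks,n_decoy_transcripts Background features placed at
#'   random positions; a fraction `antisense_frac` of loci additionally get
#'   an antisense decoy transcript to exercise the strand rule.
#' @param antisense_frac Fraction of loci with an antisense decoy.
#' @param gap_min Minimum gap between consecutive pri-miRNA spans (bp).
#' @param seed Default seed used by [simulate_mirna_sample()].
#' @return A `mirtrans_sim_config` list.
#' @export
simulation_config <- function(n_chroms = 4L,
                              chrom_length = 60e6,
                              n_early = 600L,
                              n_late = 900L,
                              number_cutoff = 1000L,
                              pri_length_median = 41000,
                              pri_length_sdlog = 0.6,
                              pre_length = 80L,
                              mu_logT_early = 3.0,
                              mu_logT_late = 5.0,
                              sd_logT = 1.0,
                              eff_early = c(8, 2),
                              eff_late = c(0.3, 40),
                              const_efficiency = NULL,
                              sigma_bio = 1.5,
                              sigma_meas = 0.6,
                              peaks_lambda = 2,
                              sigma_share = 1.0,
                              sigma_peak = 0.3,
                              n_replicates = 2L,
                              n_decoy_peaks = 200L,
                              n_decoy_transcripts = 200L,
                              antisense_frac = 0.3,
                              gap_min = 60000,
                              seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chroms > 0, cfg$chrom_length > 0,
            cfg$n_early > 0, cfg$n_late > 0,
            cfg$sigma_bio >= 0, cfg$sigma_meas >= 0, cfg$sd_logT >= 0,
            cfg$n_replicates >= 1, cfg$n_early < cfg$number_cutoff)
  if (!is.null(cfg$const_efficiency)) {
    stopifnot(cfg$const_efficiency >= 0, cfg$const_efficiency <= 1)
  }
  structure(cfg, class = "mirtrans_sim_config")
}

.rlnorm0 <- function(n, sdlog) {
  if (sdlog == 0) rep(1, n) else exp(stats::rnorm(n, 0, sdlog))
}

#' Simulate a complete synthetic sample
#'
#' Generates chromosome sizes, named miRNA loci (early/late groups encoded
#' in the family number), pri-miRNA intervals containing each pre-miRNA,
#' replicate Pol2-like peak tracks, replicate transcript quantifications
#' (host transcripts on the coding strand plus antisense and intergenic
#' decoys), replicate mature-miRNA quantifications, a miRBase-style weight
#' table, and the latent ground truth.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed (defaults to `config$seed`); identical config
#'   and seed give identical output.
#' @return A `mirtrans_sim` list: `chrom_sizes`, `loci`, `pri`, `peaks`
#'   (list per replicate), `transcripts` (list per replicate),
#'   `mirna_quant` (list per replicate), `weights`, `truth`, `config`,
#'   `seed`.
#' @export
simulate_mirna_sample <- function(config = simulation_config(),
                                  seed = config$seed) {
  set.seed(seed)
  cfg <- config
  n <- cfg$n_early + cfg$n_late
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom_sizes <- stats::setNames(rep(as.integer(cfg$chrom_length),
                                     cfg$n_chroms), chroms)

  # names: early numbers < cutoff, late >= cutoff, all unique
  early_numbers <- sort(sample.int(cfg$number_cutoff - 1L, cfg$n_early))
  late_numbers <- sort(cfg$number_cutoff - 1L +
                         sample.int(9L * cfg$number_cutoff, cfg$n_late))
  numbers <- c(early_numbers, late_numbers)
  group <- rep(c("early", "late"), c(cfg$n_early, cfg$n_late))
  name <- sprintf("hsa-mir-%d", numbers)

  # pri-miRNA spans laid out left to right, round-robin across chromosomes
  pri_len <- as.integer(round(cfg$pri_length_median *
                                .rlnorm0(n, cfg$pri_length_sdlog)))
  pri_len <- pmax(pri_len, cfg$pre_length + 200L)
  chrom_idx <- rep(seq_len(cfg$n_chroms), length.out = n)
  ord <- sample.int(n)  # shuffle so groups interleave along chromosomes
  pri_start <- integer(n)
  cursor <- stats::setNames(rep(0, cfg$n_chroms), chroms)
  for (i in ord) {
    ci <- chrom_idx[i]
    gap <- cfg$gap_min * stats::runif(1, 1, 1.5)
    pri_start[i] <- as.integer(cursor[ci] + gap)
    cursor[ci] <- pri_start[i] + pri_len[i]
    if (cursor[ci] > cfg$chrom_length) {
      stop("loci do not fit on chromosomes; increase chrom_length ",
           "or reduce locus counts", call. = FALSE)
    }
  }
  pri_end <- pri_start + pri_len
  strand <- sample(c("+", "-"), n, replace = TRUE)

  # pre-miRNA inside its pri-miRNA
  pre_off <- vapply(pri_len - cfg$pre_length, function(m)
    sample.int(m, 1L), integer(1))
  pre_start <- pri_start + pre_off
  pre_end <- pre_start + cfg$pre_length

  loci <- data.frame(name = name, chrom = chroms[chrom_idx],
                     start = pre_start, end = pre_end, strand = strand,
                     number_index = numbers,
                     species_prefix = "hsa", group = group,
                     stringsAsFactors = FALSE)
  pri <- data.frame(mirna_id = name, chrom = chroms[chrom_idx],
                    start = pri_start, end = pri_end, strand = strand,
                    stringsAsFactors = FALSE)

  # latent truth
  mu <- ifelse(group == "early", cfg$mu_logT_early, cfg$mu_logT_late)
  T_lat <- exp(stats::rnorm(n, mu, cfg$sd_logT))
  E_lat <- if (!is.null(cfg$const_efficiency)) {
    rep(cfg$const_efficiency, n)
  } else {
    ifelse(group == "early",
           stats::rbeta(n, cfg$eff_early[1], cfg$eff_early[2]),
           stats::rbeta(n, cfg$eff_late[1], cfg$eff_late[2]))
  }
  M_bio <- T_lat * E_lat * .rlnorm0(n, cfg$sigma_bio)
  A_bio <- T_lat * .rlnorm0(n, cfg$sigma_bio)
  truth <- data.frame(name = name, group = group, T = T_lat, E = E_lat,
                      M_bio = M_bio, A_bio = A_bio, stringsAsFactors = FALSE)

  # peaks: one over the stem-loop itself (travelling polymerase) plus extras
  # spread over the pri span; per-peak signals are uneven lognormal shares
  # of the locus total T, so narrow windows see a noisy fraction of T and
  # wide windows recover it completely
  npk <- 1L + stats::rpois(n, cfg$peaks_lambda)
  pk_locus <- rep(seq_len(n), npk)
  first <- !duplicated(pk_locus)
  pk_width <- as.integer(stats::runif(sum(npk), 300, 1200))
  pk_rel <- stats::runif(sum(npk))
  pk_start <- pri_start[pk_locus] +
    as.integer(pk_rel * pmax(1L, pri_len[pk_locus] - pk_width))
  ctr <- pre_start[pk_locus] + cfg$pre_length %/% 2L
  pk_start[first] <- pmax(0L, ctr[first] - pk_width[first] %/% 2L)
  u <- .rlnorm0(sum(npk), cfg$sigma_share)
  share <- u / stats::ave(u, pk_locus, FUN = sum)
  pk_base <- T_lat[pk_locus] * share * .rlnorm0(sum(npk), cfg$sigma_peak)
  decoy_pk <- if (cfg$n_decoy_peaks > 0) {
    dw <- as.integer(stats::runif(cfg$n_decoy_peaks, 300, 1200))
    ds <- as.integer(stats::runif(cfg$n_decoy_peaks, 0,
                                  cfg$chrom_length - max(dw)))
    data.frame(chrom = sample(chroms, cfg$n_decoy_peaks, replace = TRUE),
               start = ds, end = ds + dw,
               id = sprintf("bgpeak_%d", seq_len(cfg$n_decoy_peaks)),
               strand = ".",
               base = .rlnorm0(cfg$n_decoy_peaks, 1),
               stringsAsFactors = FALSE)
  } else NULL
  peaks_base <- rbind(
    data.frame(chrom = chroms[chrom_idx][pk_locus],
               start = pk_start, end = pk_start + pk_width,
               id = sprintf("peak_%d", seq_along(pk_locus)),
               strand = ".", base = pk_base, stringsAsFactors = FALSE),
    decoy_pk)

  # transcripts: host on the coding strand over the pri span, plus decoys
  anti <- stats::runif(n) < cfg$antisense_frac
  host <- data.frame(gene_id = paste0(name, "-host"),
                     chrom = chroms[chrom_idx],
                     start = pri_start, end = pri_end, strand = strand,
                     base = A_bio, stringsAsFactors = FALSE)
  anti_tx <- if (any(anti)) {
    data.frame(gene_id = paste0(name[anti], "-anti"),
               chrom = chroms[chrom_idx][anti],
               start = pri_start[anti], end = pri_end[anti],
               strand = ifelse(strand[anti] == "+", "-", "+"),
               base = exp(stats::rnorm(sum(anti), 2, 1)),
               stringsAsFactors = FALSE)
  } else NULL
  decoy_tx <- if (cfg$n_decoy_transcripts > 0) {
    dw <- as.integer(stats::runif(cfg$n_decoy_transcripts, 5000, 50000))
    ds <- as.integer(stats::runif(cfg$n_decoy_transcripts, 0,
                                  cfg$chrom_length - max(dw)))
    data.frame(gene_id = sprintf("bg_gene_%d",
                                 seq_len(cfg$n_decoy_transcripts)),
               chrom = sample(chroms, cfg$n_decoy_transcripts, replace = TRUE),
               start = ds, end = ds + dw,
               strand = sample(c("+", "-"), cfg$n_decoy_transcripts,
                               replace = TRUE),
               base = exp(stats::rnorm(cfg$n_decoy_transcripts, 2, 1)),
               stringsAsFactors = FALSE)
  } else NULL
  tx_base <- rbind(host, anti_tx, decoy_tx)

  # replicates observe log values + measurement noise
  peaks <- vector("list", cfg$n_replicates)
  transcripts <- vector("list", cfg$n_replicates)
  mirna_quant <- vector("list", cfg$n_replicates)
  for (j in seq_len(cfg$n_replicates)) {
    pj <- peaks_base
    pj$signal <- pj$base * .rlnorm0(nrow(pj), cfg$sigma_meas)
    pj$base <- NULL
    peaks[[j]] <- pj
    tj <- tx_base
    tj$abundance <- tj$base * .rlnorm0(nrow(tj), cfg$sigma_meas)
    tj$base <- NULL
    transcripts[[j]] <- tj
    mirna_quant[[j]] <- stats::setNames(
      M_bio * .rlnorm0(n, cfg$sigma_meas), name)
  }

  # miRBase-style weights: global expression evidence, correlated with the
  # locus's true mature output but from an independent body of data
  w1 <- 50 * T_lat * E_lat * .rlnorm0(n, 0.5)
  w2 <- w1 / sum(w1) * 1e6
  w3 <- 0.85 * w1 * .rlnorm0(n, 0.2)
  weights <- data.frame(mirna_id = name, w1 = w1, w2 = w2, w3 = w3,
                        stringsAsFactors = FALSE)

  structure(list(chrom_sizes = chrom_sizes, loci = loci, pri = pri,
                 peaks = peaks, transcripts = transcripts,
                 mirna_quant = mirna_quant, weights = weights,
                 truth = truth, config = cfg, seed = seed),
            class = "mirtrans_sim")
}

#' @export
print.mirtrans_sim <- function(x, ...) {
  cat("Synthetic miRNA-transcription sample\n")
  cat(sprintf("  %d loci (%d early, %d late) on %d chromosomes; seed %d\n",
              nrow(x$loci), sum(x$loci$group == "early"),
              sum(x$loci$group == "late"), length(x$chrom_sizes), x$seed))
  cat(sprintf("  %d replicates; %d peaks, %d transcripts per replicate\n",
              length(x$peaks), nrow(x$peaks[[1]]), nrow(x$transcripts[[1]])))
  invisible(x)
}

#' Correlation between latent transcription and observed miRNA abundance
#'
#' Oracle for recovery tests: correlates the latent transcription rate T
#' with the observed mature miRNA abundance over a subset of loci.
#'
#' @param sample A `mirtrans_sim` object.
#' @param subset Character vector of locus names (default: all).
#' @param method `"spearman"` or `"pearson"`.
#' @param replicate Which replicate's observation to use; 0 uses the
#'   biological (pre-measurement-noise) abundance.
#' @return A `mir_correlation` object.
#' @export
truth_correlation <- function(sample, subset = NULL,
                              method = c("spearman", "pearson"),
                              replicate = 1L) {
  method <- match.arg(method)
  tr <- sample$truth
  if (!is.null(subset)) {
    tr <- tr[tr$name %in% subset, , drop = FALSE]
    if (nrow(tr) == 0L) stop("empty subset", call. = FALSE)
  }
  m <- if (replicate == 0L) tr$M_bio else {
    unname(sample$mirna_quant[[replicate]][tr$name])
  }
  if (method == "spearman") cor_spearman(tr$T, m) else cor_pearson(tr$T, m)
}

#' Combine a transcript annotation with a quantification
#'
#' @param annotation data.frame `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param quant Named numeric vector from [read_quant()].
#' @return Feature data.frame suitable for [link_signals()] (adds an
#'   `abundance` column; genes without a quantification are an error).
#' @export
transcript_features <- function(annotation, quant) {
  i <- match(annotation$gene_id, names(quant))
  if (anyNA(i)) stop("no quantification for gene(s): ",
                     paste(annotation$gene_id[is.na(i)][1L]), call. = FALSE)
  annotation$abundance <- unname(quant[i])
  annotation
}

#' Write a synthetic sample to disk in the pipeline's input formats
#'
#' Emits miRBase-dialect GFF3 loci, a pri-miRNA table, per-replicate
#' narrowPeak files and quantification TSVs, a transcript annotation TSV, a
#' weight table, and chrom.sizes, so end-to-end tests exercise real I/O.
#'
#' @param sample A `mirtrans_sim` object.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths.
#' @export
write_sample <- function(sample, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  gff <- data.frame(chrom = sample$loci$chrom, start = sample$loci$start,
                    end = sample$loci$end, strand = sample$loci$strand,
                    type = "miRNA_primary_transcript",
                    id = sample$loci$name, name = sample$loci$name,
                    stringsAsFactors = FALSE)
  write_intervals(gff, p("loci.gff3"), "gff3_mirbase")
  write_intervals(sample$pri, p("pri_mirna.tsv"), "pri_table")
  write_chrom_sizes(sample$chrom_sizes, p("genome.chrom.sizes"))
  write_weight_table(sample$weights, p("weights.tsv"))
  ann <- sample$transcripts[[1]][, c("gene_id", "chrom", "start", "end",
                                     "strand")]
  writeLines(c("gene_id\tchrom\tstart\tend\tstrand",
               sprintf("%s\t%s\t%d\t%d\t%s", ann$gene_id, ann$chrom,
                       ann$start, ann$end, ann$strand)),
             p("transcripts.tsv"))
  paths <- list(loci = p("loci.gff3"), pri = p("pri_mirna.tsv"),
                chrom_sizes = p("genome.chrom.sizes"),
                weights = p("weights.tsv"),
                annotation = p("transcripts.tsv"))
  for (j in seq_along(sample$peaks)) {
    fp <- p(sprintf("pol2_rep%d.narrowPeak", j))
    write_intervals(sample$peaks[[j]], fp, "narrowPeak")
    paths[[sprintf("peaks_rep%d", j)]] <- fp
  }
  for (j in seq_along(sample$transcripts)) {
    fq <- p(sprintf("gene_quant_rep%d.tsv", j))
    write_quant(stats::setNames(sample$transcripts[[j]]$abundance,
                                sample$transcripts[[j]]$gene_id), fq)
    paths[[sprintf("quant_rep%d", j)]] <- fq
  }
  for (j in seq_along(sample$mirna_quant)) {
    fm <- p(sprintf("mirna_quant_rep%d.tsv", j))
    write_quant(sample$mirna_quant[[j]], fm, id_col = "mirna_id")
    paths[[sprintf("mirna_rep%d", j)]] <- fm
  }
  paths
}

#' Simulate replicate measurements of two correlated latent variables
#'
#' Generates n pairs from a bivariate normal with latent correlation `rho`
#' and per-axis reliability `reliability` (the replicate-replicate
#' correlation each axis would show in expectation), with `n_replicates`
#' noisy observations per axis. Used to check that attenuation correction
#' recovers the latent correlation.
#'
#' @param n Sample size.
#' @param rho Latent correlation.
#' @param reliability Per-axis reliability in (0, 1].
#' @param n_replicates Observations per axis.
#' @param seed Integer seed.
#' @return list with `x`, `y` (n x n_replicates matrices) and `latent`
#'   (list of the two latent vectors).
#' @export
simulate_reliability_study <- function(n, rho, reliability,
                                       n_replicates = 2L, seed = 1L) {
  stopifnot(reliability > 0, reliability <= 1, abs(rho) <= 1)
  set.seed(seed)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  s <- sqrt((1 - reliability) / reliability)
  x <- z1 + matrix(stats::rnorm(n * n_replicates, 0, s), n, n_replicates)
  y <- z2 + matrix(stats::rnorm(n * n_replicates, 0, s), n, n_replicates)
  list(x = x, y = y, latent = list(x = z1, y = z2))
}

#' Replicate cross-pairings and attenuation-corrected correlation
#'
#' Computes the four cross-correlations between two replicates of each
#' measurement (pairings labelled A-D), the replicate-replicate
#' reliabilities, and the attenuation-corrected estimate.
#'
#' @param x1,x2 Replicate observations of the first measurement.
#' @param y1,y2 Replicate observations of the second measurement.
#' @param method `"spearman"` or `"pearson"`.
#' @return list with `cross` (named numeric, A-D), `r_xx`, `r_yy`,
#'   `corrected` (output of [attenuation_correct()]).
#' @export
replicate_correction <- function(x1, x2, y1, y2,
                                 method = c("spearman", "pearson")) {
  method <- match.arg(method)
  cc <- function(a, b) {
    r <- if (method == "spearman") cor_spearman(a, b) else cor_pearson(a, b)
    r$coefficient
  }
  cross <- c(A = cc(x1, y1), B = cc(x1, y2), C = cc(x2, y1), D = cc(x2, y2))
  r_xx <- cc(x1, x2)
  r_yy <- cc(y1, y2)
  list(cross = cross, r_xx = r_xx, r_yy = r_yy,
       corrected = attenuation_correct(cross, r_xx, r_yy))
}
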