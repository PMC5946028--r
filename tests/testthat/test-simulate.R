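test_that("simulation is deterministic and respects its invariants", {
  cfg <- small_sim_config()
  s1 <- simulate_mirna_sample(cfg, seed = 5)
  s2 <- simulate_mirna_sample(cfg, seed = 5)
  expect_identical(s1[setdiff(names(s1), "config")],
                   s2[setdiff(names(s2), "config")])
  s3 <- simulate_mirna_sample(cfg, seed = 6)
  expect_false(identical(s1$truth$T, s3$truth$T))

  # pre-miRNA inside its pri-miRNA, everything inside chromosome bounds
  i <- match(s1$loci$name, s1$pri$mirna_id)
  expect_true(all(s1$loci$start >= s1$pri$start[i]))
  expect_true(all(s1$loci$end <= s1$pri$end[i]))
  expect_true(all(s1$pri$start >= 0))
  expect_true(all(s1$pri$end <= s1$chrom_sizes[s1$pri$chrom]))
  expect_true(all(s1$truth$E >= 0 & s1$truth$E <= 1))
  expect_true(all(s1$loci$strand %in% c("+", "-")))

  # names encode the groups
  sp <- apply_number_cutoff(s1$loci, cfg$number_cutoff)
  expect_setequal(sp$early$name, s1$loci$name[s1$loci$group == "early"])
  expect_setequal(sp$late$name, s1$loci$name[s1$loci$group == "late"])

  # an impossible layout is refused with advice
  expect_error(simulate_mirna_sample(small_sim_config(chrom_length = 1e6)),
               "chrom_length")
})

test_that("the noise-free limit gives a perfect rank correlation", {
  cfg <- simulation_config(n_chroms = 2L, chrom_length = 2e7, n_early = 60L,
                           n_late = 90L, sigma_bio = 0, sigma_meas = 0,
                           sigma_peak = 0, const_efficiency = 1,
                           n_decoy_transcripts = 0L, n_decoy_peaks = 0L,
                           antisense_frac = 0)
  smp <- simulate_mirna_sample(cfg, seed = 2)
  linked <- link_signals(smp$loci, smp$transcripts[[1]],
                         strand_mode = "match", agg = "sum")
  pairs <- build_paired_vectors(linked, smp$mirna_quant[[1]])
  expect_equal(pairs$n, nrow(smp$loci))
  expect_equal(cor_spearman(pairs$x, pairs$y)$coefficient, 1)

  expect_equal(truth_correlation(smp)$coefficient, 1)
  expect_equal(truth_correlation(smp, method = "pearson",
                                 replicate = 0)$coefficient, 1)
})

test_that("truth_correlation matches direct computation on the emitted truth", {
  smp <- simulate_mirna_sample(small_sim_config(), seed = 3)
  got <- truth_correlation(smp, method = "spearman", replicate = 1)
  want <- cor(smp$truth$T, unname(smp$mirna_quant[[1]][smp$truth$name]),
              method = "spearman")
  expect_equal(got$coefficient, want)

  late <- smp$loci$name[smp$loci$group == "late"]
  got_late <- truth_correlation(smp, subset = late)
  expect_lt(abs(got_late$coefficient), 0.5)  # near-zero maturation decouples
  expect_error(truth_correlation(smp, subset = "nope"), "empty")
})

test_that("written samples read back through the real file formats", {
  smp <- simulate_mirna_sample(small_sim_config(), seed = 4)
  dir <- withr::local_tempdir()
  paths <- write_sample(smp, dir)

  loci <- as_mirna_loci(read_intervals(paths$loci, "gff3_mirbase"))
  expect_identical(loci$name, smp$loci$name)
  expect_identical(loci$start, smp$loci$start)
  expect_identical(loci$end, smp$loci$end)
  expect_identical(loci$strand, smp$loci$strand)
  expect_identical(loci$number_index, smp$loci$number_index)

  expect_identical(read_intervals(paths$pri, "pri_table"), smp$pri)
  expect_identical(read_chrom_sizes(paths$chrom_sizes), smp$chrom_sizes)

  pk <- read_intervals(paths$peaks_rep1, "narrowPeak")
  expect_identical(pk[c("chrom", "start", "end", "id")],
                   smp$peaks[[1]][c("chrom", "start", "end", "id")])
  expect_equal(pk$signal, smp$peaks[[1]]$signal, tolerance = 1e-4)

  q <- read_quant(paths$quant_rep1)
  ann <- utils::read.delim(paths$annotation, stringsAsFactors = FALSE)
  feats <- transcript_features(ann, q)
  expect_equal(feats$abundance, smp$transcripts[[1]]$abundance,
               tolerance = 1e-4)

  mq <- read_quant(paths$mirna_rep1, id_col = "mirna_id")
  expect_equal(unname(mq), unname(smp$mirna_quant[[1]]), tolerance = 1e-4)

  # the end-to-end path from files reproduces the in-memory correlation
  linked_file <- link_signals(
    extend_intervals(loci, 10000, read_chrom_sizes(paths$chrom_sizes)),
    feats, strand_mode = "match", agg = "sum")
  pairs_file <- build_paired_vectors(linked_file, mq)
  linked_mem <- link_signals(
    extend_intervals(smp$loci, 10000, smp$chrom_sizes),
    smp$transcripts[[1]], strand_mode = "match", agg = "sum")
  pairs_mem <- build_paired_vectors(linked_mem, smp$mirna_quant[[1]])
  expect_equal(cor_spearman(pairs_file$x, pairs_file$y)$coefficient,
               cor_spearman(pairs_mem$x, pairs_mem$y)$coefficient,
               tolerance = 1e-6)
})

test_that("replicate observables sit in a high-reproducibility band", {
  smp <- simulate_mirna_sample(seed = 7)
  ra <- replicate_analysis(smp, window_kb = 20, filter = "all")
  rr <- c(ra$chip$r_xx, ra$rna$r_xx, ra$chip$r_yy)
  expect_true(all(rr > 0.84 & rr < 0.98))
})
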