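test_that("interval extension is symmetric, clipped and strand-preserving", {
  sizes <- c(chr1 = 1000000L)
  iv <- data.frame(chrom = "chr1", start = 1000L, end = 1100L, strand = "+")
  out <- extend_intervals(iv, 2000, sizes)
  expect_equal(c(out$start, out$end), c(0L, 3100L))  # clipped at chrom start
  expect_equal(out$strand, "+")

  iv2 <- data.frame(chrom = "chr1", start = 10000L, end = 10100L, strand = "-")
  out2 <- extend_intervals(iv2, 5000, sizes)
  expect_equal(c(out2$start, out2$end), c(5000L, 15100L))
  expect_identical(extend_intervals(iv2, 0, sizes), iv2)

  near_end <- data.frame(chrom = "chr1", start = 999000L, end = 999500L)
  expect_equal(extend_intervals(near_end, 5000, sizes)$end, 1000000L)
  expect_error(extend_intervals(data.frame(chrom = "chrX", start = 1L,
                                           end = 2L), 10, sizes),
               "unknown chromosome")
})

test_that("ChIP linking counts both strands, RNA linking only the coding strand", {
  locus <- data.frame(name = "hsa-mir-1", chrom = "chr1", start = 0L,
                      end = 3100L, strand = "+", stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "chr1", start = c(500L, 3000L),
                      end = c(600L, 4000L), strand = c("+", "-"),
                      signal = c(2, 3), stringsAsFactors = FALSE)
  chip <- link_signals(locus, peaks, strand_mode = "both", agg = "sum")
  expect_equal(chip$signal, 5)
  expect_equal(chip$n_features, 2L)

  tx <- data.frame(chrom = "chr1", start = c(500L, 3000L),
                   end = c(600L, 4000L), strand = c("+", "-"),
                   abundance = c(2, 3), stringsAsFactors = FALSE)
  rna <- link_signals(locus, tx, strand_mode = "match", agg = "sum")
  expect_equal(rna$signal, 2)   # antisense transcript excluded
  expect_equal(rna$n_features, 1L)

  # strandless features are skipped under "match" and tallied
  tx$strand[1] <- "."
  rna2 <- link_signals(locus, tx, strand_mode = "match", agg = "sum")
  expect_equal(nrow(rna2), 0L)
  expect_equal(attr(rna2, "n_skipped"), 1L)

  # one-nucleotide overlap scores positive
  edge <- data.frame(chrom = "chr1", start = 3099L, end = 5000L,
                     strand = "+", signal = 1, stringsAsFactors = FALSE)
  expect_equal(link_signals(locus, edge)$n_features, 1L)
  # adjacent (zero-overlap) does not
  edge$start <- 3100L
  expect_equal(nrow(link_signals(locus, edge)), 0L)
})

test_that("link_signals equals the all-pairs brute-force scan on random instances", {
  set.seed(42)
  for (trial in 1:3) {
    loci <- random_loci(100)
    feats <- random_features(1000)
    for (sm in c("both", "match")) {
      for (agg in c("sum", "max")) {
        got <- link_signals(loci, feats, strand_mode = sm, agg = agg)
        want <- brute_link(loci, feats, strand_mode = sm, agg = agg)
        expect_identical(got$mirna_id, want$mirna_id)
        expect_identical(got$n_features, want$n_features)
        expect_identical(got$signal, want$signal)  # exact, same summation order
      }
    }
  }
})

test_that("signal and feature count are monotone in the extension window", {
  set.seed(11)
  sizes <- c(chr1 = 1e6L, chr2 = 1e6L)
  loci <- random_loci(50)
  feats <- random_features(500)
  prev <- NULL
  for (k in c(0, 1000, 2000, 5000, 10000, 20000)) {
    ext <- extend_intervals(loci, k, sizes)
    cur <- link_signals(ext, feats, strand_mode = "both", agg = "sum",
                        keep_unlinked_as_zero = TRUE)
    cur <- cur[match(loci$name, cur$mirna_id), ]
    if (!is.null(prev)) {
      expect_true(all(cur$signal >= prev$signal - 1e-12))
      expect_true(all(cur$n_features >= prev$n_features))
    }
    prev <- cur
  }
})

test_that("max aggregation never exceeds sum aggregation", {
  set.seed(12)
  loci <- random_loci(60)
  feats <- random_features(600)
  s <- link_signals(loci, feats, agg = "sum")
  m <- link_signals(loci, feats, agg = "max")
  expect_identical(s$mirna_id, m$mirna_id)
  expect_true(all(m$signal <= s$signal + 1e-12))
  expect_true(all(s$signal >= m$signal))  # sum >= max of contributors
})

test_that("pri-miRNA intervals link directly for RNA and extended for ChIP", {
  sizes <- c(chr1 = 1e6L)
  pri <- data.frame(mirna_id = "hsa-mir-7", chrom = "chr1", start = 100000L,
                    end = 141000L, strand = "+", stringsAsFactors = FALSE)
  loci <- data.frame(name = pri$mirna_id, chrom = pri$chrom,
                     start = pri$start, end = pri$end, strand = pri$strand,
                     stringsAsFactors = FALSE)
  tx <- data.frame(chrom = "chr1", start = 100000L, end = 141000L,
                   strand = "+", abundance = 4, stringsAsFactors = FALSE)
  direct <- link_signals(loci, tx, strand_mode = "match")
  expect_equal(direct$signal, 4)

  pk <- data.frame(chrom = "chr1", start = 145000L, end = 145500L,
                   strand = ".", signal = 9, stringsAsFactors = FALSE)
  expect_equal(nrow(link_signals(loci, pk)), 0L)  # outside the raw span
  ext <- extend_intervals(loci, 5000, sizes)
  expect_equal(link_signals(ext, pk)$signal, 9)   # captured after extension
})

test_that("paired vectors intersect ids deterministically", {
  linked <- data.frame(mirna_id = c("b", "a"), n_features = 1L,
                       signal = c(2, 1), stringsAsFactors = FALSE)
  quant <- c(b = 5, c = 7)
  p <- build_paired_vectors(linked, quant)
  expect_equal(p$n, 1L)
  expect_equal(p$ids, "b")
  expect_equal(p$x, 2)
  expect_equal(p$y, 5)
  expect_error(cor_spearman(p$x, p$y), "at least 3")  # error arises downstream

  quant10 <- setNames(1:10, paste0("m", 10:1))
  linked10 <- data.frame(mirna_id = sample(names(quant10)), n_features = 1L,
                         signal = runif(10), stringsAsFactors = FALSE)
  p10 <- build_paired_vectors(linked10, quant10)
  expect_equal(p10$n, 10L)
  expect_identical(p10$ids, sort(names(quant10)))

  set.seed(3)
  for (i in 1:5) {
    la <- sample(letters, 12)
    qa <- setNames(runif(12), sample(letters, 12))
    li <- data.frame(mirna_id = la, n_features = 1L, signal = runif(12),
                     stringsAsFactors = FALSE)
    expect_equal(build_paired_vectors(li, qa)$n,
                 length(intersect(la, names(qa))))
  }

  # zero-abundance miRNAs kept by default, dropped on request
  lz <- data.frame(mirna_id = c("a", "b", "c"), n_features = 1L,
                   signal = 1:3, stringsAsFactors = FALSE)
  qz <- c(a = 0, b = 1, c = 2)
  expect_equal(build_paired_vectors(lz, qz)$n, 3L)
  expect_equal(build_paired_vectors(lz, qz, drop_zero_mirna = TRUE)$n, 2L)
})
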