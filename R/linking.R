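# Interval extension and per-locus aggregation of overlapping transcription
# signals. Overlap = >= 1 shared bp on the same chromosome; ChIP linking
# considers peaks on both strands, RNA linking only the miRNA-coding strand.

#' Extend genomic intervals symmetrically
#'
#' Extends each interval by `k` bp on both sides in genomic coordinates
#' (i.e. both the 5' and 3' directions, regardless of strand), clipped to
#' `[0, chromosome length)`.
#'
#' @param x data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open); other columns are preserved.
#' @param k Extension distance in bp (>= 0).
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @return `x` with `start`/`end` replaced by the extended, clipped
#'   coordinates.
#' @export
extend_intervals <- function(x, k, chrom_sizes) {
  stopifnot(k >= 0)
  unknown <- setdiff(unique(x$chrom), names(chrom_sizes))
  if (length(unknown)) stop("unknown chromosome: ", unknown[1L], call. = FALSE)
  len <- unname(chrom_sizes[x$chrom])
  x$start <- pmax(0L, as.integer(x$start - k))
  x$end <- pmin(len, as.integer(x$end + k))
  x
}

.as_granges <- function(x, sizes = NULL) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Aggregate overlapping feature signals per miRNA locus
#'
#' For each locus (typically an extended pre-miRNA or a pri-miRNA interval)
#' collects every feature sharing at least one bp on the same chromosome and
#' aggregates the signals. `strand_mode = "both"` is the ChIP-seq rule
#' (Pol2 peaks on either DNA strand count); `strand_mode = "match"` is the
#' RNA-seq rule (only transcripts on the miRNA-coding strand count;
#' strandless features are skipped and tallied in the `n_skipped`
#' attribute).
#'
#' Loci with no eligible overlapping feature are dropped by default
#' (`keep_unlinked_as_zero = TRUE` emits them with signal 0 instead).
#'
#' @param loci data.frame with `name` (or `id`), `chrom`, `start`, `end`,
#'   `strand`.
#' @param features data.frame with `chrom`, `start`, `end`, `strand`, and a
#'   signal column (`signal` or `abundance`).
#' @param strand_mode `"both"` or `"match"`.
#' @param agg `"sum"` or `"max"`.
#' @param window_kb,mode Annotations copied into the output (the extension
#'   used and the track type, `"chip"` or `"rna"`).
#' @param keep_unlinked_as_zero Emit unlinked loci with signal 0.
#' @return data.frame `mirna_id`, `n_features`, `signal`, `window_kb`,
#'   `mode`, `agg`, one row per linked locus, in input locus order; with
#'   attribute `n_skipped` (strandless features skipped under `"match"`).
#' @export
link_signals <- function(loci, features,
                         strand_mode = c("both", "match"),
                         agg = c("sum", "max"),
                         window_kb = NA_real_, mode = NA_character_,
                         keep_unlinked_as_zero = FALSE) {
  strand_mode <- match.arg(strand_mode)
  agg <- match.arg(agg)
  id_col <- if ("name" %in% names(loci)) "name" else "id"
  sig_col <- if ("signal" %in% names(features)) "signal" else "abundance"
  n_skipped <- 0L

  feat <- features
  if (strand_mode == "match") {
    strandless <- feat$strand == "."
    n_skipped <- sum(strandless)
    feat <- feat[!strandless, , drop = FALSE]
  }

  if (nrow(loci) == 0L || nrow(feat) == 0L) {
    hits_loci <- integer(0); agg_sig <- numeric(0); nfeat <- integer(0)
  } else {
    ov <- GenomicRanges::findOverlaps(.as_granges(loci), .as_granges(feat))
    qi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    if (strand_mode == "match") {
      ok <- feat$strand[si] == loci$strand[qi]
      qi <- qi[ok]; si <- si[ok]
    }
    if (length(qi)) {
      f <- factor(qi, levels = sort(unique(qi)))
      sig <- feat[[sig_col]][si]
      agg_sig <- as.numeric(tapply(sig, f, if (agg == "sum") sum else max))
      nfeat <- as.integer(tapply(sig, f, length))
      hits_loci <- sort(unique(qi))
    } else {
      hits_loci <- integer(0); agg_sig <- numeric(0); nfeat <- integer(0)
    }
  }

  nh <- length(hits_loci)
  out <- data.frame(mirna_id = loci[[id_col]][hits_loci],
                    n_features = nfeat, signal = agg_sig,
                    window_kb = rep(window_kb, nh), mode = rep(mode, nh),
                    agg = rep(agg, nh), stringsAsFactors = FALSE)
  if (keep_unlinked_as_zero) {
    missing_idx <- setdiff(seq_len(nrow(loci)), hits_loci)
    if (length(missing_idx)) {
      nm <- length(missing_idx)
      zero <- data.frame(mirna_id = loci[[id_col]][missing_idx],
                         n_features = 0L, signal = 0,
                         window_kb = rep(window_kb, nm), mode = rep(mode, nm),
                         agg = rep(agg, nm), stringsAsFactors = FALSE)
      out <- rbind(out, zero)
      out <- out[order(match(out$mirna_id, loci[[id_col]])), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Pair aggregated transcription signals with mature miRNA abundances
#'
#' Restricts to miRNAs present in both inputs and returns aligned vectors
#' in deterministic (lexicographic by id) order. Zero-abundance miRNAs are
#' kept by default (rank correlation tolerates ties at zero).
#'
#' @param linked data.frame from [link_signals()].
#' @param quant Named numeric vector of mature miRNA abundances (5p + 3p
#'   combined per stem-loop).
#' @param drop_zero_mirna Drop miRNAs with zero mature abundance.
#' @return list with `ids`, `x` (aggregated transcription signal), `y`
#'   (miRNA abundance), `n`.
#' @export
build_paired_vectors <- function(linked, quant, drop_zero_mirna = FALSE) {
  ids <- sort(intersect(linked$mirna_id, names(quant)))
  x <- linked$signal[match(ids, linked$mirna_id)]
  y <- unname(quant[ids])
  if (drop_zero_mirna) {
    keep <- y > 0
    ids <- ids[keep]; x <- x[keep]; y <- y[keep]
  }
  list(ids = ids, x = x, y = y, n = length(ids))
}
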