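# miRNA stratification devices: miRBase name-number parsing and cut-offs,
# the pri-miRNA evidence filter, and expression-based weighting tables.
# Later-numbered miRBase entries were discovered later and are more likely
# misannotated; the cut-offs and weights down-weight or exclude them.

#' Parse the family number from a miRBase name
#'
#' Returns the first run of digits following the `mir`/`let` component.
#' Lettered variants (`-302a`) and genomic-copy suffixes (`-124-2`) are
#' ignored, and mature-name suffixes (`-5p`/`-3p`) map to the same number
#' as the stem-loop. Case-insensitive.
#'
#' @param name Character vector of miRBase names, e.g. `"hsa-mir-21"`.
#' @return Integer vector of family numbers.
#' @export
#' @examples
#' parse_mirna_number(c("hsa-mir-21", "mmu-mir-124-2", "hsa-let-7a-1"))
parse_mirna_number <- function(name) {
  m <- regexpr("(mir|let)-?([0-9]+)", name, ignore.case = TRUE, perl = TRUE)
  tok <- rep(NA_character_, length(name))
  tok[m > 0] <- regmatches(name, m)
  if (anyNA(tok)) {
    stop("no miRNA number found in name(s): ",
         paste(name[is.na(tok)], collapse = ", "), call. = FALSE)
  }
  as.integer(sub("^(mir|let)-?", "", tok, ignore.case = TRUE))
}

#' Split miRNA loci at a name-number cut-off
#'
#' Partitions loci into an "early" group (family number strictly below the
#' threshold; discovered early, more likely genuine) and a "late" group
#' (the complement).
#'
#' @param loci data.frame with a `number_index` column (see
#'   [as_mirna_loci()]).
#' @param threshold Positive integer cut-off.
#' @return list with components `early` and `late`, each a subset of
#'   `loci`; the two are disjoint and exhaustive.
#' @export
apply_number_cutoff <- function(loci, threshold) {
  stopifnot(threshold > 0)
  early <- loci$number_index < threshold
  list(early = loci[early, , drop = FALSE],
       late = loci[!early, , drop = FALSE])
}

#' Restrict loci to those with experimental pri-miRNA evidence
#'
#' Keeps loci that have an entry in the pri-miRNA table and a family
#' number below `number_cutoff`; the kept loci's intervals are replaced by
#' their pri-miRNA intervals for downstream linking. A pri-miRNA interval
#' that does not overlap its pre-miRNA raises a warning, not an error.
#'
#' @param loci miRNA locus data.frame.
#' @param pri pri-miRNA table (see [read_intervals()] with
#'   `format = "pri_table"`).
#' @param number_cutoff Family-number cut-off applied alongside the
#'   evidence filter.
#' @return Subset of `loci` with pri-miRNA coordinates.
#' @export
apply_pri_filter <- function(loci, pri, number_cutoff = 1000L) {
  keep <- loci$name %in% pri$mirna_id & loci$number_index < number_cutoff
  out <- loci[keep, , drop = FALSE]
  i <- match(out$name, pri$mirna_id)
  no_overlap <- !(pri$start[i] < out$end & out$start < pri$end[i] &
                    pri$chrom[i] == out$chrom)
  if (any(no_overlap)) {
    warning("pri-miRNA interval does not overlap its pre-miRNA for: ",
            paste(out$name[no_overlap], collapse = ", "), call. = FALSE)
  }
  out$chrom <- pri$chrom[i]
  out$start <- pri$start[i]
  out$end <- pri$end[i]
  rownames(out) <- NULL
  out
}

#' Read a miRNA weighting table
#'
#' TSV with header `mirna_id  w1  w2  w3`: total stem-loop deep-sequencing
#' reads (w1), normalized reads per million (w2), and mature-miRNA reads,
#' 5p + 3p combined (w3).
#'
#' @param path Path to the TSV.
#' @return data.frame `mirna_id`, `w1`, `w2`, `w3`.
#' @export
read_weight_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "w1", "w2", "w3")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("weight table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$w1 < 0 | df$w2 < 0 | df$w3 < 0)) {
    stop("negative weight in table", call. = FALSE)
  }
  df[need]
}

#' Write a miRNA weighting table
#' @param weights data.frame `mirna_id`, `w1`, `w2`, `w3`.
#' @param path Output path.
#' @export
write_weight_table <- function(weights, path) {
  writeLines(c("mirna_id\tw1\tw2\tw3",
               sprintf("%s\t%.6f\t%.6f\t%.6f", weights$mirna_id,
                       weights$w1, weights$w2, weights$w3)), path)
  invisible(path)
}

#' Attach a weighting factor to paired vectors
#'
#' Aligns the requested weighting factor with the paired value vectors. A
#' paired miRNA without a weight is an error, never a silent zero.
#'
#' @param pairs list from [build_paired_vectors()].
#' @param weights Weight table (see [read_weight_table()]).
#' @param factor One of `"w1"`, `"w2"`, `"w3"`.
#' @return `pairs` with an added `w` component.
#' @export
attach_weights <- function(pairs, weights, factor = c("w1", "w2", "w3")) {
  factor <- match.arg(factor)
  i <- match(pairs$ids, weights$mirna_id)
  if (anyNA(i)) {
    stop("no weight for miRNA(s): ",
         paste(pairs$ids[is.na(i)], collapse = ", "), call. = FALSE)
  }
  pairs$w <- weights[[factor]][i]
  pairs$weight_factor <- factor
  pairs
}
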