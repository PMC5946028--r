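# Readers and writers for the on-disk formats the pipeline consumes:
# BED/narrowPeak peak calls, miRBase-dialect GFF3, pri-miRNA tables,
# quantification TSVs, chrom.sizes. Coordinates are internally 0-based
# half-open (BED convention); GFF3 converts on read/write.

.read_lines_nonempty <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  idx <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  list(lines = lines[idx], lineno = idx)
}

.parse_int <- function(x, what, lineno) {
  v <- suppressWarnings(as.integer(x))
  bad <- is.na(v) | v != suppressWarnings(as.numeric(x))
  if (any(bad)) {
    stop("malformed ", what, " at line ", lineno[which(bad)[1L]], call. = FALSE)
  }
  v
}

.check_interval <- function(start, end, lineno) {
  bad <- !(start >= 0L & start < end)
  if (any(bad)) {
    stop("invalid interval (need 0 <= start < end) at line ",
         lineno[which(bad)[1L]], call. = FALSE)
  }
}

#' Read genomic interval files
#'
#' Reads peak calls (BED or narrowPeak), miRBase-dialect GFF3 stem-loop
#' annotation, or a pri-miRNA coordinate table. All coordinates are
#' normalized to the 0-based half-open convention on read: GFF3 is 1-based
#' closed, so its start is decremented by one; BED-family formats are kept
#' as is. Records preserve input order.
#'
#' @param path Path to the file.
#' @param format One of `"bed"`, `"narrowPeak"`, `"gff3_mirbase"`,
#'   `"pri_table"`.
#' @param signal_column For BED input, which column carries the signal:
#'   `"auto"` (signalValue column 7 when present, otherwise score column 5,
#'   otherwise 0), `"signalValue"` (column 7, required), or `"score"`
#'   (column 5, required).
#' @return For `bed`/`narrowPeak`: a data.frame with columns `chrom`,
#'   `start`, `end`, `id`, `strand`, `signal`. For `gff3_mirbase`: a
#'   data.frame with `chrom`, `start`, `end`, `strand`, `type`, `id`,
#'   `name`. For `pri_table`: a data.frame with `mirna_id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @export
read_intervals <- function(path,
                           format = c("bed", "narrowPeak", "gff3_mirbase", "pri_table"),
                           signal_column = c("auto", "signalValue", "score")) {
  format <- match.arg(format)
  signal_column <- match.arg(signal_column)
  switch(format,
    bed = .read_bed(path, signal_column),
    narrowPeak = .read_bed(path, "signalValue"),
    gff3_mirbase = .read_gff3_mirbase(path),
    pri_table = .read_pri_table(path)
  )
}

.read_bed <- function(path, signal_column) {
  lf <- .read_lines_nonempty(path)
  if (length(lf$lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      id = character(), strand = character(), signal = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lf$lines, "\t| +")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line (fewer than 3 fields) at line ",
         lf$lineno[which(nf < 3L)[1L]], call. = FALSE)
  }
  col <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  chrom <- col(1)
  start <- .parse_int(col(2), "start coordinate", lf$lineno)
  end <- .parse_int(col(3), "end coordinate", lf$lineno)
  .check_interval(start, end, lf$lineno)
  id <- col(4)
  id[is.na(id)] <- paste0("feature_", seq_along(chrom))[is.na(id)]
  strand <- col(6, default = ".")
  strand[is.na(strand) | !strand %in% c("+", "-", ".")] <- "."
  sigval <- suppressWarnings(as.numeric(col(7)))
  score <- suppressWarnings(as.numeric(col(5)))
  signal <- switch(signal_column,
    auto = ifelse(!is.na(sigval), sigval, ifelse(!is.na(score), score, 0)),
    signalValue = {
      if (anyNA(sigval)) {
        stop("missing signalValue (column 7) at line ",
             lf$lineno[which(is.na(sigval))[1L]], call. = FALSE)
      }
      sigval
    },
    score = {
      if (anyNA(score)) {
        stop("missing score (column 5) at line ",
             lf$lineno[which(is.na(score))[1L]], call. = FALSE)
      }
      score
    }
  )
  if (any(signal < 0)) {
    stop("negative signal at line ", lf$lineno[which(signal < 0)[1L]],
         call. = FALSE)
  }
  data.frame(chrom = chrom, start = start, end = end, id = id,
             strand = strand, signal = signal, stringsAsFactors = FALSE)
}

.gff3_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
  out <- rep(NA_character_, length(attrs))
  hit <- lengths(regmatches(attrs, gregexpr(paste0("(^|;)", key, "="), attrs))) > 0
  out[hit] <- sub(paste0("^(;)?", key, "="), "", sub("^;", "", m))
  out
}

.read_gff3_mirbase <- function(path) {
  lf <- .read_lines_nonempty(path)
  fields <- strsplit(lf$lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    stop("malformed GFF3 line (fewer than 9 fields) at line ",
         lf$lineno[which(nf < 9L)[1L]], call. = FALSE)
  }
  col <- function(i) vapply(fields, `[`, character(1), i)
  start1 <- .parse_int(col(4), "start coordinate", lf$lineno)
  end1 <- .parse_int(col(5), "end coordinate", lf$lineno)
  start <- start1 - 1L  # 1-based closed -> 0-based half-open
  .check_interval(start, end1, lf$lineno)
  strand <- col(7)
  attrs <- col(9)
  id <- .gff3_attr(attrs, "ID")
  name <- .gff3_attr(attrs, "Name")
  if (anyNA(id) && anyNA(name)) {
    miss <- which(is.na(id) & is.na(name))
    if (length(miss)) {
      stop("GFF3 record without an ID or Name attribute at line ",
           lf$lineno[miss[1L]], call. = FALSE)
    }
  }
  name[is.na(name)] <- id[is.na(name)]
  id[is.na(id)] <- name[is.na(id)]
  data.frame(chrom = col(1), start = start, end = end1, strand = strand,
             type = col(3), id = id, name = name, stringsAsFactors = FALSE)
}

.read_pri_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pri table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(!(df$start >= 0L & df$start < df$end))) {
    stop("invalid pri-miRNA interval (need 0 <= start < end)", call. = FALSE)
  }
  df[need]
}

#' Convert miRBase GFF3 records to a miRNA locus table
#'
#' Keeps stem-loop (`miRNA_primary_transcript`) records and parses the
#' miRBase name into its numeric index and species prefix. The coding
#' strand must be defined (`+` or `-`).
#'
#' @param gff data.frame from `read_intervals(format = "gff3_mirbase")`.
#' @return data.frame with columns `name`, `chrom`, `start`, `end`,
#'   `strand`, `number_index`, `species_prefix`.
#' @export
as_mirna_loci <- function(gff) {
  x <- gff[gff$type == "miRNA_primary_transcript", , drop = FALSE]
  if (any(!x$strand %in% c("+", "-"))) {
    stop("miRNA locus without a defined coding strand: ",
         x$name[which(!x$strand %in% c("+", "-"))[1L]], call. = FALSE)
  }
  data.frame(name = x$name, chrom = x$chrom, start = x$start, end = x$end,
             strand = x$strand,
             number_index = parse_mirna_number(x$name),
             species_prefix = sub("-.*$", "", x$name),
             stringsAsFactors = FALSE)
}

#' Read a quantification TSV
#'
#' Tab-separated with a header. The id and abundance columns are named
#' explicitly because quantification table layouts vary across pipelines.
#'
#' @param path Path to the TSV.
#' @param id_col,abundance_col Column names holding the feature id and the
#'   abundance (e.g. FPKM).
#' @return Named numeric vector of abundances, names = feature ids.
#' @export
read_quant <- function(path, id_col = "gene_id", abundance_col = "FPKM") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (cn in c(id_col, abundance_col)) {
    if (!cn %in% names(df)) stop("missing column: ", cn, call. = FALSE)
  }
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids)) {
    stop("duplicated id in quantification file: ",
         ids[anyDuplicated(ids)], call. = FALSE)
  }
  ab <- as.numeric(df[[abundance_col]])
  if (anyNA(ab)) stop("non-numeric abundance in column ", abundance_col,
                      call. = FALSE)
  if (any(ab < 0)) stop("negative abundance for id ", ids[which(ab < 0)[1L]],
                        call. = FALSE)
  stats::setNames(ab, ids)
}

#' Read a chrom.sizes file
#'
#' @param path Two-column whitespace-separated text: chromosome name, length.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  lf <- .read_lines_nonempty(path)
  if (length(lf$lines) == 0L) return(stats::setNames(integer(), character()))
  fields <- strsplit(trimws(lf$lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2L)) stop("malformed chrom.sizes line at line ",
                         lf$lineno[which(nf < 2L)[1L]], call. = FALSE)
  chrom <- vapply(fields, `[`, character(1), 1)
  len <- .parse_int(vapply(fields, `[`, character(1), 2), "chromosome length",
                    lf$lineno)
  if (anyDuplicated(chrom)) stop("duplicate chromosome: ",
                                 chrom[anyDuplicated(chrom)], call. = FALSE)
  if (any(len <= 0L)) stop("non-positive length for chromosome ",
                           chrom[which(len <= 0L)[1L]], call. = FALSE)
  stats::setNames(len, chrom)
}

# ---- writers (round-trip partners of the readers) ----

#' Write intervals back to disk
#'
#' Inverse of [read_intervals()]: integer coordinates are reproduced
#' exactly, signals with fixed 4-decimal formatting.
#'
#' @param x Data.frame as returned by the corresponding reader.
#' @param path Output path.
#' @param format One of `"narrowPeak"`, `"gff3_mirbase"`, `"pri_table"`.
#' @export
write_intervals <- function(x, path,
                            format = c("narrowPeak", "gff3_mirbase", "pri_table")) {
  format <- match.arg(format)
  lines <- switch(format,
    narrowPeak = sprintf("%s\t%d\t%d\t%s\t0\t%s\t%s\t-1\t-1\t-1",
                         x$chrom, x$start, x$end, x$id, x$strand,
                         sprintf("%.4f", x$signal)),
    gff3_mirbase = c("##gff-version 3",
                     sprintf("%s\t.\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                             x$chrom, x$type, x$start + 1L, x$end, x$strand,
                             x$id, x$name)),
    pri_table = c(paste(c("mirna_id", "chrom", "start", "end", "strand"),
                        collapse = "\t"),
                  sprintf("%s\t%s\t%d\t%d\t%s", x$mirna_id, x$chrom,
                          x$start, x$end, x$strand))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a quantification TSV
#' @param quant Named numeric vector.
#' @param path Output path.
#' @param id_col,abundance_col Header names to emit.
#' @export
write_quant <- function(quant, path, id_col = "gene_id", abundance_col = "FPKM") {
  writeLines(c(paste(id_col, abundance_col, sep = "\t"),
               sprintf("%s\t%.6f", names(quant), unname(quant))), path)
  invisible(path)
}

#' Write a chrom.sizes file
#' @param sizes Named integer vector.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", names(sizes), unname(sizes)), path)
  invisible(path)
}
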