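# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests. Everything here is deliberately naive (O(n*m)
# scans, pair counting, direct agglomeration) and independent of the
# package's implementation paths.

brute_link <- function(loci, features, strand_mode = "both", agg = "sum") {
  sig_col <- if ("signal" %in% names(features)) "signal" else "abundance"
  id_col <- if ("name" %in% names(loci)) "name" else "id"
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    ov <- features$chrom == loci$chrom[i] &
      features$start < loci$end[i] & loci$start[i] < features$end
    if (strand_mode == "match") ov <- ov & features$strand == loci$strand[i]
    s <- features[[sig_col]][ov]
    if (!length(s)) return(NULL)
    data.frame(mirna_id = loci[[id_col]][i], n_features = length(s),
               signal = if (agg == "sum") sum(s) else max(s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(mirna_id = character(), n_features = integer(),
                      signal = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

brute_midrank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

brute_u <- function(a, b) {
  gt <- sum(outer(a, b, ">"))
  ties <- sum(outer(a, b, "=="))
  gt + ties / 2
}

brute_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# naive agglomeration over a full distance matrix; returns merges ordered
# by execution, each with the sorted member set and the merge height
brute_agglomerate <- function(d, linkage = "average") {
  clusters <- as.list(rownames(d))
  active <- seq_along(clusters)
  merges <- list()
  while (length(active) > 1L) {
    bestd <- Inf
    best <- c(NA_integer_, NA_integer_)
    for (ii in seq_along(active)) {
      for (jj in seq_len(ii - 1L)) {
        a <- clusters[[active[ii]]]
        b <- clusters[[active[jj]]]
        cross <- d[a, b, drop = FALSE]
        dd <- switch(linkage, average = mean(cross), complete = max(cross),
                     single = min(cross))
        if (dd < bestd - 1e-12) {
          bestd <- dd
          best <- c(active[jj], active[ii])
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- list(members = merged, height = bestd)
    clusters[[best[1]]] <- merged
    active <- setdiff(active, best[2])
  }
  merges
}

hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    mem <- character()
    for (k in hc$merge[i, ]) {
      mem <- c(mem, if (k < 0) hc$labels[-k] else sets[[k]]$members)
    }
    sets[[i]] <- list(members = sort(mem), height = hc$height[i])
  }
  sets
}

random_loci <- function(n, chroms = c("chr1", "chr2"), chrom_length = 1e6,
                        width_range = c(50, 5000)) {
  w <- as.integer(runif(n, width_range[1], width_range[2]))
  s <- as.integer(runif(n, 0, chrom_length - max(w)))
  data.frame(name = sprintf("hsa-mir-%d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             start = s, end = s + w,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

random_features <- function(m, chroms = c("chr1", "chr2"), chrom_length = 1e6,
                            width_range = c(50, 3000),
                            strands = c("+", "-", ".")) {
  w <- as.integer(runif(m, width_range[1], width_range[2]))
  s <- as.integer(runif(m, 0, chrom_length - max(w)))
  data.frame(chrom = sample(chroms, m, replace = TRUE),
             start = s, end = s + w,
             id = sprintf("f%d", seq_len(m)),
             strand = sample(strands, m, replace = TRUE),
             signal = round(runif(m, 0, 100), 3),
             stringsAsFactors = FALSE)
}

# small, fast simulation settings for unit tests
small_sim_config <- function(...) {
  simulation_config(n_chroms = 2L, chrom_length = 2e7, n_early = 60L,
                    n_late = 90L, n_decoy_peaks = 40L,
                    n_decoy_transcripts = 40L, ...)
}
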