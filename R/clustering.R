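# Hierarchical clustering of samples by their correlation-coefficient
# profiles across a shared (window x filter) condition list, mirroring the
# Cluster 3.0 conventions: euclidean, 1 - Pearson, or 1 - uncentered
# correlation distances, with single/average/complete linkage.

#' Assemble correlation profiles into a sample x condition matrix
#'
#' Every sample must provide a coefficient for every condition; a missing
#' combination is an error at assembly (profiles must share the identical
#' condition ordering).
#'
#' @param tbl data.frame of correlation results with a sample id column, a
#'   value column, and one or more condition columns.
#' @param sample_col,value_col Column names.
#' @param condition_cols Character vector of columns jointly defining a
#'   condition (e.g. `c("window_kb", "filter")`).
#' @return Numeric matrix, rows = samples (lexicographic), columns =
#'   conditions (lexicographic label order).
#' @export
assemble_profiles <- function(tbl, sample_col = "sample",
                              condition_cols = c("window_kb", "filter"),
                              value_col = "coefficient") {
  cond <- do.call(paste, c(tbl[condition_cols], sep = "|"))
  samples <- sort(unique(tbl[[sample_col]]))
  conds <- sort(unique(cond))
  m <- matrix(NA_real_, length(samples), length(conds),
              dimnames = list(samples, conds))
  m[cbind(match(tbl[[sample_col]], samples), match(cond, conds))] <-
    tbl[[value_col]]
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("missing condition ", conds[bad[2L]], " for sample ",
         samples[bad[1L]], call. = FALSE)
  }
  m
}

.profile_metric <- function(p, q, metric) {
  switch(metric,
    euclidean = sqrt(sum((p - q)^2)),
    one_minus_pearson = 1 - stats::cor(p, q),
    one_minus_uncentered = 1 - sum(p * q) / sqrt(sum(p^2) * sum(q^2))
  )
}

#' Distance between two correlation profiles
#'
#' @param p,q Numeric vectors over the same condition list.
#' @param metric `"euclidean"`, `"one_minus_pearson"`, or
#'   `"one_minus_uncentered"` (Cluster 3.0's customary default).
#' @return Non-negative real; zero iff identical (euclidean) or perfectly
#'   correlated (correlation metrics).
#' @export
profile_distance <- function(p, q,
                             metric = c("one_minus_uncentered",
                                        "one_minus_pearson", "euclidean")) {
  metric <- match.arg(metric)
  if (length(p) != length(q)) stop("profile length mismatch", call. = FALSE)
  .profile_metric(p, q, metric)
}

.profile_dist <- function(profiles, metric) {
  n <- nrow(profiles)
  d <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- .profile_metric(profiles[i, ], profiles[j, ], metric)
    }
  }
  stats::as.dist(d)
}

#' Hierarchical clustering of correlation profiles
#'
#' Agglomerates samples with the chosen metric and linkage. Samples are
#' ordered lexicographically by id before clustering so the merge order is
#' deterministic given the input set. The tree serializes to Newick.
#'
#' @param profiles Matrix from [assemble_profiles()] (rows = samples).
#' @param metric See [profile_distance()].
#' @param linkage `"average"`, `"complete"`, or `"single"`.
#' @return A `mir_cluster` list: `hclust` (the stats::hclust tree),
#'   `newick` (character), `merges` (data.frame node/children/height),
#'   `metric`, `linkage`.
#' @export
hierarchical_cluster <- function(profiles,
                                 metric = c("one_minus_uncentered",
                                            "one_minus_pearson", "euclidean"),
                                 linkage = c("average", "complete", "single")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  if (nrow(profiles) < 2L) stop("need at least 2 profiles", call. = FALSE)
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  d <- .profile_dist(profiles, metric)
  hc <- stats::hclust(d, method = linkage)
  phylo <- ape::as.phylo(hc)
  nick <- ape::write.tree(phylo)
  labels <- hc$labels
  child_name <- function(k) if (k < 0) labels[-k] else paste0("node", k)
  merges <- data.frame(
    node = paste0("node", seq_len(nrow(hc$merge))),
    child1 = vapply(hc$merge[, 1], child_name, character(1)),
    child2 = vapply(hc$merge[, 2], child_name, character(1)),
    height = hc$height,
    stringsAsFactors = FALSE
  )
  structure(list(hclust = hc, newick = nick, merges = merges,
                 metric = metric, linkage = linkage),
            class = "mir_cluster")
}

#' @export
print.mir_cluster <- function(x, ...) {
  cat("Hierarchical clustering of", length(x$hclust$labels), "samples (",
      x$metric, ",", x$linkage, "linkage )\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' @method plot mir_cluster
#' @export
plot.mir_cluster <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = "", main = "Correlation-profile clustering",
       ...)
  invisible(x)
}

#' Sample memberships of the top split of a cluster tree
#'
#' Cuts the tree into two clusters and returns the membership vector,
#' useful for checking that well-separated regimes are recovered.
#'
#' @param clus A `mir_cluster` object.
#' @return Named integer vector (1/2) over sample ids.
#' @export
top_split <- function(clus) {
  stats::cutree(clus$hclust, k = 2)
}
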