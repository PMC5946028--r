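# End-to-end orchestration: simulate (or accept) samples, link signals over
# a window x filter grid, correlate (plain, rank, weighted), compare
# early/late groups, run the replicate/attenuation analysis, and cluster
# samples by their correlation profiles.

#' Pipeline run configuration
#'
#' @param sim A [simulation_config()] describing the synthetic samples.
#' @param n_samples Number of samples to simulate (seeds `seed`,
#'   `seed + 1`, ...); clustering requires at least 2.
#' @param windows_kb Extension windows in kb (non-empty, all > 0).
#' @param cutoffs Name-number cut-offs to sweep.
#' @param use_pri Include the pri-miRNA evidence filter (with a cut-off at
#'   1000).
#' @param weight_factors Weighting factors for weighted Pearson
#'   (`"w1"`, `"w2"`, `"w3"`; empty vector to skip).
#' @param agg_chip,agg_rna Aggregation for peak signal / mRNA abundance
#'   (`"sum"` is the default; `"max"` is selectable).
#' @param replicate Which replicate feeds the main sweep (one replicate is
#'   used for correlation studies; the rest feed the replicate analysis).
#' @param comparison list(window_kb, cutoff): the condition at which the
#'   early/late Mann-Whitney comparison is run.
#' @param replicate_spec list(window_kb, filter): the condition at which
#'   replicate cross-pairings and attenuation correction are computed.
#' @param cluster_metric,cluster_linkage Clustering options (see
#'   [hierarchical_cluster()]).
#' @param seed Base seed.
#' @param outdir Output directory for TSV/Newick/manifest files (NULL: no
#'   files written).
#' @return A `mirtrans_run_config` list.
#' @export
run_config <- function(sim = simulation_config(),
                       n_samples = 1L,
                       windows_kb = c(1, 2, 5, 10, 20),
                       cutoffs = c(1000L, 600L),
                       use_pri = TRUE,
                       weight_factors = c("w1", "w2", "w3"),
                       agg_chip = "sum",
                       agg_rna = "sum",
                       replicate = 1L,
                       comparison = list(window_kb = 10, cutoff = 600L),
                       replicate_spec = list(window_kb = 20, filter = "all"),
                       cluster_metric = "one_minus_uncentered",
                       cluster_linkage = "average",
                       seed = 1L,
                       outdir = NULL) {
  cfg <- as.list(environment())
  if (length(cfg$windows_kb) == 0L || any(cfg$windows_kb <= 0)) {
    stop("windows_kb must be non-empty with all entries > 0", call. = FALSE)
  }
  if (length(cfg$cutoffs) && any(cfg$cutoffs <= 0)) {
    stop("cutoffs must be positive", call. = FALSE)
  }
  stopifnot(cfg$n_samples >= 1)
  structure(cfg, class = "mirtrans_run_config")
}

.filter_loci <- function(sample, filter) {
  loci <- sample$loci
  if (filter == "all") return(loci)
  if (filter == "pri") return(apply_pri_filter(loci, sample$pri, 1000L))
  if (startsWith(filter, "cutoff_")) {
    thr <- as.integer(sub("cutoff_", "", filter))
    return(apply_number_cutoff(loci, thr)$early)
  }
  stop("unknown filter: ", filter, call. = FALSE)
}

.features_for_mode <- function(sample, mode, replicate) {
  if (mode == "chip") sample$peaks[[replicate]] else
    sample$transcripts[[replicate]]
}

#' Correlation sweep over windows and filters for one sample
#'
#' For each (mode, window, filter) the loci are filtered, extended,
#' linked to the track's features under the mode's strand rule (ChIP: both
#' strands; RNA: coding strand only), paired with mature miRNA abundance,
#' and correlated by every requested method.
#'
#' @param sample A `mirtrans_sim` object (or equivalent list of inputs).
#' @param config A [run_config()].
#' @param sample_id Label for the `sample` column.
#' @return data.frame `sample`, `mode`, `window_kb`, `filter`, `method`,
#'   `weight`, `coefficient`, `n`, `p`.
#' @export
sweep_correlations <- function(sample, config = run_config(),
                               sample_id = "sample1") {
  filters <- c("all",
               if (length(config$cutoffs)) paste0("cutoff_", config$cutoffs),
               if (config$use_pri) "pri")
  rows <- list()
  for (mode in c("chip", "rna")) {
    features <- .features_for_mode(sample, mode, config$replicate)
    strand_mode <- if (mode == "chip") "both" else "match"
    agg <- if (mode == "chip") config$agg_chip else config$agg_rna
    quant <- sample$mirna_quant[[config$replicate]]
    for (filter in filters) {
      loci <- .filter_loci(sample, filter)
      for (w in config$windows_kb) {
        ext <- extend_intervals(loci, w * 1000, sample$chrom_sizes)
        linked <- link_signals(ext, features, strand_mode = strand_mode,
                               agg = agg, window_kb = w, mode = mode)
        pairs <- build_paired_vectors(linked, quant)
        res <- list(cor_spearman(pairs$x, pairs$y),
                    cor_pearson(pairs$x, pairs$y))
        for (wf in config$weight_factors) {
          wp <- attach_weights(pairs, sample$weights, wf)
          res <- c(res, list(cor_weighted_pearson(wp$x, wp$y, wp$w,
                                                  weight_factor = wf)))
        }
        for (r in res) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sample_id, mode = mode, window_kb = w, filter = filter,
            method = r$method,
            weight = if (is.na(r$weight_factor)) "none" else r$weight_factor,
            coefficient = r$coefficient, n = r$n, p = r$p_two_sided,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Early/late group comparison at one pipeline condition
#'
#' Splits loci at the cut-off, links both tracks at the given window, and
#' compares mature miRNA abundance and linked mRNA abundance between the
#' groups with the Mann-Whitney U test.
#'
#' @param sample A `mirtrans_sim` object.
#' @param window_kb Extension window (kb).
#' @param cutoff Name-number cut-off defining early/late.
#' @param replicate Replicate index to use.
#' @return list with `mirna` and `mrna`, each a `mir_group_comparison`
#'   (group a = early, group b = late).
#' @export
compare_early_late <- function(sample, window_kb = 10, cutoff = 600L,
                               replicate = 1L) {
  split <- apply_number_cutoff(sample$loci, cutoff)
  quant <- sample$mirna_quant[[replicate]]
  tx <- sample$transcripts[[replicate]]
  linked_ab <- function(loci) {
    ext <- extend_intervals(loci, window_kb * 1000, sample$chrom_sizes)
    linked <- link_signals(ext, tx, strand_mode = "match", agg = "sum",
                           window_kb = window_kb, mode = "rna")
    build_paired_vectors(linked, quant)
  }
  early <- linked_ab(split$early)
  late <- linked_ab(split$late)
  list(mirna = mann_whitney_u(early$y, late$y),
       mrna = mann_whitney_u(early$x, late$x))
}

#' Replicate cross-pairings and attenuation correction for one sample
#'
#' Links each track replicate at the given condition, restricts to miRNAs
#' linked in both replicates, computes the four cross-correlations with the
#' two miRNA replicates (pairings A-D), the replicate-replicate
#' reliabilities, and the attenuation-corrected estimate, for both the
#' ChIP and RNA tracks.
#'
#' @param sample A `mirtrans_sim` object with >= 2 replicates.
#' @param window_kb,filter Condition at which linking is done.
#' @param method Correlation method (the analysis is customarily run on
#'   rank correlations).
#' @return list per mode (`chip`, `rna`) of [replicate_correction()]
#'   outputs (plus `n`), or NULL with a message when replicates are absent.
#' @export
replicate_analysis <- function(sample, window_kb = 20, filter = "all",
                               method = "spearman") {
  if (length(sample$peaks) < 2L || length(sample$mirna_quant) < 2L) {
    message("no replicate datasets; skipping attenuation correction")
    return(NULL)
  }
  loci <- .filter_loci(sample, filter)
  ext <- extend_intervals(loci, window_kb * 1000, sample$chrom_sizes)
  out <- list()
  for (mode in c("chip", "rna")) {
    strand_mode <- if (mode == "chip") "both" else "match"
    linked <- lapply(1:2, function(j) {
      link_signals(ext, .features_for_mode(sample, mode, j),
                   strand_mode = strand_mode, agg = "sum",
                   window_kb = window_kb, mode = mode)
    })
    ids <- sort(Reduce(intersect, c(lapply(linked, `[[`, "mirna_id"),
                                    list(names(sample$mirna_quant[[1]])))))
    x1 <- linked[[1]]$signal[match(ids, linked[[1]]$mirna_id)]
    x2 <- linked[[2]]$signal[match(ids, linked[[2]]$mirna_id)]
    y1 <- unname(sample$mirna_quant[[1]][ids])
    y2 <- unname(sample$mirna_quant[[2]][ids])
    rc <- replicate_correction(x1, x2, y1, y2, method = method)
    rc$n <- length(ids)
    out[[mode]] <- rc
  }
  out
}

.config_digest <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(config)), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Simulates `n_samples` samples, runs the correlation sweep on each, the
#' early/late comparison and (when replicates exist) the replicate /
#' attenuation analysis on the first sample, and, with >= 2 samples,
#' clusters the samples by their rank-correlation profiles. Re-running
#' with an identical configuration reproduces identical tables.
#'
#' @param config A [run_config()].
#' @return A `mirtrans_run` list: `correlations` (data.frame),
#'   `group_comparison`, `replicates`, `cluster` (or NULL), `samples`
#'   (the simulated `mirtrans_sim` objects), `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  samples <- lapply(seq_len(config$n_samples) - 1L, function(i) {
    simulate_mirna_sample(config$sim, seed = config$seed + i)
  })
  ids <- sprintf("sample%02d", seq_len(config$n_samples))
  tab <- do.call(rbind, Map(function(s, id) {
    sweep_correlations(s, config, sample_id = id)
  }, samples, ids))
  rownames(tab) <- NULL

  gc_res <- compare_early_late(samples[[1]],
                               window_kb = config$comparison$window_kb,
                               cutoff = config$comparison$cutoff,
                               replicate = config$replicate)
  rep_res <- replicate_analysis(samples[[1]],
                                window_kb = config$replicate_spec$window_kb,
                                filter = config$replicate_spec$filter)
  clus <- NULL
  if (config$n_samples >= 2L) {
    sub <- tab[tab$method == "spearman" & tab$mode == "rna", , drop = FALSE]
    prof <- assemble_profiles(sub)
    clus <- hierarchical_cluster(prof, metric = config$cluster_metric,
                                 linkage = config$cluster_linkage)
  }
  manifest <- list(config_md5 = .config_digest(config),
                   seed = config$seed,
                   n_samples = config$n_samples,
                   package_version = as.character(
                     utils::packageVersion("mirtrans")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."))
  run <- structure(list(correlations = tab, group_comparison = gc_res,
                        replicates = rep_res, cluster = clus,
                        samples = samples, manifest = manifest,
                        config = config),
                   class = "mirtrans_run")
  if (!is.null(config$outdir)) write_run(run, config$outdir)
  run
}

#' Write a pipeline run's result bundle
#'
#' Emits `correlations.tsv`, `group_comparison.tsv`, `replicates.tsv`,
#' `cluster.newick` + `cluster_merges.tsv` (when present) and
#' `manifest.txt` into `dir`. Numeric columns use fixed formatting so two
#' runs with identical configuration produce byte-identical files.
#'
#' @param run A `mirtrans_run` object.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- run$correlations
  lines <- c(paste(names(tab), collapse = "\t"),
             sprintf("%s\t%s\t%g\t%s\t%s\t%s\t%.10g\t%.10g\t%.6g",
                     tab$sample, tab$mode, tab$window_kb, tab$filter,
                     tab$method, tab$weight, tab$coefficient, tab$n, tab$p))
  writeLines(lines, file.path(dir, "correlations.tsv"))

  gc_line <- function(track, g) {
    sprintf("%s\t%.6g\t%.6g\t%.6g\t%.6g\t%d\t%.6g\t%.6g\t%d",
            track, g$u_statistic, g$p_two_sided, g$mean_a, g$sem_a, g$n_a,
            g$mean_b, g$sem_b, g$n_b)
  }
  writeLines(c("track\tU\tp\tmean_early\tsem_early\tn_early\tmean_late\tsem_late\tn_late",
               gc_line("mirna", run$group_comparison$mirna),
               gc_line("mrna", run$group_comparison$mrna)),
             file.path(dir, "group_comparison.tsv"))

  if (!is.null(run$replicates)) {
    rl <- c("mode\tpairing\tvalue")
    for (mode in names(run$replicates)) {
      r <- run$replicates[[mode]]
      rl <- c(rl,
              sprintf("%s\t%s\t%.10g", mode, names(r$cross), r$cross),
              sprintf("%s\tr_xx\t%.10g", mode, r$r_xx),
              sprintf("%s\tr_yy\t%.10g", mode, r$r_yy),
              sprintf("%s\tcorrected\t%.10g", mode, r$corrected$corrected))
    }
    writeLines(rl, file.path(dir, "replicates.tsv"))
  }
  if (!is.null(run$cluster)) {
    writeLines(run$cluster$newick, file.path(dir, "cluster.newick"))
    m <- run$cluster$merges
    writeLines(c("node\tchild1\tchild2\theight",
                 sprintf("%s\t%s\t%s\t%.10g", m$node, m$child1, m$child2,
                         m$height)),
               file.path(dir, "cluster_merges.tsv"))
  }
  writeLines(sprintf("%s\t%s", names(run$manifest),
                     vapply(run$manifest, as.character, character(1))),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @export
print.mirtrans_run <- function(x, ...) {
  cat("mirtrans pipeline run\n")
  cat(sprintf("  %d sample(s), %d correlation rows (windows: %s kb)\n",
              x$config$n_samples, nrow(x$correlations),
              paste(x$config$windows_kb, collapse = ", ")))
  sp <- x$correlations[x$correlations$method == "spearman" &
                         x$correlations$mode == "rna", ]
  agg <- stats::aggregate(coefficient ~ filter, sp, mean)
  cat("  mean mRNA~miRNA Spearman by filter:\n")
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("    %-12s %+.3f\n", agg$filter[i], agg$coefficient[i]))
  }
  gm <- x$group_comparison
  cat(sprintf("  early vs late: miRNA p = %.3g, mRNA p = %.3g\n",
              gm$mirna$p_two_sided, gm$mrna$p_two_sided))
  if (!is.null(x$replicates)) {
    cat(sprintf("  attenuation-corrected (chip): %.3f (raw mean %.3f)\n",
                x$replicates$chip$corrected$corrected,
                x$replicates$chip$corrected$raw_mean))
  }
  invisible(x)
}

#' Plot correlation coefficients against extension window
#'
#' One line per filter (rank correlation, RNA track), averaged over
#' samples: the window-extension trend at a glance.
#'
#' @param x A `mirtrans_run` object.
#' @param mode,method Which rows to plot.
#' @param ... Passed to [graphics::matplot()].
#' @method plot mirtrans_run
#' @export
plot.mirtrans_run <- function(x, mode = "rna", method = "spearman", ...) {
  sub <- x$correlations[x$correlations$mode == mode &
                          x$correlations$method == method, ]
  agg <- stats::aggregate(coefficient ~ window_kb + filter, sub, mean)
  wide <- stats::reshape(agg, idvar = "window_kb", timevar = "filter",
                         direction = "wide")
  wide <- wide[order(wide$window_kb), ]
  graphics::matplot(wide$window_kb, wide[, -1, drop = FALSE], type = "b",
                    pch = 19, lty = 1, xlab = "extension window (kb)",
                    ylab = paste(method, "coefficient"), ...)
  graphics::legend("bottomright",
                   legend = sub("coefficient\\.", "", names(wide)[-1]),
                   col = seq_len(ncol(wide) - 1), lty = 1, pch = 19,
                   bty = "n")
  invisible(x)
}
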