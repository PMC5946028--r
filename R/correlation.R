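# Correlation statistics: Spearman, Pearson, weighted Pearson with
# two-sided p-values (t approximation), replicate-based attenuation
# (disattenuation) correction, and Mann-Whitney group comparison.

new_mir_correlation <- function(method, coefficient, n, p, flag = NA_character_,
                                weight_factor = NA_character_) {
  structure(list(method = method, coefficient = coefficient, n = n,
                 p_two_sided = p, flag = flag, weight_factor = weight_factor),
            class = "mir_correlation")
}

#' @export
print.mir_correlation <- function(x, ...) {
  wf <- if (!is.na(x$weight_factor)) paste0(" (", x$weight_factor, ")") else ""
  cat(sprintf("%s correlation%s: r = %s, n = %s, two-sided p = %s\n",
              x$method, wf, format(x$coefficient, digits = 4),
              format(x$n, digits = 6),
              format(x$p_two_sided, digits = 4)))
  if (!is.na(x$flag)) cat("flag:", x$flag, "\n")
  invisible(x)
}

.t_pvalue <- function(r, df) {
  if (is.na(r) || df <= 0) return(NA_real_)
  if (abs(r) >= 1) return(0)
  2 * stats::pt(-abs(r) * sqrt(df / (1 - r^2)), df)
}

.check_xy <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs for a correlation", call. = FALSE)
}

#' Spearman rank correlation with two-sided p-value
#'
#' Midrank (average) tie handling; the coefficient is the Pearson
#' correlation of the rank vectors, with a two-sided p-value from the t
#' approximation on n - 2 degrees of freedom. A constant input vector
#' yields an undefined coefficient, reported as `NA` with an explanatory
#' flag rather than 0.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return A `mir_correlation` object.
#' @export
cor_spearman <- function(x, y) {
  .check_xy(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(new_mir_correlation("spearman", NA_real_, length(x), NA_real_,
                               flag = "constant_input"))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  r <- unname(ct$estimate)
  p <- if (abs(r) >= 1) 0 else unname(ct$p.value)
  new_mir_correlation("spearman", r, length(x), p)
}

#' Pearson correlation with two-sided p-value
#'
#' @inheritParams cor_spearman
#' @return A `mir_correlation` object.
#' @export
cor_pearson <- function(x, y) {
  .check_xy(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(new_mir_correlation("pearson", NA_real_, length(x), NA_real_,
                               flag = "constant_input"))
  }
  ct <- stats::cor.test(x, y)
  r <- unname(ct$estimate)
  p <- if (abs(r) >= 1) 0 else unname(ct$p.value)
  new_mir_correlation("pearson", r, length(x), p)
}

#' Weighted Pearson correlation (frequency-weight semantics)
#'
#' r_w = sum(w (x - xbar_w)(y - ybar_w)) /
#'       sqrt(sum(w (x - xbar_w)^2) sum(w (y - ybar_w)^2)), with weighted
#' means. The effective sample size is sum(w) (frequency weights, so with
#' integer weights the result equals the unweighted Pearson correlation of
#' the case-replicated data set); the p-value uses sum(w) - 2 degrees of
#' freedom. `normalize_weights = TRUE` rescales the weights to sum to n
#' for sensitivity analysis.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @param w Non-negative weights, sum(w) > 0.
#' @param weight_factor Optional label (`"w1"`, `"w2"`, `"w3"`) carried
#'   into the result.
#' @param normalize_weights Rescale weights to sum to n.
#' @return A `mir_correlation` object (`n` = effective sample size).
#' @export
cor_weighted_pearson <- function(x, y, w, weight_factor = NA_character_,
                                 normalize_weights = FALSE) {
  .check_xy(x, y)
  if (length(w) != length(x)) stop("weights must match x in length", call. = FALSE)
  if (any(w < 0)) stop("negative weight", call. = FALSE)
  sw <- sum(w)
  if (sw <= 0) stop("weights must sum to a positive value", call. = FALSE)
  if (normalize_weights) {
    w <- w * length(w) / sw
    sw <- sum(w)
  }
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) {
    return(new_mir_correlation("weighted_pearson", NA_real_, sw, NA_real_,
                               flag = "degenerate_weights",
                               weight_factor = weight_factor))
  }
  r <- sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
  r <- max(-1, min(1, r))  # guard rounding at |r| ~ 1
  new_mir_correlation("weighted_pearson", r, sw, .t_pvalue(r, sw - 2),
                      weight_factor = weight_factor)
}

#' Attenuation (disattenuation) correction from replicate reliabilities
#'
#' Estimates the noise-free correlation by dividing the mean observed
#' cross-correlation by the geometric mean of the replicate-replicate
#' reliabilities of the two measurements. Corrected values exceeding 1 in
#' magnitude are reported as-is with an `out_of_range` flag, never
#' silently clipped.
#'
#' @param cross_correlations Numeric vector of observed cross-correlations
#'   (e.g. the four replicate pairings), combined by arithmetic mean.
#' @param r_xx,r_yy Replicate-replicate correlations of the two
#'   measurements; both must be positive.
#' @return list with `corrected`, `raw_mean`, `r_xx`, `r_yy`, `flag`.
#' @export
attenuation_correct <- function(cross_correlations, r_xx, r_yy) {
  if (r_xx <= 0 || r_yy <= 0) {
    stop("attenuation correction undefined for non-positive reliabilities",
         call. = FALSE)
  }
  raw <- mean(cross_correlations)
  corrected <- raw / sqrt(r_xx * r_yy)
  flag <- if (abs(corrected) > 1) "out_of_range" else NA_character_
  list(corrected = corrected, raw_mean = raw, r_xx = r_xx, r_yy = r_yy,
       flag = flag)
}

#' Mann-Whitney U comparison of two groups
#'
#' U for group `a` counts pairs with a_i > b_j plus half the ties; the
#' two-sided p-value uses the tie-corrected normal approximation with
#' continuity correction. Per-group mean, standard error of the mean and
#' sample size are reported alongside.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @return A `mir_group_comparison` list: `u_statistic`, `p_two_sided`,
#'   `mean_a`, `sem_a`, `n_a`, `mean_b`, `sem_b`, `n_b`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty group", call. = FALSE)
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
  p <- unname(wt$p.value)
  if (is.na(p) || is.nan(p)) p <- 1  # zero-variance case: all values tied
  structure(list(u_statistic = unname(wt$statistic), p_two_sided = p,
                 mean_a = mean(a), sem_a = stats::sd(a) / sqrt(length(a)),
                 n_a = length(a),
                 mean_b = mean(b), sem_b = stats::sd(b) / sqrt(length(b)),
                 n_b = length(b)),
            class = "mir_group_comparison")
}

#' @export
print.mir_group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %s, two-sided p = %s\n",
              format(x$u_statistic), format(x$p_two_sided, digits = 4)))
  cat(sprintf("  group a: mean %s +/- %s (n = %d)\n",
              format(x$mean_a, digits = 4), format(x$sem_a, digits = 3), x$n_a))
  cat(sprintf("  group b: mean %s +/- %s (n = %d)\n",
              format(x$mean_b, digits = 4), format(x$sem_b, digits = 3), x$n_b))
  invisible(x)
}
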