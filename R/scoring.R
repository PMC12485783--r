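# Gene-set module scores (per-sample mean of per-gene z-scores) and
# marker-signature cell-population scores, with Wilcoxon / Welch group
# comparisons. Marker catalogs are pluggable inputs (GMT), never bundled.

#' Per-gene z-scores across samples
#'
#' z_ij = (x_ij - mean_i) / sd_i with the n-1 sample standard deviation.
#' Zero-variance genes map to all-zero rows so gene-set membership stays
#' stable.
#'
#' @param expr genes x samples numeric matrix on a normalized scale.
#' @return z-score matrix of the same dimensions.
#' @export
gene_zscores <- function(expr) {
  if (!is.matrix(expr) || ncol(expr) < 2L)
    stopf("z-scores need a matrix with at least 2 samples")
  mu <- rowMeans(expr)
  sd <- apply(expr, 1, stats::sd)
  z <- (expr - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' Gene-set module score
#'
#' score_j = mean over present set members of z_ij; missing members are
#' reported via the `missing` attribute.
#'
#' @param z z-score matrix from [gene_zscores()].
#' @param gene_set character vector of member genes (or a one-element named
#'   list).
#' @return named numeric vector of per-sample scores with attribute
#'   `missing` (absent members).
#' @export
module_score <- function(z, gene_set) {
  if (is.list(gene_set)) gene_set <- gene_set[[1]]
  present <- intersect(gene_set, rownames(z))
  if (!length(present))
    stopf("no gene-set member present in the expression matrix")
  s <- colMeans(z[present, , drop = FALSE])
  attr(s, "missing") <- setdiff(gene_set, present)
  s
}

#' Module scores for many gene sets
#'
#' @param z z-score matrix.
#' @param gene_sets named list of character vectors.
#' @return gene sets x samples matrix of mean z-scores.
#' @export
module_score_table <- function(z, gene_sets) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  t(vapply(gene_sets, function(gs) as.numeric(module_score(z, gs)),
           numeric(ncol(z)))) -> m
  colnames(m) <- colnames(z)
  m
}

#' Marker-signature cell-population scores
#'
#' score(population, sample) = mean log2 expression of the population's
#' markers present in the matrix (the marker-mean estimator family used by
#' bulk immune deconvolution tools). Populations with zero present markers
#' are dropped with a warning.
#'
#' @param expr genes x samples matrix of TMM-normalized log2 CPM (or any log2
#'   expression).
#' @param marker_sets named list of marker gene vectors.
#' @return populations x samples score matrix.
#' @export
signature_scores <- function(expr, marker_sets) {
  stopifnot(is.list(marker_sets), !is.null(names(marker_sets)))
  rows <- lapply(names(marker_sets), function(pop) {
    present <- intersect(marker_sets[[pop]], rownames(expr))
    if (!length(present)) {
      warnf("population '%s' has no marker in the matrix; excluded", pop)
      return(NULL)
    }
    colMeans(expr[present, , drop = FALSE])
  })
  names(rows) <- names(marker_sets)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stopf("no population has any marker present")
  do.call(rbind, rows)
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Uses the exact null distribution when both groups have at most 8
#' observations and there are no ties (so the n = 3 vs 3 minimum two-sided p
#' is 0.1); otherwise the normal approximation. All-tied input returns p = 1
#' with a warning.
#'
#' @param values numeric vector.
#' @param groups two-level labels aligned with `values`.
#' @return list with `statistic` (rank-sum W), `p_value`, `median_diff`
#'   (median A - median B).
#' @export
compare_groups_wilcoxon <- function(values, groups) {
  gi <- split_groups(groups)
  x <- values[gi$a]; y <- values[gi$b]
  if (!length(x) || !length(y)) stopf("each group needs >= 1 observation")
  md <- stats::median(x) - stats::median(y)
  if (length(unique(c(x, y))) == 1L) {
    warnf("all values tied across both groups; p = 1")
    return(list(statistic = NA_real_, p_value = 1, median_diff = 0))
  }
  exact <- length(x) <= 8L && length(y) <= 8L &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_diff = md)
}

#' Wilcoxon comparisons across a score table with BH adjustment
#'
#' @param scores populations (or gene sets) x samples matrix.
#' @param groups two-level labels per sample.
#' @return data.frame with `population`, `statistic`, `median_diff`,
#'   `p_value`, `q_value` (BH across rows).
#' @export
compare_groups_wilcoxon_table <- function(scores, groups) {
  res <- lapply(rownames(scores), function(pop) {
    r <- compare_groups_wilcoxon(scores[pop, ], groups)
    data.frame(population = pop, statistic = r$statistic,
               median_diff = r$median_diff, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  out
}

#' Two-sided Welch t-test
#'
#' Welch statistic with Welch-Satterthwaite degrees of freedom. Degenerate
#' zero-variance input is handled explicitly: equal means give p = 1,
#' unequal means give p = 0 with a warning.
#'
#' @param values numeric vector.
#' @param groups two-level labels aligned with `values`.
#' @return list with `t`, `df`, `p_value`, `mean_diff`.
#' @export
compare_groups_welch <- function(values, groups) {
  gi <- split_groups(groups)
  x <- values[gi$a]; y <- values[gi$b]
  if (length(x) < 2L || length(y) < 2L)
    stopf("each group needs >= 2 observations")
  vx <- stats::var(x); vy <- stats::var(y)
  dm <- mean(x) - mean(y)
  if (vx == 0 && vy == 0) {
    if (dm == 0) return(list(t = 0, df = NA_real_, p_value = 1, mean_diff = 0))
    warnf("zero variance in both groups with unequal means; p = 0")
    return(list(t = Inf * sign(dm), df = NA_real_, p_value = 0,
                mean_diff = dm))
  }
  se2 <- vx / length(x) + vy / length(y)
  tt <- dm / sqrt(se2)
  df <- se2^2 / ((vx / length(x))^2 / (length(x) - 1) +
                   (vy / length(y))^2 / (length(y) - 1))
  list(t = tt, df = df, p_value = 2 * stats::pt(-abs(tt), df),
       mean_diff = dm)
}
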