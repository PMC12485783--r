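# Expression-side quantities consumed by module scoring and the
# methylation-expression integration: low-count filtering, median-of-ratios
# size factors, TPM, TMM-normalized log2 CPM, a negative-binomial Wald
# differential-expression test (a deliberately simple stand-in so synthetic
# end-to-end runs need no external fitter), Benjamini-Hochberg adjustment and
# threshold-based DEG calling.

check_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stopf("'counts' must be a numeric matrix")
  if (any(counts < 0)) stopf("counts must be nonnegative")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stopf("counts must have unique row (gene) names")
  invisible(counts)
}

#' Remove genes with very low total counts
#'
#' @param counts genes x samples count matrix.
#' @param min_row_sum genes with row sum strictly below this are dropped
#'   (default 10).
#' @return filtered count matrix, samples unchanged.
#' @export
filter_low_counts <- function(counts, min_row_sum = 10) {
  check_counts(counts)
  keep <- rowSums(counts) >= min_row_sum
  if (!any(keep)) stopf("all genes removed by the low-count filter")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' s_j = median over reference genes of count_ij / geometric mean_i, where
#' reference genes are those with a positive count in every sample.
#'
#' @param counts genes x samples count matrix.
#' @return named numeric vector of per-sample size factors.
#' @export
size_factors_median_of_ratios <- function(counts) {
  check_counts(counts)
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use))
    stopf("no gene has positive counts in every sample; size factors undefined")
  sf <- apply(counts[use, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - loggeo[use])))
  sf
}

#' Transcripts per million
#'
#' TPM_ij = (count_ij / length_i) / sum_g (count_gj / length_g) * 1e6; no
#' pseudo-count is used in TPM itself.
#'
#' @param counts genes x samples count matrix.
#' @param gene_lengths positive lengths, named by gene or in row order.
#' @return TPM matrix; every column sums to 1e6.
#' @export
tpm <- function(counts, gene_lengths) {
  check_counts(counts)
  if (!is.null(names(gene_lengths)))
    gene_lengths <- gene_lengths[rownames(counts)]
  if (length(gene_lengths) != nrow(counts) || any(is.na(gene_lengths)) ||
      any(gene_lengths <= 0))
    stopf("'gene_lengths' must be positive and cover every gene")
  rate <- counts / gene_lengths
  denom <- colSums(rate)
  if (any(denom == 0)) stopf("a sample has zero counts; TPM undefined")
  sweep(rate, 2, denom, "/") * 1e6
}

#' log2(TPM + 1)
#' @param tpm_matrix output of [tpm()].
#' @return element-wise log2(TPM + 1).
#' @export
log2_tpm_plus1 <- function(tpm_matrix) log2(tpm_matrix + 1)

#' TMM normalization factors
#'
#' Trimmed mean of M-values between each sample and a reference sample:
#' gene-wise log2 ratios (M) are trimmed by `trim_m` per tail and average
#' log2 abundances (A) by `trim_a` per tail, genes with zeros excluded, and
#' the surviving M values combined by inverse-variance (binomial) weights.
#' The returned factors are normalized to geometric mean 1.
#'
#' @param counts genes x samples count matrix (>= 2 samples).
#' @param trim_m trim fraction on M values, each tail (default 0.30).
#' @param trim_a trim fraction on A values, each tail (default 0.05).
#' @param ref_column reference sample (index or name); default picks the
#'   sample whose upper quartile of scaled counts is closest to the mean
#'   upper quartile.
#' @return named numeric vector of TMM factors.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05,
                        ref_column = NULL) {
  check_counts(counts)
  if (ncol(counts) < 2L) stopf("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stopf("a sample has zero library size")
  if (is.null(ref_column)) {
    uq <- apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
    ref_column <- which.min(abs(uq - mean(uq)))
  }
  ref <- counts[, ref_column]
  nref <- lib[ref_column]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]; nobs <- lib[j]
    use <- obs > 0 & ref > 0
    if (sum(use) < 2L) stopf("fewer than 2 usable genes for TMM")
    m <- log2((obs[use] / nobs) / (ref[use] / nref))
    a <- 0.5 * log2((obs[use] / nobs) * (ref[use] / nref))
    w <- (nobs - obs[use]) / (nobs * obs[use]) +
      (nref - ref[use]) / (nref * ref[use])
    n <- length(m)
    # trim fractions apply per tail (the published TMM convention)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    rm_ <- rank(m)
    ra_ <- rank(a)
    keep <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
    if (!any(keep)) stopf("TMM trimming removed all genes")
    # inverse-variance weighting: w is the (delta-method) variance of M
    fj <- sum(m[keep] / w[keep]) / sum(1 / w[keep])
    if (!is.finite(fj) || abs(fj) < 1e-6) fj <- 0
    2^fj
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' TMM-normalized log2 counts per million
#'
#' log2((count * 1e6) / (library size * TMM factor) + 0.5), the input scale
#' used for marker-signature immune scoring and the integration layer.
#'
#' @inheritParams tmm_factors
#' @return log2 CPM matrix, same dimensions as `counts`.
#' @export
tmm_log2_cpm <- function(counts, trim_m = 0.30, trim_a = 0.05,
                         ref_column = NULL) {
  f <- tmm_factors(counts, trim_m, trim_a, ref_column)
  eff <- colSums(counts) * f
  log2(sweep(counts, 2, eff, "/") * 1e6 + 0.5)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: q_(i) = min over j >= i of p_(j) * m / j on
#' ascending-sorted p values, mapped back to the input order.
#'
#' @param p_values numeric vector in \[0, 1\]; NAs propagate.
#' @return q values in input order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m > 0) {
    pv <- p[ok]
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    q[ok] <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  }
  q
}

#' Simple negative-binomial Wald differential-expression test
#'
#' Counts are normalized by median-of-ratios size factors; the log2 fold
#' change of (pseudo-count 0.5 shifted) group means is tested with a Wald
#' statistic whose standard error comes from an NB variance with a per-gene
#' method-of-moments dispersion (floored at 1e-8). Because raw per-gene
#' dispersions are unusable at minimal replication, they are shrunk toward
#' the across-gene median with prior weight `dispersion_moderation` (the
#' same reasoning behind DESeq2/edgeR/limma moderation); set it to 0 for the
#' raw per-gene estimate. Wald p-values are asymptotic: at n = 3 per group
#' the test is anti-conservative under the null (see the methods vignette);
#' calibration holds from about n = 10 per group. This is plumbing for
#' synthetic end-to-end runs, not a DESeq2 reimplementation; externally
#' produced DEG tables can be used interchangeably downstream.
#'
#' @param counts genes x samples count matrix.
#' @param groups two-level labels, one per sample (>= 2 samples per level).
#' @param a optional name of the level treated as group A (numerator);
#'   default is the first level encountered.
#' @param dispersion_moderation prior weight pulling per-gene dispersions
#'   toward the across-gene median (default 20; 0 disables moderation).
#' @return data.frame with `gene`, `base_mean`, `log2fc` (A over B),
#'   `p_value`, `q_value`.
#' @export
de_test <- function(counts, groups, a = NULL, dispersion_moderation = 20) {
  check_counts(counts)
  gi <- split_groups(groups, a)
  if (length(gi$a) < 2L || length(gi$b) < 2L)
    stopf("each group needs at least 2 samples")
  sf <- size_factors_median_of_ratios(counts)
  q <- sweep(counts, 2, sf, "/")
  qa <- q[, gi$a, drop = FALSE]; qb <- q[, gi$b, drop = FALSE]
  ma <- rowMeans(qa); mb <- rowMeans(qb)
  base_mean <- rowMeans(q)
  log2fc <- log2((ma + 0.5) / (mb + 0.5))
  # pooled method-of-moments dispersion on the normalized scale
  va <- apply(qa, 1, stats::var); vb <- apply(qb, 1, stats::var)
  na <- length(gi$a); nb <- length(gi$b)
  pooled_var <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  disp <- pmax((pooled_var - base_mean) / base_mean^2, 1e-8)
  disp[!is.finite(disp)] <- 1e-8
  if (dispersion_moderation > 0) {
    k <- na + nb - 2
    med <- stats::median(disp[base_mean > 5])
    if (is.finite(med))
      disp <- pmax((dispersion_moderation * med + k * disp) /
                     (dispersion_moderation + k), 1e-8)
  }
  var_ma <- (ma + disp * ma^2) / na
  var_mb <- (mb + disp * mb^2) / nb
  se <- sqrt(var_ma / (ma + 0.5)^2 + var_mb / (mb + 0.5)^2) / log(2)
  w <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * stats::pnorm(-abs(w))
  p[base_mean == 0] <- 1
  data.frame(gene = rownames(counts), base_mean = base_mean,
             log2fc = log2fc, p_value = p, q_value = bh_adjust(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call differentially expressed genes at fold-change and FDR thresholds
#'
#' @param records DEG table with `log2fc` and `q_value` (e.g. [de_test()]).
#' @param lfc_threshold minimum absolute log2 fold change (default 1, i.e.
#'   absolute fold change >= 2).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return `records` with logical `is_deg` and `direction` ("up", "down" or
#'   NA) columns added.
#' @export
call_degs <- function(records, lfc_threshold = 1, fdr_threshold = 0.05) {
  stopifnot(all(c("log2fc", "q_value") %in% names(records)))
  records$is_deg <- abs(records$log2fc) >= lfc_threshold &
    records$q_value < fdr_threshold
  records$is_deg[is.na(records$is_deg)] <- FALSE
  records$direction <- ifelse(records$is_deg,
                              ifelse(records$log2fc > 0, "up", "down"),
                              NA_character_)
  records
}
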