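# Beta-value handling, differential-methylation calling at the |delta-beta|
# >= 0.2 & p < 0.05 thresholds, aggregation to genomic feature classes
# (5 kb tiling, gene bodies, promoters, CpG islands) and hyper/hypo counting.
# The per-site test is a Welch t on M-values: the beta scale carries the
# effect size, the (near-Gaussian) M scale carries the test.

FEATURE_CLASSES <- c("tiling", "genes", "promoters", "cpg_islands")

check_beta <- function(beta) {
  if (!is.matrix(beta) || !is.numeric(beta))
    stopf("'beta' must be a numeric matrix")
  if (any(beta < 0 | beta > 1)) stopf("beta values must lie in [0, 1]")
  if (is.null(rownames(beta)) || anyDuplicated(rownames(beta)))
    stopf("beta matrix must have unique row (probe/region) names")
  invisible(beta)
}

#' M-values from beta values
#'
#' Betas are clipped to \[clip, 1 - clip\] and transformed by
#' M = log2(beta / (1 - beta)); the transform is monotone in beta.
#'
#' @param beta probes x samples matrix in \[0, 1\].
#' @param clip clipping bound in (0, 0.5) guarding against infinite M
#'   (default 0.01).
#' @return M-value matrix.
#' @export
m_values <- function(beta, clip = 0.01) {
  check_beta(beta)
  if (clip <= 0 || clip >= 0.5) stopf("'clip' must lie in (0, 0.5)")
  b <- pmin(pmax(beta, clip), 1 - clip)
  log2(b / (1 - b))
}

#' Differential methylation test
#'
#' Per unit (probe or region): delta-beta = mean beta(group A) - mean
#' beta(group B) on the beta scale; two-sided Welch p on M-values; a unit is
#' a DMS iff |delta-beta| >= `delta_threshold` and p < `p_threshold`.
#' Direction is hyper (A above B) or hypo. No multiple-testing adjustment is
#' applied at this stage by default (raw p < 0.05 is the operative rule);
#' set `adjust = TRUE` to test on BH q-values instead.
#'
#' @param beta probes/regions x samples beta matrix.
#' @param groups two-level labels per sample (>= 2 per level).
#' @param a optional level treated as group A.
#' @param delta_threshold minimum |delta-beta| (default 0.2).
#' @param p_threshold p cutoff (default 0.05).
#' @param adjust apply BH and threshold q instead of p (default FALSE).
#' @param clip clipping passed to [m_values()].
#' @return data.frame with `unit`, `delta_beta`, `p_value`, `q_value`,
#'   `direction`, `is_dms`.
#' @export
dms_test <- function(beta, groups, a = NULL, delta_threshold = 0.2,
                     p_threshold = 0.05, adjust = FALSE, clip = 0.01) {
  check_beta(beta)
  gi <- split_groups(groups, a)
  if (length(gi$a) < 2L || length(gi$b) < 2L)
    stopf("each group needs at least 2 samples")
  m <- m_values(beta, clip = clip)
  da <- rowMeans(beta[, gi$a, drop = FALSE]) -
    rowMeans(beta[, gi$b, drop = FALSE])
  p <- vapply(seq_len(nrow(m)), function(i) {
    x <- m[i, gi$a]; y <- m[i, gi$b]
    vx <- stats::var(x); vy <- stats::var(y)
    if (vx == 0 && vy == 0) return(if (mean(x) == mean(y)) 1 else 0)
    se2 <- vx / length(x) + vy / length(y)
    tt <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / length(x))^2 / (length(x) - 1) +
                     (vy / length(y))^2 / (length(y) - 1))
    2 * stats::pt(-abs(tt), df)
  }, numeric(1))
  q <- bh_adjust(p)
  crit <- if (adjust) q else p
  out <- data.frame(unit = rownames(beta), delta_beta = da, p_value = p,
                    q_value = q,
                    direction = ifelse(da >= 0, "hyper", "hypo"),
                    is_dms = abs(da) >= delta_threshold & crit < p_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

check_annotation <- function(ann) {
  need <- c("probe_id", "feature_class", "region_id")
  if (!all(need %in% names(ann)))
    stopf("annotation needs columns: %s", paste(need, collapse = ", "))
  bad <- setdiff(unique(ann$feature_class), FEATURE_CLASSES)
  if (length(bad))
    stopf("unknown feature class(es): %s", paste(bad, collapse = ", "))
  invisible(ann)
}

#' Aggregate probe betas to region level
#'
#' Region value per sample = unweighted mean of member-probe betas; regions
#' with fewer than `min_probes` members present in the matrix are dropped.
#'
#' @param beta probes x samples beta matrix.
#' @param ann long annotation data.frame with `probe_id`, `feature_class`,
#'   `region_id` (one row per membership).
#' @param feature_class one of "tiling", "genes", "promoters", "cpg_islands".
#' @param min_probes minimum member probes per region (default 1).
#' @return regions x samples beta matrix.
#' @export
aggregate_regions <- function(beta, ann, feature_class, min_probes = 1L) {
  check_beta(beta)
  check_annotation(ann)
  if (!feature_class %in% FEATURE_CLASSES)
    stopf("unknown feature class '%s'", feature_class)
  sub <- ann[ann$feature_class == feature_class &
               ann$probe_id %in% rownames(beta), , drop = FALSE]
  if (nrow(sub) == 0) stopf("no probe of class '%s' present", feature_class)
  members <- split(sub$probe_id, sub$region_id)
  members <- members[vapply(members, length, integer(1)) >= min_probes]
  out <- t(vapply(members, function(pr)
    colMeans(beta[pr, , drop = FALSE]), numeric(ncol(beta))))
  colnames(out) <- colnames(beta)
  out
}

#' Region-level log2 methylation quotient (mean.quot.log2)
#'
#' mean_quot_log2 = log2((mean beta_A + eps) / (mean beta_B + eps)); its sign
#' always agrees with the sign of delta-beta.
#'
#' @param region_beta regions x samples beta matrix.
#' @param groups two-level labels per sample.
#' @param a optional level treated as group A.
#' @param epsilon positive stabilizer (default 0.01).
#' @return data.frame with `region`, `mean_beta_a`, `mean_beta_b`,
#'   `delta_beta`, `mean_quot_log2`, `p_value` (Welch on M-values).
#' @export
region_log2_quotient <- function(region_beta, groups, a = NULL,
                                 epsilon = 0.01) {
  if (epsilon <= 0) stopf("'epsilon' must be positive")
  check_beta(region_beta)
  gi <- split_groups(groups, a)
  ma <- rowMeans(region_beta[, gi$a, drop = FALSE])
  mb <- rowMeans(region_beta[, gi$b, drop = FALSE])
  d <- dms_test(region_beta, groups, a = a)
  data.frame(region = rownames(region_beta), mean_beta_a = ma,
             mean_beta_b = mb, delta_beta = ma - mb,
             mean_quot_log2 = log2((ma + epsilon) / (mb + epsilon)),
             p_value = d$p_value, row.names = NULL, stringsAsFactors = FALSE)
}

#' Count hyper- and hypomethylated DMSs
#'
#' @param records output of [dms_test()].
#' @return named integer vector `c(n_hyper, n_hypo)` over `is_dms` records.
#' @export
count_dms_directions <- function(records) {
  d <- records[records$is_dms, , drop = FALSE]
  c(n_hyper = sum(d$direction == "hyper"),
    n_hypo = sum(d$direction == "hypo"))
}
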