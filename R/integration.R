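# Promoter methylation-expression integration: pairing the two layers per
# gene, Pearson correlation with the t-based two-sided p, five-category
# quadrant classification, and the inverse-correlation filter that defines
# "epigenetically controlled" genes (DEG and DMG in opposite directions with
# r <= -0.6 and p < 0.1).

#' Align expression and promoter-methylation matrices by gene
#'
#' Restricts both layers to genes present in both (after mapping promoter
#' region IDs to gene names), to samples present in both, and to complete
#' cases; sample order is made identical across layers.
#'
#' @param expr_matrix genes x samples expression matrix (normalized scale).
#' @param meth_matrix promoter regions (or genes) x samples methylation
#'   matrix.
#' @param gene_map optional data.frame with `region_id`, `gene` mapping
#'   methylation rows to gene names; when a gene maps to multiple regions the
#'   region with the most probes (`n_probes` column, optional) and then the
#'   lexicographically smallest region ID wins.
#' @return list with aligned matrices `expr` and `meth` (same genes, same
#'   samples, same order).
#' @export
align_layers <- function(expr_matrix, meth_matrix, gene_map = NULL) {
  if (!is.null(gene_map)) {
    stopifnot(all(c("region_id", "gene") %in% names(gene_map)))
    gm <- gene_map[gene_map$region_id %in% rownames(meth_matrix), ,
                   drop = FALSE]
    np <- gm$n_probes %||% rep(1L, nrow(gm))
    gm <- gm[order(gm$gene, -np, gm$region_id), , drop = FALSE]
    gm <- gm[!duplicated(gm$gene), , drop = FALSE]
    meth_matrix <- meth_matrix[gm$region_id, , drop = FALSE]
    rownames(meth_matrix) <- gm$gene
  }
  genes <- intersect(rownames(expr_matrix), rownames(meth_matrix))
  samples <- intersect(colnames(expr_matrix), colnames(meth_matrix))
  if (!length(genes) || !length(samples))
    stopf("no overlapping genes or samples between the two layers")
  e <- expr_matrix[genes, samples, drop = FALSE]
  m <- meth_matrix[genes, samples, drop = FALSE]
  complete <- stats::complete.cases(e) & stats::complete.cases(m)
  list(expr = e[complete, , drop = FALSE], meth = m[complete, , drop = FALSE])
}

#' Pearson correlation with a two-sided t-based p-value
#'
#' p comes from t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of
#' freedom (the cor.test route); exact |r| = 1 maps to p = 0. Zero variance
#' in either vector is an error (callers exclude and log such genes).
#'
#' @param meth_row,expr_row paired per-sample values (n >= 3).
#' @return list with `r` and `p_value`.
#' @export
gene_correlation <- function(meth_row, expr_row) {
  n <- length(meth_row)
  if (n != length(expr_row)) stopf("paired vectors of unequal length")
  if (n < 3L) stopf("correlation needs at least 3 paired values")
  if (stats::sd(meth_row) == 0 || stats::sd(expr_row) == 0)
    stopf("zero variance; correlation undefined")
  r <- stats::cor(meth_row, expr_row)
  if (abs(r) >= 1 - 1e-15) return(list(r = sign(r), p_value = 0))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * stats::pt(-abs(tt), n - 2))
}

#' Five-category quadrant classification
#'
#' Low-effect iff |expr_log2fc| < `expr_cut` or |meth_log2quot| < `meth_cut`;
#' otherwise Hyper-Up / Hyper-Down / Hypo-Up / Hypo-Down by the two signs
#' (hyper = positive methylation change in A vs B).
#'
#' @param expr_log2fc expression log2 fold change(s).
#' @param meth_log2quot methylation mean.quot.log2 value(s).
#' @param expr_cut expression cutoff (default 1).
#' @param meth_cut methylation cutoff (default 0.1).
#' @return character vector of quadrant labels.
#' @export
quadrant_classify <- function(expr_log2fc, meth_log2quot, expr_cut = 1,
                              meth_cut = 0.1) {
  stopifnot(length(expr_log2fc) == length(meth_log2quot))
  if (any(!is.finite(expr_log2fc)) || any(!is.finite(meth_log2quot)))
    stopf("effect sizes must be finite")
  low <- abs(expr_log2fc) < expr_cut | abs(meth_log2quot) < meth_cut
  meth_dir <- ifelse(meth_log2quot >= 0, "Hyper", "Hypo")
  expr_dir <- ifelse(expr_log2fc >= 0, "Up", "Down")
  ifelse(low, "Low-effect", paste(meth_dir, expr_dir, sep = "-"))
}

#' Build the per-gene integration table
#'
#' Joins the aligned layers with DEG and promoter-DMG calls, computes the
#' per-gene Pearson correlation across the paired samples (by default the
#' treated-arm samples only), the quadrant class, and the epigenetic-control
#' filter.
#'
#' @param aligned output of [align_layers()].
#' @param deg_table DEG table with `gene`, `log2fc`, `is_deg`, `direction`.
#' @param dmg_table promoter methylation table with `region` (gene names
#'   after mapping), `mean_quot_log2`, `delta_beta`, `p_value`, and
#'   optionally `is_dms`/`direction` (recomputed from thresholds otherwise).
#' @param cor_samples optional character vector of sample IDs over which to
#'   correlate (default: all columns of the aligned matrices).
#' @param delta_threshold,p_threshold promoter DMG thresholds (defaults 0.2
#'   and 0.05).
#' @param expr_cut,meth_cut quadrant cutoffs (defaults 1 and 0.1).
#' @param r_cut,p_cut inverse-correlation filter thresholds (defaults -0.6
#'   and 0.1).
#' @return data.frame with one row per aligned gene: effect sizes, r, p,
#'   quadrant, DEG/DMG status, `passes_epigenetic_filter` and `filter_class`
#'   ("activated", "repressed" or "none").
#' @export
integrate_omics <- function(aligned, deg_table, dmg_table,
                            cor_samples = NULL,
                            delta_threshold = 0.2, p_threshold = 0.05,
                            expr_cut = 1, meth_cut = 0.1,
                            r_cut = -0.6, p_cut = 0.1) {
  genes <- rownames(aligned$expr)
  cols <- cor_samples %||% colnames(aligned$expr)
  if (!all(cols %in% colnames(aligned$expr)))
    stopf("cor_samples not all present in the aligned matrices")
  di <- match(genes, deg_table$gene)
  mi <- match(genes, dmg_table$region)
  if (any(is.na(di)) || any(is.na(mi)))
    stopf("aligned genes missing from the DEG or DMG table")
  expr_l2fc <- deg_table$log2fc[di]
  meth_l2q <- dmg_table$mean_quot_log2[mi]
  is_deg <- (deg_table$is_deg %||% stopf("deg_table lacks is_deg"))[di]
  deg_dir <- deg_table$direction[di]
  is_dmg <- abs(dmg_table$delta_beta[mi]) >= delta_threshold &
    dmg_table$p_value[mi] < p_threshold
  dmg_dir <- ifelse(dmg_table$delta_beta[mi] >= 0, "hyper", "hypo")
  cor_res <- lapply(genes, function(g) {
    mr <- aligned$meth[g, cols]; er <- aligned$expr[g, cols]
    if (stats::sd(mr) == 0 || stats::sd(er) == 0)
      return(list(r = NA_real_, p_value = NA_real_))
    gene_correlation(mr, er)
  })
  r <- vapply(cor_res, `[[`, numeric(1), "r")
  rp <- vapply(cor_res, `[[`, numeric(1), "p_value")
  out <- data.frame(
    gene = genes, expr_log2fc = expr_l2fc, meth_log2quot = meth_l2q,
    pearson_r = r, cor_p_value = rp,
    quadrant = quadrant_classify(expr_l2fc, meth_l2q, expr_cut, meth_cut),
    is_deg = is_deg, deg_direction = deg_dir,
    is_dmg = is_dmg, dmg_direction = dmg_dir,
    row.names = NULL, stringsAsFactors = FALSE)
  epigenetic_control_filter(out, r_cut = r_cut, p_cut = p_cut)
}

#' Inverse-correlation epigenetic-control filter
#'
#' A gene passes iff it is a DEG and a promoter DMG with opposite directions
#' (hypomethylated-upregulated or hypermethylated-downregulated) and its
#' methylation-expression Pearson correlation satisfies r <= `r_cut` with
#' p < `p_cut`. Passing genes are classed "activated" (hypo-up) or
#' "repressed" (hyper-down).
#'
#' @param records integration table carrying `is_deg`, `deg_direction`,
#'   `is_dmg`, `dmg_direction`, `pearson_r`, `cor_p_value`.
#' @param r_cut correlation threshold (default -0.6).
#' @param p_cut correlation p threshold (default 0.1).
#' @return `records` with `passes_epigenetic_filter` and `filter_class`
#'   columns.
#' @export
epigenetic_control_filter <- function(records, r_cut = -0.6, p_cut = 0.1) {
  need <- c("is_deg", "deg_direction", "is_dmg", "dmg_direction",
            "pearson_r", "cor_p_value")
  stopifnot(all(need %in% names(records)))
  hypo_up <- records$dmg_direction == "hypo" & records$deg_direction %in% "up"
  hyper_down <- records$dmg_direction == "hyper" &
    records$deg_direction %in% "down"
  discordant <- hypo_up | hyper_down
  pass <- records$is_deg & records$is_dmg & discordant &
    !is.na(records$pearson_r) & records$pearson_r <= r_cut &
    !is.na(records$cor_p_value) & records$cor_p_value < p_cut
  records$passes_epigenetic_filter <- pass
  records$filter_class <- ifelse(pass & hypo_up, "activated",
                                 ifelse(pass & hyper_down, "repressed",
                                        "none"))
  records
}

#' DMG/DEG overlap counts (Venn)
#'
#' @param dmg_genes,deg_genes character vectors of gene names.
#' @return named integer vector `c(n_dmg_only, n_deg_only, n_both)`.
#' @export
dmg_deg_venn <- function(dmg_genes, deg_genes) {
  dmg <- unique(dmg_genes); deg <- unique(deg_genes)
  both <- intersect(dmg, deg)
  c(n_dmg_only = length(setdiff(dmg, deg)),
    n_deg_only = length(setdiff(deg, dmg)),
    n_both = length(both))
}
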