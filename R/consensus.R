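# Ensemble somatic-variant consensus and post-calling filters.
#
# The pipeline mirrors the ensemble strategy used with Mutect2 / VarScan2 /
# Strelka2 / MuSe call sets: keep variants supported by at least two callers,
# then flag known-polymorphism (blacklist) sites, matched-germline variants,
# mutations shared across samples, and clustered mutations (> 3 within a
# 10 bp window). Filters flag rather than delete so the audit trail is
# preserved; `consensus_retained()` gives the analysis view.

#' Classify variants from allele lengths
#'
#' @param ref,alt character vectors of REF/ALT alleles (ACGT, VCF-style
#'   anchored indels).
#' @return character vector over SNV, DBS, INS, DEL, MNV-other.
#' @export
classify_variants <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  if (any(ref == alt)) stopf("ref and alt alleles must differ")
  nr <- nchar(ref); na <- nchar(alt)
  out <- rep("MNV-other", length(ref))
  out[nr == 1L & na == 1L] <- "SNV"
  is_dbs <- nr == 2L & na == 2L &
    substr(ref, 1, 1) != substr(alt, 1, 1) &
    substr(ref, 2, 2) != substr(alt, 2, 2)
  out[is_dbs] <- "DBS"
  anchored_ins <- nr < na & substr(alt, 1, nr) == ref
  anchored_del <- nr > na & substr(ref, 1, na) == alt
  out[anchored_ins] <- "INS"
  out[anchored_del] <- "DEL"
  out
}

variant_key <- function(v) paste(v$contig, v$pos, v$ref, v$alt, sep = ":")

empty_consensus <- function() {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character(), var_class = character(),
             sample_id = character(), n_callers = integer(),
             supporting_callers = character(),
             flag_blacklist = logical(), flag_germline = logical(),
             flag_shared = logical(), flag_clustered = logical(),
             stringsAsFactors = FALSE)
}

#' Build the caller consensus for one or more samples
#'
#' Variant identity is the exact tuple (contig, pos, ref, alt) per sample.
#' A variant is retained when called by at least `min_callers` callers;
#' dropped variants do not enter the consensus table at all (they never were
#' candidates), whereas downstream filters only flag.
#'
#' @param callsets either a named list `caller -> data.frame` (single sample,
#'   in which case `sample_id` is taken from the tables or defaults to
#'   "sample1"), or a named list `sample -> named list caller -> data.frame`.
#'   Each table needs columns `contig`, `pos`, `ref`, `alt` (and optionally
#'   `var_class`).
#' @param min_callers minimum supporting callers (default 2, the two-of-four
#'   ensemble rule).
#' @return consensus data.frame with per-variant provenance columns
#'   `n_callers`, `supporting_callers` (comma-separated) and the four filter
#'   flag columns, all initialized to FALSE.
#' @export
consensus_calls <- function(callsets, min_callers = 2L) {
  assert_count(min_callers, "min_callers", min = 1)
  if (!is.list(callsets) || is.null(names(callsets)))
    stopf("'callsets' must be a named list")
  nested <- all(vapply(callsets, function(x)
    is.list(x) && !is.data.frame(x), logical(1)))
  if (!nested) callsets <- list(sample1 = callsets)
  per_sample <- lapply(names(callsets), function(sid) {
    sets <- callsets[[sid]]
    rows <- lapply(names(sets), function(cid) {
      df <- sets[[cid]]
      if (nrow(df) == 0) return(NULL)
      data.frame(contig = df$contig, pos = as.integer(df$pos), ref = df$ref,
                 alt = df$alt,
                 var_class = df$var_class %||% classify_variants(df$ref, df$alt),
                 caller_id = cid, stringsAsFactors = FALSE)
    })
    all_calls <- do.call(rbind, rows)
    if (is.null(all_calls) || nrow(all_calls) == 0) return(NULL)
    key <- variant_key(all_calls)
    supp <- lapply(split(all_calls$caller_id, key), unique)
    first <- all_calls[!duplicated(key), , drop = FALSE]
    kf <- variant_key(first)
    n_sup <- vapply(supp[kf], length, integer(1))
    keep <- n_sup >= min_callers
    if (!any(keep)) return(NULL)
    out <- first[keep, c("contig", "pos", "ref", "alt", "var_class")]
    out$sample_id <- sid
    out$n_callers <- n_sup[keep]
    out$supporting_callers <- vapply(supp[kf][keep], function(s)
      paste(sort(s), collapse = ","), character(1))
    out
  })
  out <- do.call(rbind, per_sample)
  if (is.null(out)) return(empty_consensus())
  out$flag_blacklist <- FALSE
  out$flag_germline <- FALSE
  out$flag_shared <- FALSE
  out$flag_clustered <- FALSE
  out <- out[order(out$sample_id, out$contig, out$pos, out$ref, out$alt), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag consensus variants found in a blacklist
#'
#' Emulates dbSNP-style removal of known germline polymorphisms: any
#' allele-exact (contig, pos, ref, alt) match is flagged `blacklist`.
#'
#' @param consensus consensus table from [consensus_calls()].
#' @param blacklist data.frame with `contig`, `pos`, `ref`, `alt` (may be
#'   empty, in which case the input is returned unchanged).
#' @return consensus table with updated `flag_blacklist`.
#' @export
filter_blacklist <- function(consensus, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0) return(consensus)
  consensus$flag_blacklist <- consensus$flag_blacklist |
    variant_key(consensus) %in% variant_key(blacklist)
  consensus
}

#' Flag variants present in the matched germline reference
#'
#' Each analysis sample maps to one germline individual (e.g. the same
#' mouse's spleen WGS); variants exactly matching that individual's germline
#' call set are flagged `germline`.
#'
#' @param consensus consensus table.
#' @param germline named list `individual -> data.frame(contig, pos, ref,
#'   alt)`.
#' @param sample_to_individual named character vector mapping every
#'   `sample_id` in the consensus to an individual in `germline`.
#' @return consensus table with updated `flag_germline`.
#' @export
subtract_germline <- function(consensus, germline, sample_to_individual) {
  if (nrow(consensus) == 0) return(consensus)
  samples <- unique(consensus$sample_id)
  missing <- setdiff(samples, names(sample_to_individual))
  if (length(missing))
    stopf("no germline mapping for sample(s): %s",
          paste(missing, collapse = ", "))
  for (sid in samples) {
    ind <- sample_to_individual[[sid]]
    gcalls <- germline[[ind]]
    if (is.null(gcalls)) stopf("no germline call set for individual '%s'", ind)
    idx <- consensus$sample_id == sid
    consensus$flag_germline[idx] <- consensus$flag_germline[idx] |
      variant_key(consensus[idx, , drop = FALSE]) %in% variant_key(gcalls)
  }
  consensus
}

#' Flag mutations shared across multiple samples
#'
#' Any (contig, pos, ref, alt) identity observed in at least `min_samples`
#' distinct samples is flagged `shared` in every carrier, the guard against
#' residual germline contamination.
#'
#' @param consensus consensus table covering all samples.
#' @param min_samples sharing threshold (default 2).
#' @return consensus table with updated `flag_shared`.
#' @export
filter_shared <- function(consensus, min_samples = 2L) {
  assert_count(min_samples, "min_samples", min = 2)
  if (length(unique(consensus$sample_id)) < 2L) {
    warnf("filter_shared: fewer than 2 samples, no-op")
    return(consensus)
  }
  key <- variant_key(consensus)
  carriers <- vapply(split(consensus$sample_id, key),
                     function(s) length(unique(s)), integer(1))
  consensus$flag_shared <- consensus$flag_shared |
    carriers[key] >= min_samples
  consensus
}

#' Flag clustered mutations
#'
#' A variant is flagged `clustered` when it lies in any window of
#' `window_bp` consecutive bases (inclusive span) that contains more than
#' `max_in_window` of the same sample's variants on the same contig — the
#' "> 3 mutations within a 10 bp window" exclusion. Applied per sample.
#'
#' @param consensus consensus table.
#' @param window_bp window width in bases (default 10).
#' @param max_in_window maximum tolerated count per window; strictly more
#'   triggers the flag (default 3).
#' @return consensus table with updated `flag_clustered`.
#' @export
filter_clustered <- function(consensus, window_bp = 10L, max_in_window = 3L) {
  assert_count(window_bp, "window_bp", min = 1)
  assert_count(max_in_window, "max_in_window", min = 1)
  if (nrow(consensus) == 0) return(consensus)
  grp <- paste(consensus$sample_id, consensus$contig, sep = "\r")
  for (g in unique(grp)) {
    idx <- which(grp == g)
    pos <- consensus$pos[idx]
    ord <- order(pos)
    p <- pos[ord]
    flag <- logical(length(p))
    # every maximal offending window can be anchored at some variant position
    for (i in seq_along(p)) {
      inw <- which(p >= p[i] & p <= p[i] + window_bp - 1L)
      if (length(inw) > max_in_window) flag[inw] <- TRUE
    }
    consensus$flag_clustered[idx[ord]] <- consensus$flag_clustered[idx[ord]] |
      flag
  }
  consensus
}

#' Analysis view of a consensus table
#'
#' @param consensus consensus table after any subset of the filters.
#' @return rows with no filter flag set.
#' @export
consensus_retained <- function(consensus) {
  keep <- !(consensus$flag_blacklist | consensus$flag_germline |
              consensus$flag_shared | consensus$flag_clustered)
  consensus[keep, , drop = FALSE]
}

#' Per-stage attrition counts for a consensus table
#' @param consensus consensus table.
#' @return named integer vector: total, flagged per filter, retained.
#' @export
consensus_summary <- function(consensus) {
  c(total = nrow(consensus),
    blacklist = sum(consensus$flag_blacklist),
    germline = sum(consensus$flag_germline),
    shared = sum(consensus$flag_shared),
    clustered = sum(consensus$flag_clustered),
    retained = nrow(consensus_retained(consensus)))
}
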