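# Mutational-spectrum channel classification and profile comparison.
#
# Channel labels and ordering follow the COSMIC v3 catalog conventions:
# SBS96 = 6 pyrimidine-centred substitution types x 16 trinucleotide
# contexts; DBS78 = 78 canonical doublet substitutions; ID83 = 83 indel
# categories by type, length, homopolymer/repeat context and microhomology.

SBS_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

# Canonical DBS78 reference doublets and their admissible alt doublets.
DBS78_ALTS <- list(
  AC = c("CA", "CG", "CT", "GA", "GG", "GT", "TA", "TG", "TT"),
  AT = c("CA", "CC", "CG", "GA", "GC", "TA"),
  CC = c("AA", "AG", "AT", "GA", "GG", "GT", "TA", "TG", "TT"),
  CG = c("AT", "GC", "GT", "TA", "TC", "TT"),
  CT = c("AA", "AC", "AG", "GA", "GC", "GG", "TA", "TC", "TG"),
  GC = c("AA", "AG", "AT", "CA", "CG", "TA"),
  TA = c("AT", "CG", "CT", "GC", "GG", "GT"),
  TC = c("AA", "AG", "AT", "CA", "CG", "CT", "GA", "GG", "GT"),
  TG = c("AA", "AC", "AT", "CA", "CC", "CT", "GA", "GC", "GT"),
  TT = c("AA", "AC", "AG", "CA", "CC", "CG", "GA", "GC", "GG"))

#' SBS96 channel catalog
#' @return character vector of the 96 channel labels in canonical order.
#' @export
sbs96_channels <- function() {
  out <- character(0)
  for (ty in SBS_TYPES)
    for (b5 in BASES)
      for (b3 in BASES)
        out <- c(out, paste0(b5, "[", ty, "]", b3))
  out
}

#' DBS78 channel catalog
#' @return character vector of the 78 channel labels in canonical order.
#' @export
dbs78_channels <- function() {
  unlist(lapply(names(DBS78_ALTS), function(r)
    paste0(r, ">", DBS78_ALTS[[r]])), use.names = FALSE)
}

#' ID83 channel catalog
#' @return character vector of the 83 channel labels in canonical order.
#' @export
id83_channels <- function() {
  lab <- function(len, ty, ctx, n) sprintf("%s:%s:%s:%s", len, ty, ctx, n)
  out <- c(
    lab(1, "Del", "C", 0:5), lab(1, "Del", "T", 0:5),
    lab(1, "Ins", "C", 0:5), lab(1, "Ins", "T", 0:5))
  for (len in 2:5) out <- c(out, lab(len, "Del", "R", 0:5))
  for (len in 2:5) out <- c(out, lab(len, "Ins", "R", 0:5))
  out <- c(out,
           lab(2, "Del", "M", 1),
           lab(3, "Del", "M", 1:2),
           lab(4, "Del", "M", 1:3),
           lab(5, "Del", "M", 1:5))
  out
}

schema_channels <- function(schema) {
  switch(schema,
         SBS96 = sbs96_channels(),
         DBS78 = dbs78_channels(),
         ID83 = id83_channels(),
         stopf("unknown schema '%s'", schema))
}

schema_class <- function(schema) {
  switch(schema, SBS96 = "SNV", DBS78 = "DBS", ID83 = c("INS", "DEL"))
}

genome_slice <- function(genome, contig, start, end) {
  seqs <- genome[contig]
  substr(seqs, start, end)
}

#' SBS96 channel of single-base substitutions
#'
#' Pyrimidine-centred labeling: when the reference base is a purine the
#' variant and its immediate context are reverse-complemented, so a mutation
#' and its reverse complement map to the same channel.
#'
#' @param variants data.frame with `contig`, `pos`, `ref`, `alt` (SNVs).
#' @param genome named character vector of contig sequences.
#' @return character vector of channel labels; NA where the context is
#'   truncated at a contig edge.
#' @export
sbs96_channel <- function(variants, genome) {
  if (any(classify_variants(variants$ref, variants$alt) != "SNV"))
    stopf("sbs96_channel expects SNVs only")
  n <- nrow(variants)
  clen <- nchar(genome)[match(variants$contig, names(genome))]
  if (any(is.na(clen))) stopf("variant contig absent from genome")
  at_edge <- variants$pos <= 1L | variants$pos >= clen
  tri <- rep(NA_character_, n)
  ok <- !at_edge
  tri[ok] <- substr(genome[variants$contig[ok]],
                    variants$pos[ok] - 1L, variants$pos[ok] + 1L)
  mid <- substr(tri, 2, 2)
  bad <- ok & mid != variants$ref
  if (any(bad))
    stopf("reference allele disagrees with genome at %s:%d",
          variants$contig[which(bad)[1]], variants$pos[which(bad)[1]])
  out <- rep(NA_character_, n)
  if (any(ok)) {
    ref <- variants$ref[ok]; alt <- variants$alt[ok]; ctx <- tri[ok]
    flip <- ref %in% c("A", "G")
    ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
    alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
    ctx[flip] <- revcomp(ctx[flip])
    out[ok] <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]",
                      substr(ctx, 3, 3))
  }
  out
}

#' DBS78 channel of doublet-base substitutions
#'
#' Reference doublets are mapped to the canonical ten by reverse-complementing
#' both alleles when needed; for palindromic reference doublets the alt
#' orientation is resolved by the catalog's fixed admissible-alt lists.
#'
#' @param variants data.frame with `contig`, `pos`, `ref`, `alt` (DBS rows).
#' @param genome named character vector of contig sequences (used to verify
#'   the reference alleles).
#' @return character vector of channel labels.
#' @export
dbs78_channel <- function(variants, genome) {
  if (any(classify_variants(variants$ref, variants$alt) != "DBS"))
    stopf("dbs78_channel expects DBS variants only")
  gref <- substr(genome[variants$contig], variants$pos, variants$pos + 1L)
  bad <- gref != variants$ref
  if (any(bad))
    stopf("reference doublet disagrees with genome at %s:%d",
          variants$contig[which(bad)[1]], variants$pos[which(bad)[1]])
  mapply(function(ref, alt) {
    lab <- paste0(ref, ">", alt)
    if (ref %in% names(DBS78_ALTS) && alt %in% DBS78_ALTS[[ref]]) return(lab)
    rr <- revcomp(ref); ra <- revcomp(alt)
    if (rr %in% names(DBS78_ALTS) && ra %in% DBS78_ALTS[[rr]])
      return(paste0(rr, ">", ra))
    stopf("doublet %s>%s has no DBS78 channel", ref, alt)
  }, variants$ref, variants$alt, USE.NAMES = FALSE)
}

# Longest run of `base` in `seq_str` scanning from position `from` in
# direction `dir` (+1 or -1).
run_length <- function(genome, contig, from, base, dir) {
  clen <- nchar(genome[[contig]])
  k <- 0L
  p <- from
  while (p >= 1L && p <= clen &&
         substr(genome[[contig]], p, p) == base) {
    k <- k + 1L
    p <- p + dir
  }
  k
}

# Number of tandem copies of `unit` in the reference starting at `from`,
# scanning 3'.
tandem_copies <- function(genome, contig, from, unit) {
  len <- nchar(unit)
  clen <- nchar(genome[[contig]])
  k <- 0L
  p <- from
  while (p + len - 1L <= clen &&
         substr(genome[[contig]], p, p + len - 1L) == unit) {
    k <- k + 1L
    p <- p + len
  }
  k
}

# Longest prefix of `unit` matching the reference starting at `from` (3'
# microhomology), or longest suffix matching backwards ending at `from` (5').
mh_length <- function(genome, contig, from, unit, side) {
  len <- nchar(unit)
  clen <- nchar(genome[[contig]])
  k <- 0L
  for (i in seq_len(len)) {
    if (side == "3") {
      p <- from + i - 1L
      if (p > clen || substr(genome[[contig]], p, p) != substr(unit, i, i))
        break
    } else {
      p <- from - i + 1L
      j <- len - i + 1L
      if (p < 1L || substr(genome[[contig]], p, p) != substr(unit, j, j))
        break
    }
    k <- k + 1L
  }
  k
}

id83_one <- function(contig, pos, ref, alt, genome) {
  cls <- classify_variants(ref, alt)
  if (!cls %in% c("INS", "DEL"))
    stopf("id83_channel expects anchored insertions/deletions")
  gref <- substr(genome[[contig]], pos, pos + nchar(ref) - 1L)
  if (gref != ref)
    stopf("indel REF disagrees with genome at %s:%d", contig, pos)
  if (cls == "DEL") {
    unit <- substr(ref, nchar(alt) + 1L, nchar(ref))
    site <- pos + nchar(alt)            # first deleted base
    len <- nchar(unit)
    if (len == 1L) {
      # homopolymer length: the run containing the deleted base
      run <- run_length(genome, contig, site, unit, +1L) +
        run_length(genome, contig, site - 1L, unit, -1L)
      base <- if (unit %in% c("A", "G")) chartr("ACGT", "TGCA", unit) else unit
      return(sprintf("1:Del:%s:%d", base, min(run - 1L, 5L)))
    }
    lenb <- min(len, 5L)
    k <- tandem_copies(genome, contig, site, unit)  # >= 1 (the deleted copy)
    # a full-length 5' copy also makes it a tandem repeat
    mh5 <- mh_length(genome, contig, site - 1L, unit, "5")
    if (k >= 2L || mh5 == len)
      return(sprintf("%d:Del:R:%d", lenb, min(max(k, 2L) - 1L, 5L)))
    mh3 <- mh_length(genome, contig, site + len, unit, "3")
    mh <- max(mh3, mh5)
    if (mh >= 1L)
      return(sprintf("%d:Del:M:%d", lenb, min(mh, 5L)))
    sprintf("%d:Del:R:0", lenb)
  } else {
    unit <- substr(alt, nchar(ref) + 1L, nchar(alt))
    len <- nchar(unit)
    site <- pos + nchar(ref)            # first reference base after anchor
    if (len == 1L) {
      run <- run_length(genome, contig, site, unit, +1L) +
        run_length(genome, contig, site - 1L, unit, -1L)
      base <- if (unit %in% c("A", "G")) chartr("ACGT", "TGCA", unit) else unit
      return(sprintf("1:Ins:%s:%d", base, min(run, 5L)))
    }
    k <- tandem_copies(genome, contig, site, unit)
    sprintf("%d:Ins:R:%d", min(len, 5L), min(k, 5L))
  }
}

#' ID83 channel of small insertions and deletions
#'
#' Categories follow the COSMIC ID83 grid: indel type, length bin (1-5+),
#' pyrimidine identity for 1-bp events, homopolymer/tandem-repeat copy count
#' (counted 3' of the left-anchored event), and microhomology length for
#' non-repeat deletions of length >= 2 (evaluated on both flanks, maximum
#' taken).
#'
#' @param variants data.frame with `contig`, `pos`, `ref`, `alt`
#'   (VCF-anchored indels).
#' @param genome named character vector of contig sequences.
#' @return character vector of channel labels.
#' @export
id83_channel <- function(variants, genome) {
  mapply(id83_one, variants$contig, variants$pos, variants$ref, variants$alt,
         MoreArgs = list(genome = genome), USE.NAMES = FALSE)
}

#' Construct a spectrum profile from channel counts
#'
#' @param counts named numeric vector of nonnegative channel counts; names
#'   must be a subset of the schema's catalog. Missing channels are zero.
#' @param schema one of "SBS96", "DBS78", "ID83".
#' @param n_unclassified count of variants that could not be classified
#'   (e.g. contig-edge SNVs).
#' @return a `spectrum_profile`: named numeric vector over the full catalog
#'   with attributes `schema`, `n_total`, `n_unclassified`.
#' @export
spectrum_profile <- function(counts, schema, n_unclassified = 0L) {
  chans <- schema_channels(schema)
  if (any(counts < 0)) stopf("channel counts must be nonnegative")
  unknown <- setdiff(names(counts), chans)
  if (length(unknown))
    stopf("labels outside the %s catalog: %s", schema,
          paste(utils::head(unknown, 3), collapse = ", "))
  v <- stats::setNames(numeric(length(chans)), chans)
  v[names(counts)] <- counts
  structure(v, schema = schema, n_total = sum(v),
            n_unclassified = n_unclassified, class = "spectrum_profile")
}

#' @export
print.spectrum_profile <- function(x, ...) {
  cat(sprintf("<spectrum_profile %s: %d channels, %g mutations, %d unclassified>\n",
              attr(x, "schema"), length(x), attr(x, "n_total"),
              attr(x, "n_unclassified")))
  nz <- x[x > 0]
  if (length(nz)) print(utils::head(sort(nz, decreasing = TRUE), 10))
  invisible(x)
}

#' Build a spectrum profile from variants
#'
#' Variants of the wrong class for the schema are rejected; variants that
#' cannot be classified (contig-edge context) are excluded from the channel
#' counts and reported in the `n_unclassified` attribute.
#'
#' @param variants variant data.frame (`contig`, `pos`, `ref`, `alt`, and
#'   optionally `var_class`).
#' @param genome named character vector of contig sequences.
#' @param schema one of "SBS96", "DBS78", "ID83".
#' @return a `spectrum_profile`.
#' @export
build_profile <- function(variants, genome, schema) {
  cls <- variants$var_class %||% classify_variants(variants$ref, variants$alt)
  keep <- cls %in% schema_class(schema)
  v <- variants[keep, , drop = FALSE]
  if (nrow(v) == 0) return(spectrum_profile(numeric(0), schema))
  labels <- switch(schema,
                   SBS96 = sbs96_channel(v, genome),
                   DBS78 = dbs78_channel(v, genome),
                   ID83 = id83_channel(v, genome))
  n_unc <- sum(is.na(labels))
  tab <- table(labels[!is.na(labels)])
  spectrum_profile(stats::setNames(as.numeric(tab), names(tab)), schema,
                   n_unclassified = n_unc)
}

#' Cosine similarity of two spectrum profiles
#'
#' @param p,q `spectrum_profile`s of the same schema (or plain nonnegative
#'   numeric vectors of equal length).
#' @return similarity in \[0, 1\]; invariant to rescaling of either profile.
#' @export
cosine_similarity <- function(p, q) {
  if (inherits(p, "spectrum_profile") && inherits(q, "spectrum_profile") &&
      !identical(attr(p, "schema"), attr(q, "schema")))
    stopf("profiles have different schemas")
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q)) stopf("profiles have different lengths")
  np <- sqrt(sum(p^2)); nq <- sqrt(sum(q^2))
  if (np == 0 || nq == 0) stopf("cosine similarity undefined for zero profile")
  sum(p * q) / (np * nq)
}

#' Average a list of spectrum profiles
#'
#' Each profile is normalized to sum 1 and the per-channel arithmetic mean is
#' returned, the operation behind "average profile of n samples" panels.
#'
#' @param profiles non-empty list of `spectrum_profile`s of one schema.
#' @return normalized `spectrum_profile` (weights summing to 1).
#' @export
average_profiles <- function(profiles) {
  if (!length(profiles)) stopf("need at least one profile to average")
  schema <- attr(profiles[[1]], "schema")
  mats <- vapply(profiles, function(p) {
    if (!identical(attr(p, "schema"), schema))
      stopf("profiles have mixed schemas")
    s <- sum(p)
    if (s == 0) stopf("cannot normalize an all-zero profile")
    as.numeric(p) / s
  }, numeric(length(profiles[[1]])))
  avg <- rowMeans(mats)
  spectrum_profile(stats::setNames(avg, schema_channels(schema)), schema)
}

#' Mutational burden per megabase
#'
#' @param n_mutations mutation count.
#' @param callable_bases interrogated bases (denominator; must be positive).
#' @return list with `n_mutations`, `callable_bases`, `burden_per_mb`.
#' @export
mutational_burden <- function(n_mutations, callable_bases) {
  assert_count(n_mutations, "n_mutations")
  if (!is.numeric(callable_bases) || callable_bases <= 0)
    stopf("'callable_bases' must be positive")
  list(n_mutations = as.integer(n_mutations),
       callable_bases = callable_bases,
       burden_per_mb = n_mutations * 1e6 / callable_bases)
}

#' Per-sample burden table with a two-group Welch comparison
#'
#' @param consensus retained consensus table (one row per mutation).
#' @param callable_bases denominator in bases, shared across samples.
#' @param groups optional named group label per sample; when given, a
#'   two-sided Welch t-test on per-sample burdens is attached.
#' @return list with `table` (sample, n_mutations, burden_per_mb, group) and
#'   optionally `test` (t, df, p_value).
#' @export
burden_table <- function(consensus, callable_bases, groups = NULL) {
  counts <- table(consensus$sample_id)
  tab <- data.frame(sample_id = names(counts),
                    n_mutations = as.integer(counts),
                    burden_per_mb = as.numeric(counts) * 1e6 / callable_bases,
                    stringsAsFactors = FALSE)
  out <- list(table = tab)
  if (!is.null(groups)) {
    tab$group <- groups[tab$sample_id]
    out$table <- tab
    out$test <- compare_groups_welch(tab$burden_per_mb, tab$group)
  }
  out
}
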