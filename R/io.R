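# File-format interfaces. Standard formats go through Bioconductor readers
# (Biostrings for FASTA, VariantAnnotation for VCF); simple tabular formats
# use base TSV I/O so outputs stay greppable.

#' Write a genome to FASTA
#'
#' @param genome named character vector of contig sequences (uppercase ACGT).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  dna <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dna, filepath = path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA path.
#' @return named character vector of uppercase contig sequences.
#' @export
read_genome_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(dna))
  # FASTA headers may carry descriptions; contig name is the first word
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Read variant calls from a VCF file
#'
#' Parses a VCF v4.x file into the package's variant-call table. Multi-allelic
#' records are split into one row per ALT allele and each row is assigned a
#' variant class (SNV, DBS, INS, DEL or MNV-other) from its allele lengths.
#'
#' @param path VCF path.
#' @param sample_id,caller_id optional provenance labels attached to every row.
#' @return data.frame with columns `contig`, `pos`, `ref`, `alt`, `var_class`
#'   and, when given, `sample_id` and `caller_id`.
#' @export
read_vcf <- function(path, sample_id = NULL, caller_id = NULL) {
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  v <- tryCatch(
    VariantAnnotation::readVcf(path),
    error = function(e) stopf("failed to parse VCF '%s': %s",
                              path, conditionMessage(e)))
  v <- VariantAnnotation::expand(v)  # one row per ALT allele
  gr <- SummarizedExperiment::rowRanges(v)
  n <- length(gr)
  out <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    pos = BiocGenerics::start(gr),
    ref = as.character(VariantAnnotation::ref(v)),
    alt = as.character(VariantAnnotation::alt(v)),
    stringsAsFactors = FALSE)
  if (n > 0 && any(!grepl("^[ACGT]+$", out$ref) | !grepl("^[ACGT]+$", out$alt)))
    stopf("VCF '%s' contains non-ACGT alleles", path)
  out$var_class <- classify_variants(out$ref, out$alt)
  if (!is.null(sample_id)) out$sample_id <- rep(sample_id, n)
  if (!is.null(caller_id)) out$caller_id <- rep(caller_id, n)
  out
}

#' Write variant calls to a minimal VCF v4.2 file
#'
#' @param variants data.frame with `contig`, `pos`, `ref`, `alt`.
#' @param path output path.
#' @param contig_lengths optional named integer vector used to emit
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=allergomics")
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  v <- variants[order(variants$contig, variants$pos, variants$ref,
                      variants$alt), , drop = FALSE]
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                  v$contig, as.integer(v$pos), v$ref, v$alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT is tab-separated: set name, description, then member genes.
#'
#' @param path GMT path.
#' @return named list of character vectors of gene names.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) stopf("GMT line with fewer than 3 fields")
    unique(f[-(1:2)])
  })
  names(out) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description column (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- mapply(function(nm, genes, d) {
    paste(c(nm, d, genes), collapse = "\t")
  }, names(sets), sets, rep_len(description, length(sets)))
  writeLines(unname(lines), path)
  invisible(path)
}

#' Write a numeric matrix as TSV with a leading id column
#' @param m matrix with row and column names.
#' @param path output path.
#' @param id_col name of the row-id column.
#' @return `path`, invisibly.
#' @export
write_tsv_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a numeric matrix from TSV written by [write_tsv_matrix()]
#' @param path TSV path.
#' @return numeric matrix with row names from the first column.
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a data frame as TSV
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV into a data frame
#' @param path TSV path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
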