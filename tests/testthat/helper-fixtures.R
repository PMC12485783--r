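# Shared fixtures and independent brute-force oracles. Everything is built
# in code; no binary fixtures.

# Small, fast config for generator-level tests; `...` overrides any default.
small_config <- function(seed = 1, ...) {
  args <- list(seed = seed, genome_length_bp = 50000,
               n_true_variants_per_sample = 50, n_blacklist_variants = 10,
               n_germline_variants = 20, n_shared_artifacts = 5,
               n_clustered_artifacts = 2, n_genes = 300, n_deg_up = 20,
               n_deg_down = 20, n_probes = 300, n_promoter_genes = 60,
               n_hyper = 10, n_hypo = 10, n_coupled_hypo_up = 4,
               n_coupled_hyper_down = 3)
  do.call(synth_config, utils::modifyList(args, list(...)))
}

# The default benchmark, computed once per test run.
.bench_cache <- new.env(parent = emptyenv())
default_benchmark <- function() {
  if (is.null(.bench_cache$b))
    .bench_cache$b <- simulate_benchmark(synth_config(seed = 42))
  .bench_cache$b
}

# Full downstream integration run on a benchmark object.
run_integration <- function(b) {
  counts <- filter_low_counts(b$expr$counts, 10)
  deg <- call_degs(de_test(counts, b$groups, a = "HDM"))
  pb <- aggregate_regions(b$meth$beta, b$meth$annotation$memberships,
                          "promoters")
  rq <- region_log2_quotient(pb, b$groups, a = "HDM")
  gm <- b$meth$annotation$gene_map
  rq$region <- gm$gene[match(rq$region, gm$region_id)]
  al <- align_layers(tmm_log2_cpm(counts), pb, gm)
  hdm <- names(b$groups)[b$groups == "HDM"]
  integrate_omics(al, deg, rq, cor_samples = hdm)
}

# A tiny deterministic genome built from an explicit string.
str_genome <- function(s) c(chrS = s)

# Random variant table on a genome, away from contig edges.
random_snvs <- function(genome, n, seed) {
  set.seed(seed)
  L <- nchar(genome[[1]])
  pos <- sample(5:(L - 5), n, replace = FALSE)
  ref <- substring(genome[[1]], pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1), USE.NAMES = FALSE)
  data.frame(contig = names(genome)[1], pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

# --- independent oracles ----------------------------------------------------

# SBS96: direct per-variant re-derivation with an explicit complement table.
oracle_sbs96 <- function(genome, pos, ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  s <- genome[[1]]
  l <- substr(s, pos - 1, pos - 1)
  r <- substr(s, pos + 1, pos + 1)
  stopifnot(substr(s, pos, pos) == ref)
  if (ref %in% c("A", "G")) {
    new_l <- comp[[r]]; new_r <- comp[[l]]
    ref <- comp[[ref]]; alt <- comp[[alt]]
    l <- new_l; r <- new_r
  }
  paste0(l, "[", ref, ">", alt, "]", r)
}

# Clustered-mutation flags by exhaustive window scan (O(n * range)).
oracle_clustered <- function(positions, window = 10, max_in_window = 3) {
  flag <- logical(length(positions))
  if (!length(positions)) return(flag)
  for (w in (min(positions) - window):(max(positions))) {
    inw <- which(positions >= w & positions <= w + window - 1)
    if (length(inw) > max_in_window) flag[inw] <- TRUE
  }
  flag
}

# ID83 homopolymer/repeat counting by explicit character scanning.
oracle_run_count <- function(seq_chars, site, base) {
  n <- 0L
  i <- site
  while (i <= length(seq_chars) && seq_chars[i] == base) { n <- n + 1L; i <- i + 1L }
  i <- site - 1L
  while (i >= 1L && seq_chars[i] == base) { n <- n + 1L; i <- i - 1L }
  n
}

# Independent ID83 re-derivation working on explicit character vectors with
# plain loops (a second implementation, structurally different from the
# package's substring-based one).
oracle_id83 <- function(chars, pos, ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (nchar(ref) > nchar(alt)) {
    unit <- strsplit(substr(ref, nchar(alt) + 1L, nchar(ref)), "")[[1]]
    site <- pos + nchar(alt)
    len <- length(unit)
    if (len == 1L) {
      run <- oracle_run_count(chars, site, unit)
      b <- if (unit %in% c("A", "G")) comp[[unit]] else unit
      return(sprintf("1:Del:%s:%d", b, min(run - 1L, 5L)))
    }
    # tandem copies 3' of the deletion start
    k <- 0L; i <- site
    while (i + len - 1L <= length(chars) &&
           all(chars[i:(i + len - 1L)] == unit)) { k <- k + 1L; i <- i + len }
    # full-length 5' copy also counts as a repeat
    full5 <- site - len >= 1L && all(chars[(site - len):(site - 1L)] == unit)
    if (k >= 2L || full5)
      return(sprintf("%d:Del:R:%d", min(len, 5L), min(max(k, 2L) - 1L, 5L)))
    mh3 <- 0L
    for (j in seq_len(len)) {
      p <- site + len + j - 1L
      if (p > length(chars) || chars[p] != unit[j]) break
      mh3 <- j
    }
    mh5 <- 0L
    for (j in seq_len(len)) {
      p <- site - j
      if (p < 1L || chars[p] != unit[len - j + 1L]) break
      mh5 <- j
    }
    mh <- max(mh3, mh5)
    if (mh >= 1L) return(sprintf("%d:Del:M:%d", min(len, 5L), min(mh, 5L)))
    return(sprintf("%d:Del:R:0", min(len, 5L)))
  }
  unit <- strsplit(substr(alt, nchar(ref) + 1L, nchar(alt)), "")[[1]]
  site <- pos + nchar(ref)
  len <- length(unit)
  if (len == 1L) {
    n <- 0L
    i <- site
    while (i <= length(chars) && chars[i] == unit) { n <- n + 1L; i <- i + 1L }
    i <- site - 1L
    while (i >= 1L && chars[i] == unit) { n <- n + 1L; i <- i - 1L }
    b <- if (unit %in% c("A", "G")) comp[[unit]] else unit
    return(sprintf("1:Ins:%s:%d", b, min(n, 5L)))
  }
  k <- 0L; i <- site
  while (i + len - 1L <= length(chars) &&
         all(chars[i:(i + len - 1L)] == unit)) { k <- k + 1L; i <- i + len }
  sprintf("%d:Ins:R:%d", min(len, 5L), min(k, 5L))
}

# Random anchored indels on a genome.
random_indels <- function(genome, n, seed, max_len = 5) {
  set.seed(seed)
  s <- genome[[1]]
  pos <- sample(20:(nchar(s) - 20), n)
  is_del <- runif(n) < 0.5
  len <- sample(seq_len(max_len), n, replace = TRUE)
  ref <- ifelse(is_del, substring(s, pos, pos + len), substring(s, pos, pos))
  alt <- ifelse(is_del, substring(s, pos, pos),
                paste0(substring(s, pos, pos),
                       vapply(len, function(k)
                         paste(sample(c("A", "C", "G", "T"), k,
                                      replace = TRUE), collapse = ""),
                         character(1))))
  data.frame(contig = names(genome)[1], pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

# Random DBS variants on a genome.
random_dbs <- function(genome, n, seed) {
  set.seed(seed)
  s <- genome[[1]]
  bases <- c("A", "C", "G", "T")
  pos <- sample(5:(nchar(s) - 5), n)
  ref <- substring(s, pos, pos + 1)
  alt <- vapply(ref, function(r)
    paste0(sample(setdiff(bases, substr(r, 1, 1)), 1),
           sample(setdiff(bases, substr(r, 2, 2)), 1)),
    character(1), USE.NAMES = FALSE)
  data.frame(contig = names(genome)[1], pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}
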