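test_that("classify_variants follows the allele-length rules", {
  expect_identical(
    classify_variants(c("A", "AT", "A", "AT", "ATG", "AC"),
                      c("T", "GC", "AT", "A", "ACG", "AA")),
    c("SNV", "DBS", "INS", "DEL", "MNV-other", "MNV-other"))
  expect_error(classify_variants("A", "A"), "differ")
})

test_that("read_vcf parses records, splits multi-allelics, classes variants", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrS,length=10000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chrS\t100\t.\tA\tT\t.\tPASS\t.",
    "chrS\t200\t.\tAT\tGC\t.\tPASS\t.",
    "chrS\t300\t.\tC\tT,G\t.\tPASS\t.",
    "chrS\t400\t.\tG\tGAA\t.\tPASS\t.",
    "chrS\t500\t.\tGTT\tG\t.\tPASS\t."), path)
  v <- read_vcf(path, sample_id = "s1", caller_id = "mutect2")
  expect_identical(nrow(v), 6L)
  expect_identical(v$var_class[v$pos == 100], "SNV")
  expect_identical(v$var_class[v$pos == 200], "DBS")
  expect_identical(sort(v$alt[v$pos == 300]), c("G", "T"))
  expect_identical(v$var_class[v$pos == 400], "INS")
  expect_identical(v$var_class[v$pos == 500], "DEL")
  expect_identical(unique(v$sample_id), "s1")
})

test_that("VCF round-trip through write_vcf/read_vcf preserves variants", {
  g <- generate_reference(50000, 0.5, seed = 3)
  v <- random_snvs(g, 40, seed = 4)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, path, contig_lengths = c(chrS = 50000L))
  v2 <- read_vcf(path)
  key <- function(d) sort(paste(d$contig, d$pos, d$ref, d$alt))
  expect_identical(key(v2), key(v))
})

test_that("consensus_calls keeps variants with >= min_callers supporters", {
  v1 <- data.frame(contig = "chrS", pos = 100L, ref = "A", alt = "T")
  v2 <- data.frame(contig = "chrS", pos = 200L, ref = "C", alt = "G")
  sets <- list(A = rbind(v1, v2), B = v1)
  cs <- consensus_calls(sets, min_callers = 2)
  expect_identical(cs$pos, 100L)
  expect_identical(cs$supporting_callers, "A,B")
  # degenerate threshold: union
  cs1 <- consensus_calls(sets, min_callers = 1)
  expect_identical(sort(cs1$pos), c(100L, 200L))
  expect_error(consensus_calls(sets, min_callers = 0), "min_callers")
})

test_that("two-of-four consensus retains the binomial fraction of true variants", {
  # independent oracle: P(>=2 of 4 at sens 0.9) = 1 - 0.1^4 - 4*0.9*0.1^3
  p_expected <- 1 - 0.1^4 - 4 * 0.9 * 0.1^3
  set.seed(99)
  n <- 4000
  support <- rowSums(matrix(runif(n * 4) <= 0.9, n, 4))
  expect_lt(abs(mean(support >= 2) - p_expected), 0.01)

  cfg <- small_config(seed = 11, n_true_variants_per_sample = 400,
                      caller_fp_rates = stats::setNames(rep(0, 4),
                        c("mutect2", "varscan2", "strelka2", "muse")),
                      n_blacklist_variants = 0, n_germline_variants = 0,
                      n_shared_artifacts = 0, n_clustered_artifacts = 0,
                      genome_length_bp = 200000)
  g <- generate_reference(cfg$genome_length_bp, cfg$gc_fraction, cfg$seed)
  sim <- simulate_callsets(g, cfg)
  cs <- consensus_calls(sim$callsets, 2)
  tv <- sim$truth$true_variants
  key <- function(d) paste(d$sample_id, d$pos, d$ref, d$alt)
  recall <- mean(key(tv) %in% key(cs))
  expect_gte(recall, 0.95)
  expect_lt(abs(recall - p_expected), 0.02)
})

test_that("blacklist and germline filters are allele-exact flags", {
  cs <- consensus_calls(list(A = data.frame(
    contig = "chrS", pos = c(500L, 600L), ref = c("A", "C"),
    alt = c("G", "T"))), min_callers = 1)
  bl <- data.frame(contig = "chrS", pos = 500L, ref = "A", alt = "G")
  out <- filter_blacklist(cs, bl)
  expect_identical(out$flag_blacklist, c(TRUE, FALSE))
  # allele mismatch is not flagged
  bl2 <- data.frame(contig = "chrS", pos = 500L, ref = "A", alt = "T")
  expect_false(any(filter_blacklist(cs, bl2)$flag_blacklist))
  # empty blacklist is the identity
  expect_identical(filter_blacklist(cs, bl[0, ]), cs)

  germ <- list(mouse_1 = data.frame(contig = "chrS", pos = 600L, ref = "C",
                                    alt = "T"))
  out2 <- subtract_germline(cs, germ, c(sample1 = "mouse_1"))
  expect_identical(out2$flag_germline, c(FALSE, TRUE))
  expect_error(subtract_germline(cs, germ, c(other = "mouse_1")),
               "germline mapping")
  # two samples, same mouse: both filtered against the same germline list
  cs2 <- consensus_calls(list(
    s1 = list(A = data.frame(contig = "chrS", pos = 600L, ref = "C", alt = "T")),
    s2 = list(A = data.frame(contig = "chrS", pos = 600L, ref = "C", alt = "T"))),
    min_callers = 1)
  out3 <- subtract_germline(cs2, germ, c(s1 = "mouse_1", s2 = "mouse_1"))
  expect_true(all(out3$flag_germline))
})

test_that("filter_shared flags identities present in >= min_samples samples", {
  mk <- function(pos) data.frame(contig = "chrS", pos = pos, ref = "C",
                                 alt = "T")
  cs <- consensus_calls(list(S1 = list(A = mk(c(700L, 800L))),
                             S2 = list(A = mk(700L))), min_callers = 1)
  out <- filter_shared(cs, 2)
  expect_identical(out$flag_shared[out$pos == 700], c(TRUE, TRUE))
  expect_false(any(out$flag_shared[out$pos == 800]))
  # below threshold: retained
  expect_false(any(filter_shared(cs, 3)$flag_shared))
  # single sample: warning no-op
  cs1 <- consensus_calls(list(S1 = list(A = mk(700L))), min_callers = 1)
  expect_warning(out1 <- filter_shared(cs1, 2), "fewer than 2")
  expect_false(any(out1$flag_shared))
})

test_that("filter_clustered implements the >3-in-10bp rule", {
  mk_cs <- function(pos) consensus_calls(list(A = data.frame(
    contig = "chrS", pos = pos, ref = "C", alt = "T")), min_callers = 1)
  # worked example: {100,102,105,109} span 10 bp -> flagged; 500 retained
  out <- filter_clustered(mk_cs(c(100L, 102L, 105L, 109L, 500L)))
  expect_identical(out$flag_clustered[order(out$pos)],
                   c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # exactly 3 within 10 bp: none flagged (strict >3)
  out3 <- filter_clustered(mk_cs(c(100L, 105L, 109L)))
  expect_false(any(out3$flag_clustered))
  expect_error(filter_clustered(mk_cs(100L), window_bp = 0), "window_bp")
})

test_that("filter_clustered matches the brute-force window oracle", {
  set.seed(21)
  for (rep in 1:3) {
    pos <- sort(sample(1:2000, 200, replace = FALSE))
    cs <- consensus_calls(list(A = data.frame(
      contig = "chrS", pos = pos, ref = "C", alt = "T")), min_callers = 1)
    out <- filter_clustered(cs)
    expect_identical(out$flag_clustered[match(pos, out$pos)],
                     oracle_clustered(pos))
  }
})

test_that("filters are idempotent, order-stable and conserve variants", {
  cfg <- small_config(seed = 13)
  g <- generate_reference(cfg$genome_length_bp, cfg$gc_fraction, cfg$seed)
  sim <- simulate_callsets(g, cfg)
  cs <- consensus_calls(sim$callsets, 2)
  bl <- sim$truth$blacklist_variants
  germ <- sim$truth$germline
  s2i <- sim$truth$sample_to_individual
  apply_all <- function(x, order) {
    fns <- list(
      b = function(y) filter_blacklist(y, bl),
      g = function(y) subtract_germline(y, germ, s2i),
      s = function(y) filter_shared(y, 2),
      c = function(y) filter_clustered(y))
    for (f in order) x <- fns[[f]](x)
    x
  }
  ref <- apply_all(cs, c("b", "g", "s", "c"))
  # idempotence
  expect_identical(apply_all(ref, c("b", "g", "s", "c")), ref)
  # order stability
  perm <- apply_all(cs, c("c", "s", "g", "b"))
  expect_identical(perm[order(perm$sample_id, perm$pos), ],
                   ref[order(ref$sample_id, ref$pos), ])
  # conservation: nothing silently lost
  expect_identical(nrow(ref), nrow(cs))
  expect_identical(nrow(consensus_retained(ref)) +
                     sum(ref$flag_blacklist | ref$flag_germline |
                           ref$flag_shared | ref$flag_clustered),
                   nrow(ref))
  # summary is consistent
  s <- consensus_summary(ref)
  expect_identical(unname(s["total"]), nrow(cs))
})

test_that("the filter chain removes planted artifacts with high precision/recall", {
  cfg <- small_config(seed = 17, genome_length_bp = 200000,
                      n_true_variants_per_sample = 300)
  g <- generate_reference(cfg$genome_length_bp, cfg$gc_fraction, cfg$seed)
  sim <- simulate_callsets(g, cfg)
  cs <- consensus_calls(sim$callsets, 2)
  cs <- filter_blacklist(cs, sim$truth$blacklist_variants)
  cs <- subtract_germline(cs, sim$truth$germline,
                          sim$truth$sample_to_individual)
  cs <- filter_shared(cs, 2)
  cs <- filter_clustered(cs)
  kept <- consensus_retained(cs)
  key <- function(d) paste(d$sample_id, d$pos, d$ref, d$alt)
  tv <- sim$truth$true_variants
  recall <- mean(key(tv) %in% key(kept))
  precision <- mean(key(kept) %in% key(tv))
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})
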