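test_that("channel catalogs have the canonical sizes and unique labels", {
  expect_length(sbs96_channels(), 96)
  expect_length(dbs78_channels(), 78)
  expect_length(id83_channels(), 83)
  expect_identical(anyDuplicated(sbs96_channels()), 0L)
  expect_identical(anyDuplicated(dbs78_channels()), 0L)
  expect_identical(anyDuplicated(id83_channels()), 0L)
})

test_that("sbs96_channel maps the worked examples and normalizes strand", {
  g <- str_genome("TTCAA")
  v <- data.frame(contig = "chrS", pos = 3L, ref = "C", alt = "T")
  expect_identical(sbs96_channel(v, g), "T[C>T]A")
  g2 <- str_genome("AAGCC")
  v2 <- data.frame(contig = "chrS", pos = 3L, ref = "G", alt = "T")
  expect_identical(sbs96_channel(v2, g2), "G[C>A]T")
  # contig edge -> NA; genome mismatch -> error
  ve <- data.frame(contig = "chrS", pos = 1L, ref = "T", alt = "A")
  expect_true(is.na(sbs96_channel(ve, g)))
  vb <- data.frame(contig = "chrS", pos = 3L, ref = "A", alt = "T")
  expect_error(sbs96_channel(vb, g), "disagrees")
})

test_that("every strand-normalized SNV combination yields the 96 catalog labels", {
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(l = bases, m = bases, r = bases, alt = bases,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$m != combos$alt, ]
  labels <- vapply(seq_len(nrow(combos)), function(i) {
    g <- str_genome(paste0("A", combos$l[i], combos$m[i], combos$r[i], "A"))
    v <- data.frame(contig = "chrS", pos = 3L, ref = combos$m[i],
                    alt = combos$alt[i])
    sbs96_channel(v, g)
  }, character(1))
  expect_identical(sort(unique(labels)), sort(sbs96_channels()))
  expect_identical(nrow(combos), 192L)  # each label hit exactly twice
})

test_that("sbs96_channel agrees with the brute-force oracle on random variants", {
  g <- generate_reference(50000, 0.45, seed = 8)
  v <- random_snvs(g, 1000, seed = 9)
  got <- sbs96_channel(v, g)
  want <- vapply(seq_len(nrow(v)), function(i)
    oracle_sbs96(g, v$pos[i], v$ref[i], v$alt[i]), character(1))
  expect_identical(got, want)
})

test_that("strand involution: a variant and its reverse complement share channels", {
  g <- generate_reference(20000, 0.5, seed = 10)
  v <- random_snvs(g, 200, seed = 11)
  L <- nchar(g[[1]])
  g_rc <- str_genome(revcomp(g[[1]]))
  v_rc <- data.frame(contig = "chrS", pos = L - v$pos + 1L,
                     ref = revcomp(v$ref), alt = revcomp(v$alt))
  expect_identical(sbs96_channel(v, g), sbs96_channel(v_rc, g_rc))
})

test_that("dbs78_channel canonicalizes doublets", {
  g <- str_genome("AGGTT")
  v <- data.frame(contig = "chrS", pos = 2L, ref = "GG", alt = "TT")
  expect_identical(dbs78_channel(v, g), "CC>AA")
  g2 <- str_genome("AACTT")
  v2 <- data.frame(contig = "chrS", pos = 2L, ref = "AC", alt = "TT")
  expect_identical(dbs78_channel(v2, g2), "AC>TT")
})

test_that("DBS enumeration: 144 valid doublets collapse onto the 78 channels", {
  bases <- c("A", "C", "G", "T")
  refs <- as.vector(outer(bases, bases, paste0))
  all_labels <- character(0)
  for (ref in refs) {
    alts <- as.vector(outer(setdiff(bases, substr(ref, 1, 1)),
                            setdiff(bases, substr(ref, 2, 2)), paste0))
    for (alt in alts) {
      g <- str_genome(paste0("A", ref, "A"))
      v <- data.frame(contig = "chrS", pos = 2L, ref = ref, alt = alt)
      lab <- dbs78_channel(v, g)
      all_labels <- c(all_labels, lab)
      # involution: the reverse complement maps to the same channel
      g_rc <- str_genome(revcomp(g[[1]]))
      v_rc <- data.frame(contig = "chrS", pos = 2L, ref = revcomp(ref),
                         alt = revcomp(alt))
      expect_identical(dbs78_channel(v_rc, g_rc), lab)
    }
  }
  expect_identical(length(all_labels), 144L)
  expect_identical(sort(unique(all_labels)), sort(dbs78_channels()))
})

test_that("id83_channel handles the worked 1-bp deletion examples", {
  # deletion of one C with no adjacent C: homopolymer length 1 -> bin 0
  g <- str_genome("ATACATA")
  v <- data.frame(contig = "chrS", pos = 4L, ref = "CA", alt = "C")
  # deleting the A at position 5 (run of 1? A at 5, neighbors T) -- use C del:
  v <- data.frame(contig = "chrS", pos = 3L, ref = "AC", alt = "A")
  expect_identical(id83_channel(v, g), "1:Del:C:0")
  # deletion of one T inside a run of six T's -> top bin (6+)
  g6 <- str_genome(paste0("AC", strrep("T", 6), "GA"))
  v6 <- data.frame(contig = "chrS", pos = 2L, ref = "CT", alt = "C")
  expect_identical(id83_channel(v6, g6), "1:Del:T:5")
  # 1-bp deletion of A counts as T after strand normalization
  ga <- str_genome("GCAAAGC")
  va <- data.frame(contig = "chrS", pos = 2L, ref = "CA", alt = "C")
  expect_identical(id83_channel(va, ga), "1:Del:T:2")
})

test_that("id83_channel classifies insertions, repeats and microhomology", {
  # 1-bp insertion of C next to no C: 0 existing copies
  g <- str_genome("ATATATA")
  v <- data.frame(contig = "chrS", pos = 2L, ref = "T", alt = "TC")
  expect_identical(id83_channel(v, g), "1:Ins:C:0")
  # insertion of C before a run of 3 C's
  g3 <- str_genome(paste0("AT", strrep("C", 3), "GA"))
  v3 <- data.frame(contig = "chrS", pos = 2L, ref = "T", alt = "TC")
  expect_identical(id83_channel(v3, g3), "1:Ins:C:3")
  # 2-bp deletion of one unit of a (AC)x3 tandem repeat
  gr <- str_genome(paste0("T", strrep("AC", 3), "GGT"))
  vr <- data.frame(contig = "chrS", pos = 1L, ref = "TAC", alt = "T")
  expect_identical(id83_channel(vr, gr), "2:Del:R:2")
  # 3-bp deletion with 2-base 3' microhomology, no tandem copy
  #   delete GCA from T|GCA|GC T T: flank starts GC -> mh 2
  gm <- str_genome("TGCAGCTT")
  vm <- data.frame(contig = "chrS", pos = 1L, ref = "TGCA", alt = "T")
  expect_identical(id83_channel(vm, gm), "3:Del:M:2")
  # 2-bp insertion of a new unit: 1 existing copy -> R:1
  gi <- str_genome("TACGGGT")
  vi <- data.frame(contig = "chrS", pos = 1L, ref = "T", alt = "TAC")
  expect_identical(id83_channel(vi, gi), "2:Ins:R:1")
})

test_that("1-bp indel homopolymer bins match an explicit run-count oracle", {
  g <- generate_reference(20000, 0.5, seed = 12)
  chars <- strsplit(g[[1]], "")[[1]]
  set.seed(13)
  pos <- sample(10:(length(chars) - 10), 400)
  # deletions of the base at pos+1, anchored at pos
  v <- data.frame(contig = "chrS", pos = pos,
                  ref = paste0(chars[pos], chars[pos + 1]),
                  alt = chars[pos], stringsAsFactors = FALSE)
  labs <- id83_channel(v, g)
  for (i in seq_along(pos)) {
    run <- oracle_run_count(chars, pos[i] + 1L, chars[pos[i] + 1])
    base <- chars[pos[i] + 1]
    if (base %in% c("A", "G")) base <- c(A = "T", G = "C")[[base]]
    expect_identical(labs[i], sprintf("1:Del:%s:%d", base, min(run - 1, 5)))
  }
})

test_that("random small indels always land in the 83-channel catalog", {
  g <- generate_reference(30000, 0.42, seed = 14)
  s <- g[[1]]
  set.seed(15)
  n <- 500
  pos <- sample(20:(nchar(s) - 20), n)
  is_del <- runif(n) < 0.5
  len <- sample(1:6, n, replace = TRUE)
  ref <- ifelse(is_del, substring(s, pos, pos + len),
                substring(s, pos, pos))
  alt <- ifelse(is_del, substring(s, pos, pos),
                paste0(substring(s, pos, pos),
                       vapply(len, function(k)
                         paste(sample(c("A", "C", "G", "T"), k,
                                      replace = TRUE), collapse = ""),
                         character(1))))
  v <- data.frame(contig = "chrS", pos = pos, ref = ref, alt = alt,
                  stringsAsFactors = FALSE)
  labs <- id83_channel(v, g)
  expect_true(all(labs %in% id83_channels()))
})

test_that("build_profile counts, reports boundary exclusions, and is additive", {
  g <- generate_reference(20000, 0.5, seed = 16)
  expect_identical(
    sum(build_profile(data.frame(contig = character(), pos = integer(),
                                 ref = character(), alt = character()),
                      g, "SBS96")), 0)
  v1 <- data.frame(contig = "chrS", pos = 100L,
                   ref = substr(g[[1]], 100, 100), alt = NA)
  v1$alt <- setdiff(c("A", "C", "G", "T"), v1$ref)[1]
  p1 <- build_profile(v1, g, "SBS96")
  expect_identical(sum(p1), 1)
  expect_identical(unname(attr(p1, "n_total")), 1)
  # additivity: profile of concatenation = sum of profiles
  va <- random_snvs(g, 300, seed = 17)
  vb <- random_snvs(g, 200, seed = 18)
  pa <- build_profile(va, g, "SBS96")
  pb <- build_profile(vb, g, "SBS96")
  pab <- build_profile(rbind(va, vb), g, "SBS96")
  expect_equal(as.numeric(pab), as.numeric(pa) + as.numeric(pb))
  # contig-edge variant is excluded and counted
  vedge <- data.frame(contig = "chrS", pos = 1L,
                      ref = substr(g[[1]], 1, 1), alt = "N")
  vedge$alt <- setdiff(c("A", "C", "G", "T"), vedge$ref)[1]
  pe <- build_profile(rbind(va, vedge), g, "SBS96")
  expect_identical(attr(pe, "n_unclassified"), 1L)
  expect_identical(sum(pe), sum(pa))
})

test_that("profile of multinomial draws recovers the channel distribution", {
  set.seed(19)
  chans <- sbs96_channels()
  probs <- rep(1 / 96, 96)
  draws <- table(factor(sample(chans, 1000, replace = TRUE, prob = probs),
                        levels = chans))
  p <- spectrum_profile(stats::setNames(as.numeric(draws), chans), "SBS96")
  expect_equal(sum(p), 1000)
  expect_lt(max(abs(as.numeric(p) / 1000 - probs)),
            5 * sqrt(max(probs * (1 - probs)) / 1000))
})

test_that("cosine_similarity: identity, orthogonality, scale invariance", {
  chans <- sbs96_channels()
  set.seed(20)
  p <- spectrum_profile(stats::setNames(rpois(96, 20) + 1, chans), "SBS96")
  expect_equal(cosine_similarity(p, p), 1, tolerance = 1e-12)
  a <- spectrum_profile(c("A[C>A]A" = 5), "SBS96")
  b <- spectrum_profile(c("T[T>G]T" = 3), "SBS96")
  expect_equal(cosine_similarity(a, b), 0)
  q <- spectrum_profile(stats::setNames(as.numeric(p) * 7.5, chans), "SBS96")
  expect_equal(cosine_similarity(p, q), 1, tolerance = 1e-12)
  expect_equal(cosine_similarity(p, b), cosine_similarity(b, p))
  zero <- spectrum_profile(numeric(0), "SBS96")
  expect_error(cosine_similarity(p, zero), "zero")
  expect_error(cosine_similarity(p, spectrum_profile(c("AC>CA" = 1), "DBS78")),
               "schema")
})

test_that("average_profiles averages normalized profiles", {
  chans <- sbs96_channels()
  set.seed(22)
  p <- spectrum_profile(stats::setNames(rpois(96, 10) + 1, chans), "SBS96")
  avg_same <- average_profiles(list(p, p, p))
  expect_equal(as.numeric(avg_same), as.numeric(p) / sum(p), tolerance = 1e-12)
  one_a <- spectrum_profile(c("A[C>A]A" = 4), "SBS96")
  one_b <- spectrum_profile(c("T[T>G]T" = 2), "SBS96")
  avg <- average_profiles(list(one_a, one_b))
  expect_equal(unname(avg["A[C>A]A"]), 0.5)
  expect_equal(unname(avg["T[T>G]T"]), 0.5)
  expect_equal(sum(avg), 1)
  # brute-force element-wise mean of k random normalized profiles
  ps <- lapply(1:4, function(i)
    spectrum_profile(stats::setNames(rpois(96, 15) + 1, chans), "SBS96"))
  brute <- rowMeans(vapply(ps, function(x) as.numeric(x) / sum(x),
                           numeric(96)))
  expect_equal(as.numeric(average_profiles(ps)), brute, tolerance = 1e-12)
  expect_error(average_profiles(list()), "at least one")
})

test_that("mutational burden arithmetic and Welch comparison", {
  b <- mutational_burden(300, 1e8)
  expect_equal(b$burden_per_mb, 3.0)
  expect_equal(mutational_burden(0, 123)$burden_per_mb, 0)
  expect_error(mutational_burden(10, 0), "callable_bases")
  # Welch on per-sample burdens matches the closed form via stats::t.test
  cons <- data.frame(sample_id = rep(c("a", "b", "c", "d", "e", "f"),
                                     c(10, 12, 9, 20, 25, 22)))
  groups <- stats::setNames(rep(c("VEH", "HDM"), each = 3),
                            c("a", "b", "c", "d", "e", "f"))
  bt <- burden_table(cons, 1e6, groups)
  tt <- stats::t.test(burden_per_mb ~ group, data = bt$table)
  expect_equal(bt$test$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(abs(bt$test$t), abs(unname(tt$statistic)), tolerance = 1e-12)
})
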