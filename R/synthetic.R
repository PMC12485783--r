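# Synthetic multi-omics benchmark generator.
#
# Emulates the data the pipeline consumes in a two-arm (vehicle vs allergen,
# "VEH"/"HDM") mouse design with n samples per arm: per-caller somatic call
# sets with shared true variants plus caller-private false positives,
# blacklist/germline contaminants, cross-sample and clustered artifacts;
# negative-binomial RNA-seq counts with planted up/down DEGs; logit-normal
# promoter beta values with planted hyper/hypo DMSs; and a set of coupled
# genes whose promoter methylation and expression share one latent
# per-sample factor with opposite signs, giving the strictly monotone
# inverse relation the integration filter is designed to detect (12
# hypomethylated-upregulated and 8 hypermethylated-downregulated by
# default). Truth tables describing everything planted are returned for
# recovery testing. One root seed deterministically derives per-stage
# sub-seeds.

CALLERS <- c("mutect2", "varscan2", "strelka2", "muse")

#' Synthetic benchmark configuration
#'
#' All defaults define the package's standard benchmark world: 3 samples per
#' arm, two-of-four caller consensus inputs, 2,000 genes
#' with 100 up / 100 down planted DEGs at |log2FC| 2, 2,000 probes with 50
#' hyper / 30 hypo planted DMSs at |delta-beta| 0.3, and 12 + 8 coupled
#' promoter-methylation/expression genes.
#'
#' @param seed root seed; per-stage sub-seeds are derived from it.
#' @param genome_length_bp single synthetic contig length.
#' @param gc_fraction genome GC content in (0, 1).
#' @param n_samples_per_arm samples per treatment arm.
#' @param n_true_variants_per_sample planted somatic variants per sample.
#' @param var_class_props named proportions over SNV/DBS/INS/DEL.
#' @param caller_sensitivities per-caller detection probability for true
#'   variants.
#' @param caller_fp_rates per-caller expected private false calls per Mb.
#' @param n_blacklist_variants known-polymorphism contaminants planted.
#' @param n_germline_variants germline variants per individual; a fraction
#'   leaks into that individual's somatic calls.
#' @param germline_leak_fraction fraction of germline variants leaking.
#' @param n_shared_artifacts artifacts planted identically in >= 2 samples.
#' @param n_clustered_artifacts clustered runs (>= 4 variants within 10 bp).
#' @param n_genes,n_deg_up,n_deg_down,deg_log2fc,nb_dispersion,lib_size_range
#'   expression layer: gene count, planted DEG counts, planted effect size,
#'   NB overdispersion, library-size range.
#' @param n_probes,n_promoter_genes,probes_per_promoter methylation layout.
#' @param n_hyper,n_hypo planted hyper-/hypomethylated probes (whole
#'   promoters; must be multiples of `probes_per_promoter`).
#' @param delta_beta_planted planted group-mean beta difference in (0, 1).
#' @param logit_noise_sd per-sample noise SD on the logit scale.
#' @param n_coupled_hypo_up,n_coupled_hyper_down coupled-gene counts.
#' @param coupling_noise_sd SD of independent noise added on each coupled
#'   layer (log2 expression and beta scales); 0 gives an exactly collinear
#'   latent relation.
#' @param coupling_expr_sd,coupling_beta_slope latent-factor loadings on the
#'   log2 expression and beta scales.
#' @return validated config list of class `synth_config`.
#' @export
synth_config <- function(seed = 42L,
                         genome_length_bp = 1e6,
                         gc_fraction = 0.42,
                         n_samples_per_arm = 3L,
                         n_true_variants_per_sample = 500L,
                         var_class_props = c(SNV = 0.80, DBS = 0.08,
                                             INS = 0.06, DEL = 0.06),
                         caller_sensitivities = stats::setNames(
                           rep(0.9, 4), CALLERS),
                         caller_fp_rates = stats::setNames(rep(10, 4),
                                                           CALLERS),
                         n_blacklist_variants = 50L,
                         n_germline_variants = 100L,
                         germline_leak_fraction = 0.3,
                         n_shared_artifacts = 25L,
                         n_clustered_artifacts = 3L,
                         n_genes = 2000L,
                         n_deg_up = 100L,
                         n_deg_down = 100L,
                         deg_log2fc = 2,
                         nb_dispersion = 0.1,
                         lib_size_range = c(8e5, 1.2e6),
                         n_probes = 2000L,
                         n_promoter_genes = 400L,
                         probes_per_promoter = 2L,
                         n_hyper = 50L,
                         n_hypo = 30L,
                         delta_beta_planted = 0.3,
                         logit_noise_sd = 0.3,
                         n_coupled_hypo_up = 12L,
                         n_coupled_hyper_down = 8L,
                         coupling_noise_sd = 0.001,
                         coupling_expr_sd = 0.5,
                         coupling_beta_slope = 0.05) {
  cfg <- as.list(environment())
  assert_count(cfg$genome_length_bp, "genome_length_bp", min = 1000)
  if (cfg$gc_fraction <= 0 || cfg$gc_fraction >= 1)
    stopf("'gc_fraction' must lie in (0, 1)")
  assert_count(cfg$n_samples_per_arm, "n_samples_per_arm", min = 1)
  assert_count(cfg$n_true_variants_per_sample, "n_true_variants_per_sample")
  assert_prob(cfg$caller_sensitivities, "caller_sensitivities")
  if (any(cfg$caller_fp_rates < 0)) stopf("fp rates must be nonnegative")
  for (f in c("n_blacklist_variants", "n_germline_variants",
              "n_shared_artifacts", "n_clustered_artifacts", "n_genes",
              "n_deg_up", "n_deg_down", "n_probes", "n_promoter_genes",
              "probes_per_promoter", "n_hyper", "n_hypo",
              "n_coupled_hypo_up", "n_coupled_hyper_down",
              "n_samples_per_arm", "n_true_variants_per_sample")) {
    assert_count(cfg[[f]], f)
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  if (cfg$nb_dispersion <= 0) stopf("'nb_dispersion' must be positive")
  if (cfg$delta_beta_planted <= 0 || cfg$delta_beta_planted >= 1)
    stopf("'delta_beta_planted' must lie in (0, 1)")
  if (cfg$logit_noise_sd < 0 || cfg$coupling_noise_sd < 0)
    stopf("noise SDs must be nonnegative")
  if (cfg$n_genes < cfg$n_deg_up + cfg$n_deg_down)
    stopf("n_genes must cover the planted DEGs")
  if (cfg$n_promoter_genes * cfg$probes_per_promoter > cfg$n_probes)
    stopf("promoter probes exceed n_probes")
  if (cfg$n_hyper %% cfg$probes_per_promoter != 0 ||
      cfg$n_hypo %% cfg$probes_per_promoter != 0)
    stopf("n_hyper and n_hypo must be multiples of probes_per_promoter")
  n_dms_genes <- (cfg$n_hyper + cfg$n_hypo) / cfg$probes_per_promoter
  n_coupled <- cfg$n_coupled_hypo_up + cfg$n_coupled_hyper_down
  if (n_dms_genes + n_coupled > cfg$n_promoter_genes)
    stopf("planted DMS genes plus coupled genes exceed n_promoter_genes")
  if (cfg$n_genes < cfg$n_promoter_genes)
    stopf("every promoter gene must exist in the expression layer")
  structure(cfg, class = "synth_config")
}

sample_names <- function(cfg) {
  n <- cfg$n_samples_per_arm
  c(paste0("VEH_", seq_len(n)), paste0("HDM_", seq_len(n)))
}

sample_groups <- function(cfg) {
  n <- cfg$n_samples_per_arm
  stats::setNames(rep(c("VEH", "HDM"), each = n), sample_names(cfg))
}

gene_names <- function(cfg) sprintf("gene%04d", seq_len(cfg$n_genes))

#' Generate a synthetic reference contig
#'
#' One contig named "chrS" with i.i.d. bases at composition
#' (gc/2, gc/2, (1-gc)/2, (1-gc)/2) for (C, G, A, T).
#'
#' @param length_bp contig length (>= 1000).
#' @param gc_fraction GC content in (0, 1).
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @return named character vector of length 1 (the contig).
#' @export
generate_reference <- function(length_bp, gc_fraction, seed) {
  assert_count(length_bp, "length_bp", min = 1000)
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stopf("'gc_fraction' must lie in (0, 1)")
  set.seed(stream_seed(seed, 1L))
  p <- c(C = gc_fraction / 2, G = gc_fraction / 2,
         A = (1 - gc_fraction) / 2, T = (1 - gc_fraction) / 2)
  bases <- sample(names(p), length_bp, replace = TRUE, prob = p)
  c(chrS = paste(bases, collapse = ""))
}

# Draw a variant of a given class anchored at reference position pos.
make_variant <- function(genome, contig, pos, cls) {
  base_at <- function(p) substr(genome[[contig]], p, p)
  if (cls == "SNV") {
    ref <- base_at(pos)
    alt <- sample(setdiff(BASES, ref), 1)
  } else if (cls == "DBS") {
    ref <- substr(genome[[contig]], pos, pos + 1L)
    a1 <- sample(setdiff(BASES, substr(ref, 1, 1)), 1)
    a2 <- sample(setdiff(BASES, substr(ref, 2, 2)), 1)
    alt <- paste0(a1, a2)
  } else if (cls == "INS") {
    ref <- base_at(pos)
    alt <- paste0(ref, paste(sample(BASES, sample(1:3, 1), replace = TRUE),
                             collapse = ""))
  } else {
    len <- sample(1:3, 1)
    ref <- substr(genome[[contig]], pos, pos + len)
    alt <- base_at(pos)
  }
  data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
             var_class = cls, stringsAsFactors = FALSE)
}

#' Simulate per-sample, per-caller somatic call sets
#'
#' Plants true variants, caller-private false positives, blacklist
#' contaminants, germline leakage, cross-sample shared artifacts and
#' clustered artifact runs on a position grid coarse enough that no two
#' planted events collide or cluster accidentally.
#'
#' @param genome output of [generate_reference()].
#' @param cfg a [synth_config()].
#' @return list with `callsets` (sample -> caller -> variant data.frame),
#'   `truth` (true_variants, blacklist_variants, germline per individual,
#'   shared_artifacts, clustered_artifacts, sample_to_individual) and
#'   `samples`/`groups`.
#' @export
simulate_callsets <- function(genome, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(stream_seed(cfg$seed, 2L))
  contig <- names(genome)[1]
  L <- nchar(genome[[contig]])
  samples <- sample_names(cfg)
  ns <- length(samples)
  grid <- seq(30L, L - 30L, by = 25L)
  n_slots <- ns * cfg$n_true_variants_per_sample + cfg$n_blacklist_variants +
    ns * cfg$n_germline_variants + cfg$n_shared_artifacts +
    cfg$n_clustered_artifacts
  if (n_slots > length(grid))
    stopf("genome too short to host %d planted events without collisions",
          n_slots)
  slots <- sample(grid, n_slots)
  take <- function(k) {
    if (k == 0) return(integer(0))
    out <- slots[seq_len(k)]
    slots <<- slots[-seq_len(k)]
    out
  }
  draw_variants <- function(pos, classes) {
    do.call(rbind, mapply(make_variant, pos = pos, cls = classes,
                          MoreArgs = list(genome = genome, contig = contig),
                          SIMPLIFY = FALSE))
  }

  true_list <- lapply(samples, function(sid) {
    k <- cfg$n_true_variants_per_sample
    if (k == 0) return(NULL)
    cls <- sample(names(cfg$var_class_props), k, replace = TRUE,
                  prob = cfg$var_class_props)
    v <- draw_variants(take(k), cls)
    v$sample_id <- sid
    v
  })
  true_variants <- do.call(rbind, true_list)

  blacklist <- if (cfg$n_blacklist_variants > 0)
    draw_variants(take(cfg$n_blacklist_variants),
                  rep("SNV", cfg$n_blacklist_variants)) else NULL
  # each blacklist variant contaminates one random sample (all callers)
  bl_sample <- if (!is.null(blacklist))
    sample(samples, nrow(blacklist), replace = TRUE) else character(0)

  individuals <- stats::setNames(paste0("mouse_", seq_len(ns)), samples)
  germline <- lapply(samples, function(sid) {
    if (cfg$n_germline_variants == 0) return(NULL)
    draw_variants(take(cfg$n_germline_variants),
                  rep("SNV", cfg$n_germline_variants))
  })
  names(germline) <- individuals[samples]

  shared <- if (cfg$n_shared_artifacts > 0)
    draw_variants(take(cfg$n_shared_artifacts),
                  rep("SNV", cfg$n_shared_artifacts)) else NULL
  shared_samples <- if (!is.null(shared) && ns >= 2)
    lapply(seq_len(nrow(shared)), function(i) sample(samples, 2)) else list()

  clustered <- NULL
  if (cfg$n_clustered_artifacts > 0) {
    anchors <- take(cfg$n_clustered_artifacts)
    clustered <- do.call(rbind, lapply(seq_along(anchors), function(i) {
      offs <- c(0L, 2L, 5L, 9L)          # 4 variants spanning 10 bp
      v <- draw_variants(anchors[i] + offs, rep("SNV", 4))
      v$run_id <- i
      v$sample_id <- sample(samples, 1)
      v
    }))
  }

  callsets <- lapply(samples, function(sid) {
    tv <- true_list[[match(sid, samples)]]
    gl <- germline[[individuals[[sid]]]]
    leak <- if (!is.null(gl) && cfg$germline_leak_fraction > 0)
      gl[sample(nrow(gl), round(cfg$germline_leak_fraction * nrow(gl))), ,
         drop = FALSE] else NULL
    bl <- if (!is.null(blacklist))
      blacklist[bl_sample == sid, , drop = FALSE] else NULL
    sh <- if (length(shared_samples))
      shared[vapply(shared_samples, function(s) sid %in% s, logical(1)), ,
             drop = FALSE] else NULL
    cl <- if (!is.null(clustered))
      clustered[clustered$sample_id == sid,
                c("contig", "pos", "ref", "alt", "var_class"),
                drop = FALSE] else NULL
    contaminants <- rbind(leak, bl, sh, cl)
    per_caller <- lapply(CALLERS, function(cid) {
      sens <- cfg$caller_sensitivities[[cid]]
      hit <- if (!is.null(tv)) tv[stats::runif(nrow(tv)) <= sens,
                                  c("contig", "pos", "ref", "alt",
                                    "var_class"), drop = FALSE] else NULL
      n_fp <- stats::rpois(1, cfg$caller_fp_rates[[cid]] * L / 1e6)
      fp <- if (n_fp > 0) {
        # caller-private false positives: +7 offset keeps them off the
        # planted grid; disjoint per-caller pools keep them private
        ci <- match(cid, CALLERS)
        pool <- grid[seq_along(grid) %% length(CALLERS) == (ci - 1L)] + 7L
        if (n_fp > length(pool))
          stopf("false-positive rate exceeds the available positions")
        fpos <- sample(pool, n_fp)
        draw_variants(fpos, rep("SNV", n_fp))
      } else NULL
      out <- rbind(hit, contaminants, fp)
      if (is.null(out))
        out <- data.frame(contig = character(), pos = integer(),
                          ref = character(), alt = character(),
                          var_class = character(), stringsAsFactors = FALSE)
      out <- out[order(out$pos, out$ref, out$alt), , drop = FALSE]
      rownames(out) <- NULL
      out
    })
    names(per_caller) <- CALLERS
    per_caller
  })
  names(callsets) <- samples

  list(callsets = callsets,
       truth = list(true_variants = true_variants,
                    blacklist_variants = blacklist,
                    germline = germline,
                    shared_artifacts = shared,
                    clustered_artifacts = clustered,
                    sample_to_individual = individuals),
       samples = samples, groups = sample_groups(cfg))
}

#' Probe and region annotation for the synthetic methylome
#'
#' Lays `n_probes` probes every 100 bp on "chrS"; the first
#' `n_promoter_genes * probes_per_promoter` probes form gene promoters (and
#' gene bodies), every probe joins a 5,000 bp tiling bin, and every fifth
#' probe joins a CpG island.
#'
#' @param cfg a [synth_config()].
#' @return list with `probes` (probe_id, contig, start, end; 0-based
#'   half-open), `memberships` (probe_id, feature_class, region_id) and
#'   `gene_map` (region_id, gene, n_probes) for promoters.
#' @export
make_probe_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_probes
  probe_id <- sprintf("cg%06d", seq_len(n))
  start <- (seq_len(n) - 1L) * 100L
  probes <- data.frame(probe_id = probe_id, contig = "chrS", start = start,
                       end = start + 1L, stringsAsFactors = FALSE)
  genes <- gene_names(cfg)
  ppp <- cfg$probes_per_promoter
  npr <- cfg$n_promoter_genes * ppp
  prom_gene <- rep(genes[seq_len(cfg$n_promoter_genes)], each = ppp)
  prom_mem <- if (npr > 0) rbind(
    data.frame(probe_id = probe_id[seq_len(npr)], feature_class = "promoters",
               region_id = paste0("prom_", prom_gene),
               stringsAsFactors = FALSE),
    data.frame(probe_id = probe_id[seq_len(npr)], feature_class = "genes",
               region_id = paste0("body_", prom_gene),
               stringsAsFactors = FALSE)) else NULL
  mem <- rbind(
    prom_mem,
    data.frame(probe_id = probe_id, feature_class = "tiling",
               region_id = paste0("tile_", start %/% 5000L),
               stringsAsFactors = FALSE),
    data.frame(probe_id = probe_id[seq(1L, n, by = 5L)],
               feature_class = "cpg_islands",
               region_id = paste0("cgi_", (seq(1L, n, by = 5L) - 1L) %/% 50L),
               stringsAsFactors = FALSE))
  prom_genes <- genes[seq_len(cfg$n_promoter_genes)]
  gene_map <- data.frame(
    region_id = paste0("prom_", prom_genes, recycle0 = TRUE),
    gene = prom_genes, n_probes = rep(ppp, cfg$n_promoter_genes),
    stringsAsFactors = FALSE)
  list(probes = probes, memberships = mem, gene_map = gene_map)
}

#' Simulate the RNA-seq count layer
#'
#' Negative-binomial counts with per-sample library sizes drawn from
#' `lib_size_range`; planted DEGs multiply the HDM-arm mean by
#' 2^(+-deg_log2fc). Planted DEGs are chosen outside the promoter genes so
#' that (before coupling) no DEG is also a promoter-DMS gene.
#'
#' @param cfg a [synth_config()].
#' @return list with `counts` (genes x samples integer matrix),
#'   `gene_lengths`, `groups`, `lib_factors`, `base_mean` and `truth`
#'   (planted_degs data.frame gene/log2fc).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$nb_dispersion <= 0) stopf("'nb_dispersion' must be positive")
  set.seed(stream_seed(cfg$seed, 3L))
  genes <- gene_names(cfg)
  samples <- sample_names(cfg)
  groups <- sample_groups(cfg)
  mu <- 2^stats::runif(cfg$n_genes, 3, 11)          # baseline mean counts
  gene_lengths <- stats::setNames(
    sample(200:5000, cfg$n_genes, replace = TRUE), genes)
  lfc <- stats::setNames(numeric(cfg$n_genes), genes)
  if (cfg$deg_log2fc != 0 && (cfg$n_deg_up + cfg$n_deg_down) > 0) {
    eligible <- genes[(cfg$n_promoter_genes + 1L):cfg$n_genes]
    picked <- sample(eligible, cfg$n_deg_up + cfg$n_deg_down)
    lfc[picked[seq_len(cfg$n_deg_up)]] <- cfg$deg_log2fc
    if (cfg$n_deg_down > 0)
      lfc[picked[cfg$n_deg_up + seq_len(cfg$n_deg_down)]] <- -cfg$deg_log2fc
  }
  lib <- stats::runif(length(samples), cfg$lib_size_range[1],
                      cfg$lib_size_range[2])
  lib_factors <- stats::setNames(lib / mean(lib), samples)
  counts <- matrix(0L, cfg$n_genes, length(samples),
                   dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    arm_fc <- if (groups[j] == "HDM") 2^lfc else rep(1, cfg$n_genes)
    mu_j <- mu * arm_fc * lib_factors[j]
    counts[, j] <- stats::rnbinom(cfg$n_genes, mu = mu_j,
                                  size = 1 / cfg$nb_dispersion)
  }
  planted <- lfc[lfc != 0]
  list(counts = counts, gene_lengths = gene_lengths, groups = groups,
       lib_factors = lib_factors, base_mean = stats::setNames(mu, genes),
       truth = list(planted_degs = data.frame(
         gene = names(planted), log2fc = unname(planted),
         stringsAsFactors = FALSE)))
}

#' Simulate the methylation beta layer
#'
#' beta = inverse-logit(logit(group mean) + Normal(0, logit_noise_sd)) per
#' probe and sample; planted hyper/hypo probes shift the HDM-arm group mean
#' by +-delta_beta_planted on the beta scale. Planted DMS probes cover whole
#' promoters of genes disjoint from the planted DEGs, so every planted
#' promoter DMS maps to a gene in the expression layer.
#'
#' @param cfg a [synth_config()].
#' @param annotation optional [make_probe_annotation()] output.
#' @return list with `beta` (probes x samples), `annotation`, `groups` and
#'   `truth` (planted_dms probe/delta_beta, dms_genes).
#' @export
simulate_methylation <- function(cfg, annotation = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  ann <- annotation %||% make_probe_annotation(cfg)
  set.seed(stream_seed(cfg$seed, 4L))
  probes <- ann$probes$probe_id
  samples <- sample_names(cfg)
  groups <- sample_groups(cfg)
  delta <- cfg$delta_beta_planted
  if (delta >= 0.7)
    stopf("delta_beta_planted saturates the feasible baseline range")
  base <- stats::runif(cfg$n_probes, 0.15, 0.85)
  shift <- stats::setNames(numeric(cfg$n_probes), probes)
  ppp <- cfg$probes_per_promoter
  n_hyper_genes <- cfg$n_hyper / ppp
  n_hypo_genes <- cfg$n_hypo / ppp
  dms_genes <- character(0)
  if (n_hyper_genes + n_hypo_genes > 0) {
    gsel <- sample(cfg$n_promoter_genes, n_hyper_genes + n_hypo_genes)
    hyper_g <- gsel[seq_len(n_hyper_genes)]
    hypo_g <- if (n_hypo_genes > 0)
      gsel[n_hyper_genes + seq_len(n_hypo_genes)] else integer(0)
    probe_idx <- function(g) rep((g - 1L) * ppp, each = ppp) + seq_len(ppp)
    hyper_p <- if (length(hyper_g)) probe_idx(hyper_g) else integer(0)
    hypo_p <- if (length(hypo_g)) probe_idx(hypo_g) else integer(0)
    shift[hyper_p] <- delta
    shift[hypo_p] <- -delta
    base[hyper_p] <- stats::runif(length(hyper_p), 0.15, 0.85 - delta)
    base[hypo_p] <- stats::runif(length(hypo_p), 0.15 + delta, 0.85)
    dms_genes <- gene_names(cfg)[sort(c(hyper_g, hypo_g))]
  }
  beta <- matrix(0, cfg$n_probes, length(samples),
                 dimnames = list(probes, samples))
  for (j in seq_along(samples)) {
    mean_beta <- base + if (groups[j] == "HDM") shift else 0
    beta[, j] <- stats::plogis(stats::qlogis(mean_beta) +
                                 stats::rnorm(cfg$n_probes, 0,
                                              cfg$logit_noise_sd))
  }
  planted <- shift[shift != 0]
  list(beta = beta, annotation = ann, groups = groups,
       truth = list(planted_dms = data.frame(
         probe = names(planted), delta_beta = unname(planted),
         stringsAsFactors = FALSE),
         dms_genes = dms_genes))
}

#' Plant inversely coupled promoter-methylation/expression genes
#'
#' Coupled genes are drawn from promoter genes untouched by the planted
#' DEG/DMS sets, so the DEG-DMG intersection outside the coupled set stays
#' empty by construction. Each arm's samples carry a deterministic latent
#' factor t (equally spaced on \[-1, 1\]); a coupled gene's log2 expression
#' gains `+coupling_expr_sd * t` (plus its arm effect of
#' +-`deg_log2fc`) while its promoter probes' betas gain
#' `-coupling_beta_slope * t` (plus an arm effect of -+`delta_beta_planted`),
#' giving an exactly collinear inverse relation when `coupling_noise_sd = 0`.
#'
#' @param expr_sim output of [simulate_expression()].
#' @param meth_sim output of [simulate_methylation()].
#' @param cfg a [synth_config()].
#' @return list with updated `expr`, `meth` and `truth` (coupled_genes
#'   data.frame gene/class, latent factor, and the noiseless-scale
#'   `profiles`: per-gene expression log2 levels and promoter beta levels).
#' @export
simulate_coupled_genes <- function(expr_sim, meth_sim, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$coupling_noise_sd < 0) stopf("'coupling_noise_sd' must be >= 0")
  n_up <- cfg$n_coupled_hypo_up
  n_down <- cfg$n_coupled_hyper_down
  empty <- data.frame(gene = character(), class = character(),
                      stringsAsFactors = FALSE)
  if (n_up + n_down == 0)
    return(list(expr = expr_sim, meth = meth_sim,
                truth = list(coupled_genes = empty)))
  set.seed(stream_seed(cfg$seed, 5L))
  genes <- gene_names(cfg)
  prom_genes <- genes[seq_len(cfg$n_promoter_genes)]
  eligible <- setdiff(prom_genes, c(expr_sim$truth$planted_degs$gene,
                                    meth_sim$truth$dms_genes))
  if (length(eligible) < n_up + n_down)
    stopf("not enough eligible promoter genes for the coupled set")
  picked <- sample(eligible, n_up + n_down)
  coupled <- data.frame(gene = picked,
                        class = rep(c("hypo-up", "hyper-down"),
                                    c(n_up, n_down)),
                        stringsAsFactors = FALSE)
  samples <- sample_names(cfg)
  groups <- sample_groups(cfg)
  n <- cfg$n_samples_per_arm
  t_arm <- if (n == 1) 0 else seq(-1, 1, length.out = n)
  t_s <- stats::setNames(rep(t_arm, 2), samples)
  delta <- cfg$delta_beta_planted
  lfc <- cfg$deg_log2fc
  if (lfc < 1 || delta < 0.2)
    warnf("coupled effect sizes below the default calling thresholds")
  ppp <- cfg$probes_per_promoter
  expr_profiles <- matrix(0, nrow(coupled), length(samples),
                          dimnames = list(coupled$gene, samples))
  beta_profiles <- expr_profiles
  planted_deg <- numeric(nrow(coupled))
  planted_dms_probe <- character(0)
  planted_dms_delta <- numeric(0)
  for (i in seq_len(nrow(coupled))) {
    g <- coupled$gene[i]
    up <- coupled$class[i] == "hypo-up"
    base_log2 <- 9                              # ~512 baseline counts
    g_lfc <- if (up) lfc else -lfc
    expr_log2 <- base_log2 + g_lfc * (groups == "HDM") +
      cfg$coupling_expr_sd * t_s +
      stats::rnorm(length(samples), 0, cfg$coupling_noise_sd)
    expr_profiles[i, ] <- expr_log2
    counts <- round(2^expr_log2 * expr_sim$lib_factors[samples])
    expr_sim$counts[g, ] <- as.integer(counts)
    b_veh <- if (up) 0.60 else 0.30
    b_hdm <- if (up) 0.60 - delta else 0.30 + delta
    b_arm <- ifelse(groups == "HDM", b_hdm, b_veh)
    beta_level <- b_arm - cfg$coupling_beta_slope * t_s
    beta_profiles[i, ] <- beta_level
    gi <- match(g, genes)
    probe_rows <- (gi - 1L) * ppp + seq_len(ppp)
    for (pr in probe_rows) {
      val <- beta_level + stats::rnorm(length(samples), 0,
                                       cfg$coupling_noise_sd)
      meth_sim$beta[pr, ] <- pmin(pmax(val, 0.001), 0.999)
      planted_dms_probe <- c(planted_dms_probe,
                             rownames(meth_sim$beta)[pr])
      planted_dms_delta <- c(planted_dms_delta, b_hdm - b_veh)
    }
    planted_deg[i] <- g_lfc
  }
  expr_sim$truth$planted_degs <- rbind(
    expr_sim$truth$planted_degs,
    data.frame(gene = coupled$gene, log2fc = planted_deg,
               stringsAsFactors = FALSE))
  meth_sim$truth$planted_dms <- rbind(
    meth_sim$truth$planted_dms,
    data.frame(probe = planted_dms_probe, delta_beta = planted_dms_delta,
               stringsAsFactors = FALSE))
  meth_sim$truth$dms_genes <- sort(c(meth_sim$truth$dms_genes, coupled$gene))
  list(expr = expr_sim, meth = meth_sim,
       truth = list(coupled_genes = coupled, latent = t_s,
                    profiles = list(expr_log2 = expr_profiles,
                                    beta = beta_profiles)))
}

#' Run the full synthetic multi-omics benchmark generator
#'
#' Convenience wrapper: expression + methylation + coupled genes (and,
#' optionally, genome + variant call sets).
#'
#' @param cfg a [synth_config()].
#' @param with_variants also generate the genome and caller call sets
#'   (default FALSE; the integration benchmark does not need them).
#' @return list with `expr`, `meth`, `coupled` truth, and optionally
#'   `genome` + `variants`.
#' @export
simulate_benchmark <- function(cfg = synth_config(), with_variants = FALSE) {
  expr_sim <- simulate_expression(cfg)
  meth_sim <- simulate_methylation(cfg)
  cp <- simulate_coupled_genes(expr_sim, meth_sim, cfg)
  out <- list(expr = cp$expr, meth = cp$meth, coupled = cp$truth,
              groups = sample_groups(cfg), config = cfg)
  if (with_variants) {
    out$genome <- generate_reference(cfg$genome_length_bp, cfg$gc_fraction,
                                     cfg$seed)
    out$variants <- simulate_callsets(out$genome, cfg)
  }
  out
}
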