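# End-to-end orchestration: one configuration drives simulate -> consensus ->
# spectra and simulate -> expr/methyl -> score -> integrate, with files-on-
# disk TSV/VCF/FASTA handoff between stages so each stage is independently
# re-runnable, plus a JSON/markdown run report with per-stage attrition.

PIPELINE_STAGES <- c("simulate", "consensus", "spectra", "expr", "methyl",
                     "score", "integrate")

#' Default pipeline configuration
#'
#' Defaults are the field-standard thresholds for this workflow:
#' two-of-four caller consensus;
#' clustered filter > 3 mutations per 10 bp window; shared filter at 2
#' samples; DEGs at |log2FC| >= 1 and FDR < 0.05; DMSs at |delta-beta| >= 0.2
#' and p < 0.05; integration quadrant cutoffs 1 (expression) and 0.1
#' (methylation); inverse-correlation filter at r <= -0.6, p < 0.1.
#'
#' @param seed root seed for the synthetic mode.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 42L) {
  list(
    seed = seed,
    synthetic = TRUE,
    stages = PIPELINE_STAGES,
    thresholds = list(
      min_callers = 2L, window_bp = 10L, max_in_window = 3L,
      min_shared_samples = 2L, min_row_sum = 10, lfc = 1, fdr = 0.05,
      delta_beta = 0.2, dms_p = 0.05, expr_cut = 1, meth_cut = 0.1,
      r_cut = -0.6, cor_p = 0.1),
    callable_bases = NULL,   # defaults to the reference contig length
    synth = list(),          # overrides forwarded to synth_config()
    input = list()           # external input paths when synthetic = FALSE
  )
}

#' Read a pipeline configuration file
#'
#' YAML (.yml/.yaml) or JSON; keys override [default_pipeline_config()].
#'
#' @param path config file path.
#' @return merged configuration list.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_pipeline_config()
  for (k in names(raw)) {
    if (k %in% c("thresholds", "synth", "input") && is.list(raw[[k]])) {
      for (k2 in names(raw[[k]])) cfg[[k]][[k2]] <- raw[[k]][[k2]]
    } else cfg[[k]] <- raw[[k]]
  }
  cfg
}

#' Validate a pipeline configuration
#'
#' Never throws: returns a data.frame of findings with `level` ("error" for
#' fatal, "warning" otherwise) and `message`. Unknown keys, out-of-range
#' thresholds, missing inputs and stage-dependency problems are reported.
#'
#' @param config configuration list (see [default_pipeline_config()]).
#' @return data.frame with columns `level`, `message` (zero rows when clean).
#' @export
validate_config <- function(config) {
  findings <- list()
  add <- function(level, msg)
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, message = msg, stringsAsFactors = FALSE)
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  for (k in unknown) add("warning", sprintf("unknown key '%s'", k))
  th <- utils::modifyList(defaults$thresholds,
                          config$thresholds %||% list())
  unknown_th <- setdiff(names(config$thresholds %||% list()),
                        names(defaults$thresholds))
  for (k in unknown_th)
    add("warning", sprintf("unknown threshold key '%s'", k))
  for (k in c("fdr", "dms_p", "cor_p")) {
    v <- th[[k]]
    if (!is.numeric(v) || v <= 0 || v > 1)
      add("error", sprintf("threshold '%s' = %s outside (0, 1]", k,
                           format(v)))
  }
  if (th$min_callers < 1) add("error", "min_callers must be >= 1")
  if (th$window_bp < 1) add("error", "window_bp must be >= 1")
  if (th$min_shared_samples < 2)
    add("error", "min_shared_samples must be >= 2")
  if (th$delta_beta < 0 || th$delta_beta > 1)
    add("error", "delta_beta must lie in [0, 1]")
  stages <- config$stages %||% defaults$stages
  bad <- setdiff(stages, PIPELINE_STAGES)
  for (s in bad) add("error", sprintf("unknown stage '%s'", s))
  synthetic <- isTRUE(config$synthetic %||% TRUE)
  inp <- config$input %||% list()
  if (!synthetic && "consensus" %in% stages &&
      is.null(inp$callsets_dir) && !"simulate" %in% stages)
    add("error", "consensus stage needs callsets_dir or the simulate stage")
  if ("spectra" %in% stages && !"consensus" %in% stages &&
      is.null(inp$consensus_tsv))
    add("error",
        "spectra stage needs the consensus stage or a consensus_tsv input")
  if ("integrate" %in% stages &&
      !all(c("expr", "methyl") %in% stages) &&
      (is.null(inp$deg_tsv) || is.null(inp$region_meth_tsv)))
    add("error", "integrate stage needs the expr and methyl stages or inputs")
  if (!length(findings))
    return(data.frame(level = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, findings)
}

#' Run the pipeline
#'
#' Executes the enabled stages in dependency order, writes every stage's
#' outputs under `outdir` and returns (and writes) a run report with
#' per-stage record counts and the thresholds in effect. On stage failure the
#' partial outputs are preserved under a `failed/` marker directory.
#'
#' @param config configuration list or path to a YAML/JSON config.
#' @param outdir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return run report list, invisibly; also written to
#'   `outdir/report.json` and `outdir/report.md`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         outdir = "allergomics_run", quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  findings <- validate_config(config)
  if (any(findings$level == "error"))
    stopf("invalid configuration:\n%s",
          paste("-", findings$message[findings$level == "error"],
                collapse = "\n"))
  for (m in findings$message[findings$level == "warning"]) warnf("%s", m)
  defaults <- default_pipeline_config()
  th <- utils::modifyList(defaults$thresholds, config$thresholds %||% list())
  stages <- config$stages %||% defaults$stages
  seed <- config$seed %||% 42L
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  report <- list(package_version = as.character(
    utils::packageVersion("allergomics")),
    seed = seed, thresholds = th, stages = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    say("[%s] starting (thresholds: %s)", name,
        paste(names(th), unlist(th), sep = "=", collapse = " "))
    res <- tryCatch(fun(), error = function(e) {
      dir.create(file.path(outdir, "failed"), showWarnings = FALSE)
      writeLines(sprintf("stage '%s' failed: %s", name,
                         conditionMessage(e)),
                 file.path(outdir, "failed", paste0(name, ".txt")))
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    report$stages[[name]] <<- res
    say("[%s] done", name)
  }

  run_stage("simulate", function() {
    scfg <- do.call(synth_config, utils::modifyList(
      list(seed = seed), config$synth %||% list()))
    need_variants <- any(c("consensus", "spectra") %in% stages)
    bench <- simulate_benchmark(scfg, with_variants = need_variants)
    state$bench <- bench
    state$scfg <- scfg
    if (need_variants) {
      write_genome_fasta(bench$genome, file.path(outdir, "reference.fasta"))
      vdir <- file.path(outdir, "vcf")
      dir.create(vdir, showWarnings = FALSE)
      clen <- stats::setNames(nchar(bench$genome), names(bench$genome))
      for (sid in names(bench$variants$callsets))
        for (cid in names(bench$variants$callsets[[sid]]))
          write_vcf(bench$variants$callsets[[sid]][[cid]],
                    file.path(vdir, sprintf("%s.%s.vcf", sid, cid)), clen)
      bl <- bench$variants$truth$blacklist_variants
      if (!is.null(bl))
        write_vcf(bl, file.path(outdir, "blacklist.vcf"), clen)
      gdir <- file.path(outdir, "germline")
      dir.create(gdir, showWarnings = FALSE)
      for (ind in names(bench$variants$truth$germline))
        write_vcf(bench$variants$truth$germline[[ind]],
                  file.path(gdir, paste0(ind, ".vcf")), clen)
    }
    write_tsv_matrix(bench$expr$counts, file.path(outdir, "counts.tsv"),
                     "gene")
    write_tsv(data.frame(gene = names(bench$expr$gene_lengths),
                         length = unname(bench$expr$gene_lengths)),
              file.path(outdir, "gene_lengths.tsv"))
    write_tsv(data.frame(sample_id = names(bench$groups),
                         group = unname(bench$groups)),
              file.path(outdir, "samples.tsv"))
    write_tsv_matrix(bench$meth$beta, file.path(outdir, "beta.tsv"), "probe")
    ann <- bench$meth$annotation
    write_tsv(ann$probes, file.path(outdir, "probes.bed.tsv"))
    write_tsv(ann$memberships, file.path(outdir, "memberships.tsv"))
    write_tsv(ann$gene_map, file.path(outdir, "gene_map.tsv"))
    degs <- bench$expr$truth$planted_degs
    sets <- list(planted_up = degs$gene[degs$log2fc > 0],
                 planted_down = degs$gene[degs$log2fc < 0])
    sets <- sets[vapply(sets, length, integer(1)) > 0]
    if (length(sets)) write_gmt(sets, file.path(outdir, "modules.gmt"))
    truth <- list(
      planted_degs = degs,
      planted_dms = bench$meth$truth$planted_dms,
      coupled_genes = bench$coupled$coupled_genes,
      n_true_variants = if (need_variants)
        nrow(bench$variants$truth$true_variants) else 0L)
    jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                         dataframe = "columns", auto_unbox = TRUE)
    list(n_genes = nrow(bench$expr$counts),
         n_probes = nrow(bench$meth$beta),
         n_samples = length(bench$groups),
         n_true_variants = truth$n_true_variants)
  })

  run_stage("consensus", function() {
    bench <- state$bench
    callsets <- bench$variants$callsets
    cs <- consensus_calls(callsets, min_callers = th$min_callers)
    n_in <- nrow(cs)
    cs <- filter_blacklist(cs, bench$variants$truth$blacklist_variants)
    cs <- subtract_germline(cs, bench$variants$truth$germline,
                            bench$variants$truth$sample_to_individual)
    cs <- filter_shared(cs, min_samples = th$min_shared_samples)
    cs <- filter_clustered(cs, window_bp = th$window_bp,
                           max_in_window = th$max_in_window)
    write_tsv(cs, file.path(outdir, "consensus.tsv"))
    retained <- consensus_retained(cs)
    clen <- stats::setNames(nchar(bench$genome), names(bench$genome))
    write_vcf(retained, file.path(outdir, "consensus_retained.vcf"), clen)
    state$consensus <- cs
    as.list(consensus_summary(cs))
  })

  run_stage("spectra", function() {
    bench <- state$bench
    retained <- consensus_retained(state$consensus)
    callable <- config$callable_bases %||% nchar(bench$genome[[1]])
    per_sample <- split(retained, retained$sample_id)
    for (schema in c("SBS96", "DBS78", "ID83")) {
      profs <- lapply(per_sample, build_profile, genome = bench$genome,
                      schema = schema)
      m <- vapply(profs, as.numeric, numeric(length(profs[[1]])))
      rownames(m) <- schema_channels(schema)
      write_tsv_matrix(m, file.path(outdir,
                                    sprintf("profile_%s.tsv",
                                            tolower(schema))), "channel")
      if (schema == "SBS96") {
        sims <- outer(seq_along(profs), seq_along(profs),
                      Vectorize(function(i, j)
                        cosine_similarity(profs[[i]], profs[[j]])))
        dimnames(sims) <- list(names(profs), names(profs))
        write_tsv_matrix(sims, file.path(outdir, "cosine_sbs96.tsv"),
                         "sample")
      }
    }
    bt <- burden_table(retained, callable, groups = bench$groups)
    write_tsv(bt$table, file.path(outdir, "burden.tsv"))
    list(n_retained = nrow(retained), callable_bases = callable,
         burden_welch_p = bt$test$p_value)
  })

  run_stage("expr", function() {
    bench <- state$bench
    counts <- filter_low_counts(bench$expr$counts, th$min_row_sum)
    deg <- call_degs(de_test(counts, bench$groups, a = "HDM"),
                     lfc_threshold = th$lfc, fdr_threshold = th$fdr)
    write_tsv(deg, file.path(outdir, "deg_table.tsv"))
    tpm_m <- tpm(counts, bench$expr$gene_lengths[rownames(counts)])
    write_tsv_matrix(log2_tpm_plus1(tpm_m),
                     file.path(outdir, "log2_tpm_plus1.tsv"), "gene")
    cpm <- tmm_log2_cpm(counts)
    write_tsv_matrix(cpm, file.path(outdir, "tmm_log2_cpm.tsv"), "gene")
    state$deg <- deg
    state$cpm <- cpm
    list(n_genes_in = nrow(bench$expr$counts),
         n_genes_tested = nrow(deg),
         n_genes_filtered = nrow(bench$expr$counts) - nrow(deg),
         n_deg = sum(deg$is_deg),
         n_up = sum(deg$is_deg & deg$direction == "up"),
         n_down = sum(deg$is_deg & deg$direction == "down"))
  })

  run_stage("methyl", function() {
    bench <- state$bench
    beta <- bench$meth$beta
    ann <- bench$meth$annotation
    dms <- dms_test(beta, bench$groups, a = "HDM",
                    delta_threshold = th$delta_beta,
                    p_threshold = th$dms_p)
    write_tsv(dms, file.path(outdir, "dms_sites.tsv"))
    counts_by_class <- list(
      sites = as.list(count_dms_directions(dms)))
    for (fc in FEATURE_CLASSES) {
      rb <- aggregate_regions(beta, ann$memberships, fc)
      rd <- dms_test(rb, bench$groups, a = "HDM",
                     delta_threshold = th$delta_beta, p_threshold = th$dms_p)
      counts_by_class[[fc]] <- as.list(count_dms_directions(rd))
      if (fc == "promoters") {
        rq <- region_log2_quotient(rb, bench$groups, a = "HDM")
        write_tsv(rq, file.path(outdir, "promoter_methylation.tsv"))
        state$promoter_beta <- rb
        state$promoter_quot <- rq
      }
    }
    jsonlite::write_json(counts_by_class,
                         file.path(outdir, "dms_direction_counts.json"),
                         auto_unbox = TRUE)
    state$dms <- dms
    c(list(n_probes = nrow(beta)), counts_by_class["sites"])
  })

  run_stage("score", function() {
    bench <- state$bench
    gmt_path <- file.path(outdir, "modules.gmt")
    sets <- if (!is.null(config$input$gmt)) read_gmt(config$input$gmt)
    else if (file.exists(gmt_path)) read_gmt(gmt_path) else NULL
    if (is.null(sets)) return(list(skipped = "no gene sets available"))
    z <- gene_zscores(state$cpm)
    ms <- module_score_table(z, sets)
    write_tsv_matrix(ms, file.path(outdir, "module_scores.tsv"), "set")
    cmp <- compare_groups_wilcoxon_table(ms, bench$groups)
    write_tsv(cmp, file.path(outdir, "module_comparisons.tsv"))
    list(n_sets = nrow(ms), n_samples = ncol(ms))
  })

  run_stage("integrate", function() {
    bench <- state$bench
    gene_map <- bench$meth$annotation$gene_map
    aligned <- align_layers(state$cpm, state$promoter_beta, gene_map)
    rq <- state$promoter_quot
    rq$region <- gene_map$gene[match(rq$region, gene_map$region_id)]
    hdm <- names(bench$groups)[bench$groups == "HDM"]
    rec <- integrate_omics(aligned, state$deg, rq, cor_samples = hdm,
                           delta_threshold = th$delta_beta,
                           p_threshold = th$dms_p, expr_cut = th$expr_cut,
                           meth_cut = th$meth_cut, r_cut = th$r_cut,
                           p_cut = th$cor_p)
    write_tsv(rec, file.path(outdir, "integration.tsv"))
    venn <- dmg_deg_venn(rec$gene[rec$is_dmg], rec$gene[rec$is_deg])
    jsonlite::write_json(as.list(venn), file.path(outdir, "venn.json"),
                         auto_unbox = TRUE)
    pass <- rec[rec$passes_epigenetic_filter, , drop = FALSE]
    write_tsv(pass, file.path(outdir, "epigenetically_controlled.tsv"))
    list(n_genes_aligned = nrow(rec),
         n_pass = nrow(pass),
         n_activated = sum(pass$filter_class == "activated"),
         n_repressed = sum(pass$filter_class == "repressed"),
         venn = as.list(venn))
  })

  cfg_json <- file.path(outdir, "config.json")
  jsonlite::write_json(config, cfg_json, auto_unbox = TRUE, null = "null")
  report$config_md5 <- unname(tools::md5sum(cfg_json))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  md <- c("# allergomics run report", "",
          sprintf("- seed: %s", seed),
          sprintf("- stages: %s", paste(stages, collapse = ", ")), "")
  for (s in names(report$stages)) {
    md <- c(md, sprintf("## %s", s),
            vapply(names(report$stages[[s]]), function(k)
              sprintf("- %s: %s", k,
                      paste(format(unlist(report$stages[[s]][[k]])),
                            collapse = "/")), character(1)), "")
  }
  writeLines(md, file.path(outdir, "report.md"))
  invisible(report)
}
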