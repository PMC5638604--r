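# Run manifest: configuration hash, seed, package version and the stages
# executed so far, written as JSON next to the stage outputs.
write_manifest <- function(dir, config, stage) {
  path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(path))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else list(package = "paradapt",
            version = as.character(utils::packageVersion("paradapt")),
            stages = character())
  cfg_plain <- unclass(config)
  manifest$config <- cfg_plain
  manifest$config_hash <- unname(tools::md5sum(
    textConnection_md5(cfg_plain)))
  manifest$seed <- config$seed
  manifest$stages <- union(manifest$stages, stage)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

textConnection_md5 <- function(x) {
  f <- tempfile()
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  f
}

require_stage_file <- function(dir, file, produced_by) {
  path <- file.path(dir, file)
  if (!file.exists(path))
    stop(sprintf("missing %s; run the '%s' stage first", file, produced_by))
  path
}

#' Run pipeline stages against an output directory
#'
#' Thin orchestration over the package's functions: each stage reads the
#' files earlier stages wrote under `out_dir`, runs one analysis step, and
#' writes its outputs as TSV/BED plus an updated `manifest.json`. Stages:
#'
#' * `simulate` — [simulate_popgen_dataset()] (genome, GFF3, outgroup, sync,
#'   truth).
#' * `popgen` — site filtering, per-SNP F_ST, windowed pi/F_ST and tail
#'   flags (`snps.tsv`, `windows.tsv`, `windows.bed`).
#' * `outliers` — mid-p tests, per-arm q-values (arms = scaffolds here),
#'   outlier flags and outgroup polarization (`snps_tested.tsv`,
#'   `arm_summary.tsv`).
#' * `annotate` — gene assignment and codon-aware effect classes
#'   (`snp_effects.tsv`).
#' * `mk` — [simulate_mk_dataset()] then per-gene MK tests
#'   (`mk_results.tsv`).
#' * `expression` — [simulate_expression_dataset()] then the top-N overlap
#'   and direction-split statistics (`expr_overlap.tsv`).
#'
#' @param stages character vector of stages, run in the given order.
#' @param out_dir output directory (created if needed).
#' @param sim_cfg a [sim_config()] for the generator stages.
#' @param cfg an [analysis_config()] for the analysis stages.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(stages, out_dir,
                         sim_cfg = sim_config(),
                         cfg = analysis_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (stage in stages) {
    switch(stage,
      simulate = simulate_popgen_dataset(sim_cfg, dir = out_dir),
      popgen = stage_popgen(out_dir, cfg),
      outliers = stage_outliers(out_dir, cfg),
      annotate = stage_annotate(out_dir, cfg),
      mk = stage_mk(out_dir, sim_cfg),
      expression = stage_expression(out_dir, sim_cfg, cfg),
      stop("unknown stage: ", stage))
    write_manifest(out_dir, sim_cfg, stage)
    message("paradapt: stage '", stage, "' complete")
  }
  invisible(out_dir)
}

stage_popgen <- function(dir, cfg) {
  sync <- read_sync(require_stage_file(dir, "counts.sync", "simulate"))
  genome <- read_genome_fasta(
    require_stage_file(dir, "genome.fasta", "simulate"))
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  cl <- classify_sites(sync, cfg)
  message(sprintf(
    "paradapt: %d sites: %s",
    length(cl$status),
    paste(names(table(cl$status)), table(cl$status),
          sep = "=", collapse = ", ")))
  win <- window_stats(sync, lens, cfg, classified = cl)
  tails <- window_tails(win, cfg$window_tail_fractions)
  win <- cbind(win, tails$flags)
  write_tsv(cl$snps, file.path(dir, "snps.tsv"))
  write_tsv(win, file.path(dir, "windows.tsv"))
  # BED: 0-based half-open window spans
  bed <- data.frame(win$scaffold, win$start - 1L, win$end,
                    sprintf("fst=%.4g", win$fst))
  utils::write.table(bed, file.path(dir, "windows.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

stage_outliers <- function(dir, cfg) {
  snps <- read_tsv(require_stage_file(dir, "snps.tsv", "popgen"))
  res <- midp_test_vec(snps$maj1, snps$min1, snps$maj2, snps$min2)
  snps$midp <- res
  arm <- snps$scaffold  # pseudo-arms: one per scaffold
  qv <- qvalues_per_arm(snps$midp, arm)
  snps$q <- qv$q
  snps$outlier <- flag_outliers(snps$q, snps$fst, cfg)
  outg <- read_genome_fasta(
    require_stage_file(dir, "outgroup.fasta", "simulate"))
  ob <- vapply(seq_len(nrow(snps)), function(i)
    as.character(Biostrings::subseq(outg[[snps$scaffold[i]]],
                                    snps$pos[i], snps$pos[i])),
    character(1))
  pol <- polarize_ancestral(snps$major, snps$minor, ob)
  snps$ancestral <- pol$ancestral
  snps$derived <- pol$derived
  write_tsv(snps, file.path(dir, "snps_tested.tsv"))
  write_tsv(qv$arms, file.path(dir, "arm_summary.tsv"))
  message(sprintf("paradapt: %d of %d SNPs flagged as outliers",
                  sum(snps$outlier), nrow(snps)))
  invisible(dir)
}

stage_annotate <- function(dir, cfg) {
  snps <- read_tsv(require_stage_file(dir, "snps_tested.tsv", "outliers"))
  genome <- read_genome_fasta(
    require_stage_file(dir, "genome.fasta", "simulate"))
  models <- read_gff3(require_stage_file(dir, "genes.gff3", "simulate"),
                      genome)
  eff <- annotate_snps(snps, models, genome, cfg)
  eff <- cbind(snps[eff$snp_idx, c("scaffold", "pos", "major", "minor",
                                   "fst", "q", "outlier")], eff)
  write_tsv(eff, file.path(dir, "snp_effects.tsv"))
  invisible(dir)
}

stage_mk <- function(dir, sim_cfg) {
  sim <- simulate_mk_dataset(sim_cfg, dir = dir)
  cn <- sim$counts
  cn$testable <- mk_testable(cn$Dn, cn$Ds, cn$Pn, cn$Ps)
  stats <- lapply(seq_len(nrow(cn)), function(i)
    if (cn$testable[i]) mk_test(cn$Dn[i], cn$Ds[i], cn$Pn[i], cn$Ps[i])
    else list(fisher_p = NA_real_, alpha = NA_real_, dos = NA_real_))
  cn$fisher_p <- vapply(stats, `[[`, numeric(1), "fisher_p")
  cn$alpha <- vapply(stats, `[[`, numeric(1), "alpha")
  cn$dos <- vapply(stats, `[[`, numeric(1), "dos")
  cn$adaptive <- call_adaptive(cn$fisher_p, cn$alpha, cn$dos)
  write_tsv(cn, file.path(dir, "mk_results.tsv"))
  message(sprintf("paradapt: %d of %d testable genes called adaptive",
                  sum(cn$adaptive), sum(cn$testable)))
  invisible(dir)
}

stage_expression <- function(dir, sim_cfg, cfg) {
  sim <- simulate_expression_dataset(sim_cfg, dir = dir)
  expr <- expressed_orthologs(sim$fpkm_a, sim$fpkm_b, sim$ortholog_map)
  lfc_a <- stats::setNames(log2_fold_change(expr$a_pop1, expr$a_pop2),
                           expr$gene_a)
  lfc_b <- stats::setNames(log2_fold_change(expr$b_pop1, expr$b_pop2),
                           expr$gene_a)
  N <- min(cfg$top_n_expression, floor(length(lfc_a) / 2))
  ov <- topn_overlap(lfc_a, lfc_b, N)
  ds <- direction_split_correlation(lfc_a, lfc_b)
  out <- data.frame(universe = ov$N, top_n = N, overlap = ov$k,
                    expected = ov$expected, fold = ov$fold, p = ov$p,
                    r_same = ds$r_same, r_opp = ds$r_opp,
                    n_same = ds$n_same, n_opp = ds$n_opp)
  write_tsv(out, file.path(dir, "expr_overlap.tsv"))
  invisible(dir)
}
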