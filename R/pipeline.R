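#' Build a pipeline configuration
#'
#' Collects stage toggles, filter thresholds, the simulation configuration
#' and the alignment scheme in one plain list that round-trips losslessly
#' through YAML.
#'
#' @param seed Base seed; each stochastic stage derives its own stream from
#'   it.
#' @param sim Named list of [sim_config()] overrides.
#' @param thresholds Named list of [filter_thresholds()] overrides.
#' @param scheme Named list of [scoring_scheme()] overrides.
#' @param stages Character vector of stages to run (default: all, in
#'   pipeline order).
#' @param discovery Named list of [discover_candidates()] overrides
#'   (max_gap, max_precursor_length, min_loop, n_shuffles, min_signature).
#' @param targets Named list with score_min, energy_max, n_scrambles,
#'   mirna_fraction.
#' @param enrichment Named list with n_pathways, pathway_size.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = list(), thresholds = list(),
                            scheme = list(), stages = NULL,
                            discovery = list(), targets = list(),
                            enrichment = list()) {
  all_stages <- c("simulate", "discover", "filter", "quantify", "normalize",
                  "gate", "de", "survival", "targets", "enrich")
  if (is.null(stages)) stages <- all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  cfg <- list(
    seed = as.integer(seed),
    stages = stages,
    sim = utils::modifyList(list(seed = as.integer(seed)), sim),
    thresholds = thresholds,
    scheme = scheme,
    discovery = utils::modifyList(
      list(max_gap = 30L, max_precursor_length = 120L, min_loop = 3L,
           n_shuffles = 99L, min_signature = 0.6), discovery),
    targets = utils::modifyList(
      list(score_min = 140, energy_max = -20, n_scrambles = 5L,
           mirna_fraction = 0.10), targets),
    enrichment = utils::modifyList(
      list(n_pathways = 20L, pathway_size = 25L), enrichment)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config` (for the reader).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full discovery and characterization pipeline
#'
#' Executes, in order, the enabled stages: simulate (synthetic genome,
#' reads, cohort, UTRs, pathways), discover (hairpin candidates), filter
#' (the cascade plus Knm id assignment), quantify/normalize/gate, de
#' (paired differential expression), survival (tertile weighted log-rank
#' per DE locus), targets (seed-weighted alignment plus scrambled null) and
#' enrich.  Every applied threshold is logged to `run.log`; identical
#' configuration and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the per-stage results.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  logmsg <- function(...) writeLines(paste0(...), log_con)
  stage_on <- function(s) s %in% config$stages

  th <- do.call(filter_thresholds, config$thresholds)
  scheme <- do.call(scoring_scheme, config$scheme)
  sim_cfg <- do.call(sim_config, config$sim)
  logmsg("seed: ", config$seed)
  logmsg("thresholds: ",
         paste(names(unclass(th)), unlist(th), sep = "=", collapse = " "))
  logmsg("scheme: gap_open=", scheme$gap_open, " gap_extend=",
         scheme$gap_extend, " seed_multiplier=", scheme$seed_multiplier)
  logmsg("targets: score_min=", config$targets$score_min, " energy_max=",
         config$targets$energy_max, " n_scrambles=",
         config$targets$n_scrambles, " mirna_fraction=",
         config$targets$mirna_fraction)
  res <- list()

  if (stage_on("simulate")) {
    logmsg("stage simulate: n_true_hairpins=", sim_cfg$n_true_hairpins,
           " n_decoy_loci=", sim_cfg$n_decoy_loci, " n_pairs=",
           sim_cfg$n_pairs)
    gen <- generate_genome(sim_cfg)
    reads <- simulate_reads(gen$genome, gen$truth, sim_cfg)
    cohort <- simulate_cohort(gen$truth, sim_cfg)
    res$truth <- gen$truth
    res$genome <- gen$genome
    res$reads <- reads
    res$cohort <- cohort
    write_fasta(res$genome, file.path(outdir, "genome.fa"))
    write_reads(reads, file.path(outdir, "reads.tsv"))
    write_tsv_matrix(cohort$counts, file.path(outdir, "cohort_counts.tsv"),
                     "locus_id")
    write.table(cohort$annotations, file.path(outdir, "annotations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    hp <- gen$truth$hairpins
    if (nrow(hp)) {
      write_bed(data.frame(chrom = hp$chrom, start = hp$start, end = hp$end,
                           name = hp$id, score = 0, strand = hp$strand),
                file.path(outdir, "truth_hairpins.bed"))
    }
    dc <- gen$truth$decoys
    if (nrow(dc)) {
      write_bed(data.frame(chrom = dc$chrom, start = dc$start, end = dc$end,
                           name = paste(dc$id, dc$class, sep = "|"),
                           score = 0, strand = dc$strand),
                file.path(outdir, "decoys.bed"))
    }
  }

  if (stage_on("discover")) {
    d <- config$discovery
    logmsg("stage discover: max_gap=", d$max_gap, " max_precursor_length=",
           d$max_precursor_length, " min_loop=", d$min_loop,
           " n_shuffles=", d$n_shuffles, " min_signature=", d$min_signature)
    res$candidates <- discover_candidates(
      res$reads, res$genome, max_gap = d$max_gap,
      max_precursor_length = d$max_precursor_length, min_loop = d$min_loop,
      n_shuffles = d$n_shuffles, min_signature = d$min_signature,
      seed = config$seed + 10L)
    logmsg("discovered ", nrow(res$candidates), " candidate(s)")
    write.table(res$candidates, file.path(outdir, "candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (stage_on("filter")) {
    logmsg("stage filter")
    fc <- apply_filter_cascade(res$candidates, res$truth$decoys,
                               known_mirnas = character(0), thresholds = th)
    res$filtered <- assign_knm_ids(fc$candidates)
    res$filter_report <- fc$report
    logmsg("retained ", nrow(res$filtered), " candidate(s) after cascade")
    write.table(fc$report$per_step, file.path(outdir, "filter_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(fc$report$rejections,
                file.path(outdir, "filter_rejections.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(res$filtered)) {
      write_fasta(setNames(res$filtered$mature_seq, res$filtered$knm_id),
                  file.path(outdir, "retained_mature.fa"))
      write_bed(data.frame(chrom = res$filtered$chrom,
                           start = res$filtered$start,
                           end = res$filtered$end,
                           name = res$filtered$knm_id, score = 0,
                           strand = res$filtered$strand),
                file.path(outdir, "retained.bed"))
    }
  }

  if (stage_on("quantify")) {
    logmsg("stage quantify")
    # cohort counts keyed by truth locus ids; map retained candidates to the
    # truth locus they overlap so downstream stages use Knm ids
    map <- .match_candidates_to_truth(res$filtered, res$truth$hairpins)
    keep <- !is.na(map)
    res$filtered <- res$filtered[keep, , drop = FALSE]
    map <- map[keep]
    counts <- res$cohort$counts[map, , drop = FALSE]
    rownames(counts) <- res$filtered$knm_id
    res$counts <- expression_matrix(counts, "raw_counts")
    write_tsv_matrix(counts, file.path(outdir, "counts.tsv"), "knm_id")
  }

  if (stage_on("normalize")) {
    logmsg("stage normalize: TMM trim_m=0.3 trim_a=0.05")
    res$tmm <- tmm_factors(res$counts)
    res$normalized <- tmm_normalize(res$counts, res$tmm)
    write.table(data.frame(sample = names(res$tmm$factors),
                           factor = res$tmm$factors),
                file.path(outdir, "tmm_factors.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_tsv_matrix(res$normalized$values,
                     file.path(outdir, "normalized.tsv"), "knm_id")
  }

  if (stage_on("gate")) {
    logmsg("stage gate: sum_reads>=", th$min_total_reads,
           " then TMM>", th$tmm_expression_min, " in 10% of samples")
    g1 <- expression_gates(res$counts, "sum_reads",
                           min_total_reads = th$min_total_reads)
    g2 <- expression_gates(res$normalized, "fraction_of_samples",
                           expression_min = th$tmm_expression_min)
    res$expressed <- intersect(g1, g2)
    logmsg(length(res$expressed), " locus/loci pass the expression gates")
    writeLines(res$expressed, file.path(outdir, "expressed_loci.txt"))
  }

  if (stage_on("de")) {
    logmsg("stage de: paired t-test, BH correction")
    keep <- rownames(res$normalized$values) %in% res$expressed
    nm <- expression_matrix(res$normalized$values[keep, , drop = FALSE],
                            "tmm_normalized")
    res$de <- paired_de(nm, res$cohort$annotations)
    res$de_significant <- res$de[!is.na(res$de$bh_p) & res$de$bh_p < 0.05, ]
    logmsg(nrow(res$de_significant), " of ", nrow(res$de),
           " loci differentially expressed (BH p < 0.05)")
    write.table(res$de, file.path(outdir, "de_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (nrow(nm$values) >= 2) {
      res$clustering <- tryCatch(hier_cluster(nm$values),
                                 error = function(e) NULL)
    }
  }

  if (stage_on("survival")) {
    logmsg("stage survival: high vs low tertile, GBW + log-rank")
    ann <- res$cohort$annotations
    tum <- ann[ann$condition == "tumour", , drop = FALSE]
    expr_mat <- res$normalized$values[, tum$sample, drop = FALSE]
    ids <- res$de_significant$locus_id
    rows <- lapply(ids, function(id) {
      e <- setNames(expr_mat[id, ], tum$pair)
      s <- tryCatch(
        survival_association(e, setNames(tum$time_days, tum$pair),
                             setNames(tum$event, tum$pair)),
        error = function(err) NULL)
      if (is.null(s)) return(NULL)
      data.frame(locus_id = id, gbw_chisq = s$gbw$statistic,
                 gbw_p = s$gbw$p, logrank_p = s$log_rank$p)
    })
    res$survival <- do.call(rbind, rows)
    if (!is.null(res$survival)) {
      write.table(res$survival, file.path(outdir, "survival.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if (stage_on("targets")) {
    tg <- config$targets
    logmsg("stage targets: score>=", tg$score_min, " energy<=",
           tg$energy_max, " scrambles=", tg$n_scrambles)
    mir <- setNames(res$filtered$mature_seq, res$filtered$knm_id)
    mir <- mir[names(mir) %in% res$de_significant$locus_id]
    planted <- plant_target_sites(mir, sim_cfg)
    res$utrs <- planted$utrs
    res$target_truth <- planted$target_truth
    write_fasta(planted$utrs, file.path(outdir, "utrs.fa"))
    res$predictions <- scramble_null_filter(
      mir, planted$utrs, scheme, n_scrambles = tg$n_scrambles,
      seed = config$seed + 23L, score_min = tg$score_min,
      energy_max = tg$energy_max)
    res$target_genes <- aggregate_targets(res$predictions,
                                          n_mirnas = length(mir),
                                          mirna_fraction = tg$mirna_fraction)
    logmsg(nrow(res$predictions), " prediction(s); ",
           length(res$target_genes), " aggregated target gene(s)")
    write.table(res$predictions, file.path(outdir, "predictions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(res$target_genes, file.path(outdir, "target_genes.txt"))
  }

  if (stage_on("enrich")) {
    en <- config$enrichment
    logmsg("stage enrich: hypergeometric, BH <= 0.05")
    pw <- simulate_pathways(names(res$utrs), res$target_truth$gene_id,
                            n_pathways = en$n_pathways,
                            pathway_size = en$pathway_size,
                            seed = config$seed + 31L)
    write_gmt(pw, file.path(outdir, "pathways.gmt"))
    if (length(res$target_genes)) {
      res$enrichment <- enrich_pathways(res$target_genes, pw,
                                        universe = names(res$utrs))
      write.table(res$enrichment, file.path(outdir, "enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      logmsg(sum(res$enrichment$significant), " pathway(s) enriched at ",
             "BH p <= 0.05")
    }
  }

  logmsg("done")
  invisible(res)
}

# match retained candidate loci to overlapping truth hairpin intervals
.match_candidates_to_truth <- function(candidates, hairpins) {
  if (nrow(candidates) == 0) return(integer(0))
  vapply(seq_len(nrow(candidates)), function(i) {
    hit <- which(hairpins$chrom == candidates$chrom[i] &
                   hairpins$start < candidates$end[i] &
                   hairpins$end > candidates$start[i])
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
}
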