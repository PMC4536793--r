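#' Pipeline configuration
#'
#' Bundles the input paths, stage parameters, seed and output directory
#' consumed by [run_stage()].  Every default is echoed into the run
#' manifest so that unstated analysis thresholds are always auditable in
#' the output.
#'
#' @param outdir output directory (created if absent).
#' @param seed integer seed used by stochastic stages and the simulator.
#' @param paths named list of input paths; the stages use the entries
#'   `catalog` (TSV feature table), `chrom_sizes`, `ripchip_matrix`,
#'   `expression_matrix`, `reads` (named character vector of BED files,
#'   names `antibody.condition.replicate`), `ct_table`, `gene_lists`
#'   (named character vector of gene-list files) and `universe`.
#' @param params named list overriding stage parameters: `z_threshold`
#'   (2.5), `rule_k` (2), `fdr_threshold` (0.005), `n_permutations` (100),
#'   `loess_span` (0.3), `enrichment_factor` (2), `reduction_factor` (2),
#'   `synth` (a [synth_config()] for the simulate stage).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1, paths = list(), params = list()) {
  defaults <- list(z_threshold = 2.5, rule_k = 2, fdr_threshold = 0.005,
                   n_permutations = 100, loess_span = 0.3,
                   enrichment_factor = 2, reduction_factor = 2,
                   synth = NULL)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0)
    stop_config("unknown parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(params)] <- params
  structure(list(outdir = outdir, seed = as.integer(seed), paths = paths,
                 params = defaults),
            class = "pipeline_config")
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("hetseq_config_error",
                                             "error", "condition")))
}

require_paths <- function(config, keys) {
  for (k in keys) {
    p <- config$paths[[k]]
    if (is.null(p))
      stop_config("config is missing required input path '", k, "'")
    if (!all(file.exists(p)))
      stop_config("input file(s) for '", k, "' not found: ",
                  paste(p[!file.exists(p)], collapse = ", "))
  }
  invisible(TRUE)
}

write_manifest <- function(config, stage, outputs) {
  params <- config$params[!vapply(config$params, is.null, logical(1))]
  if (!is.null(params$synth)) params$synth <- unclass(params$synth)
  manifest <- list(
    stage = stage,
    seed = config$seed,
    params = params,
    outputs = basename(outputs),
    package_version = as.character(utils::packageVersion("hetseq")))
  path <- file.path(config$outdir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run one pipeline stage
#'
#' Dispatches to a stage of the analysis, reading the inputs named in the
#' configuration and writing result tables plus a run manifest (config
#' echo, seed, package version) into the output directory.  All inputs are
#' validated before anything is written, so a failed stage leaves no
#' partial outputs.  Configuration problems raise conditions of class
#' `hetseq_config_error`; stage failures propagate as ordinary errors.
#'
#' @param stage one of `"simulate"`, `"ripchip"`, `"diffexpr"`,
#'   `"overlap"`, `"chip"`, `"qpcr"`.
#' @param config a [pipeline_config()].
#' @return invisibly, a character vector of the files written (manifest
#'   included).
#' @export
run_stage <- function(stage = c("simulate", "ripchip", "diffexpr",
                                "overlap", "chip", "qpcr"),
                      config) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  outputs <- switch(stage,
    simulate = {
      sc <- p$synth %||% synth_config(seed = config$seed)
      catalog <- make_genome(sc)
      truth <- plant_truth(sc, catalog)
      files <- character(0)
      f <- file.path(out, "features.gff3")
      write_features(catalog, f, format = "GFF"); files <- c(files, f)
      f <- file.path(out, "chrom_sizes.tsv")
      write_chrom_sizes(catalog$chrom_sizes, f); files <- c(files, f)
      f <- file.path(out, "ripchip_matrix.tsv")
      write_enrichment_tsv(simulate_ripchip(sc, truth), f)
      files <- c(files, f)
      f <- file.path(out, "expression_matrix.tsv")
      write_enrichment_tsv(simulate_expression(sc, truth), f)
      files <- c(files, f)
      for (cond in c("wt", "mutant")) {
        reads <- simulate_chip_reads(sc, truth, catalog, cond)
        for (k in unique(sample_key(reads))) {
          f <- file.path(out, paste0("reads_", k, ".bed"))
          write_reads_bed(reads[sample_key(reads) == k, ], f)
          files <- c(files, f)
        }
      }
      f <- file.path(out, "ct_table.tsv")
      write_ct_tsv(simulate_qpcr(sc), f); files <- c(files, f)
      f <- file.path(out, "ground_truth.json")
      jsonlite::write_json(unclass(truth), f, auto_unbox = FALSE, digits = NA)
      c(files, f)
    },
    ripchip = {
      require_paths(config, "ripchip_matrix")
      m <- read_enrichment_tsv(config$paths$ripchip_matrix, "rip")
      z <- zscores(mean_centre(m))
      calls <- call_targets(z, threshold = p$z_threshold,
                            rule = c(p$rule_k, ncol(z)))
      f1 <- file.path(out, "ripchip_zscores.tsv")
      write_enrichment_tsv(z, f1)
      f2 <- file.path(out, "ripchip_targets.tsv")
      writeLines(calls$called_ids, f2)
      c(f1, f2)
    },
    diffexpr = {
      require_paths(config, "expression_matrix")
      m <- read_enrichment_tsv(config$paths$expression_matrix, "expression")
      res <- sam_fdr(m, n_permutations = p$n_permutations,
                     seed = config$seed, fdr_threshold = p$fdr_threshold)
      f1 <- file.path(out, "de_results.tsv")
      write_de_tsv(res, f1)
      f2 <- file.path(out, "de_up.txt")
      writeLines(res$gene_id[res$direction == "up"], f2)
      f3 <- file.path(out, "de_down.txt")
      writeLines(res$gene_id[res$direction == "down"], f3)
      c(f1, f2, f3)
    },
    overlap = {
      require_paths(config, c("gene_lists", "universe"))
      sets <- lapply(config$paths$gene_lists, read_gene_list)
      names(sets) <- names(config$paths$gene_lists)
      universe <- read_gene_list(config$paths$universe)
      res <- overlap_summary(sets, universe)
      f <- file.path(out, "overlap_summary.tsv")
      write.table(res, f, sep = "\t", quote = FALSE, row.names = FALSE)
      f
    },
    chip = {
      require_paths(config, c("catalog", "reads"))
      catalog <- load_features(config$paths$catalog, format = "TSV",
                               chrom_sizes = config$paths$chrom_sizes)
      keys <- names(config$paths$reads)
      reads <- do.call(rbind, lapply(keys, function(k) {
        ann <- strsplit(k, ".", fixed = TRUE)[[1]]
        if (length(ann) != 3)
          stop_config("read sample name '", k,
                      "' is not antibody.condition.replicate")
        read_aligned_reads(config$paths$reads[[k]], format = "BED",
                           antibody = ann[1], condition = ann[2],
                           replicate = ann[3])
      }))
      occ <- occupancy_table(reads, catalog)
      f1 <- file.path(out, "occupancy.tsv")
      write_occupancy_tsv(occ, f1)
      conds <- unique(occ$condition)
      files <- f1
      enr <- detect_enriched(occ, condition = conds[1],
                             enrichment_factor = p$enrichment_factor)
      f2 <- file.path(out, "enriched_features.tsv")
      write.table(enr, f2, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f2)
      if (length(conds) >= 2) {
        cmp <- compare_conditions(occ, wt = conds[1], mutant = conds[2],
                                  reduction_factor = p$reduction_factor)
        cs <- class_summary(cmp)
        f3 <- file.path(out, "condition_comparison.tsv")
        write.table(cs$features, f3, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        f4 <- file.path(out, "class_summary.tsv")
        write.table(cs$classes, f4, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        files <- c(files, f3, f4)
      }
      files
    },
    qpcr = {
      require_paths(config, "ct_table")
      ct <- read_ct_tsv(config$paths$ct_table)
      s <- ddct_summary(ct)
      f <- file.path(out, "qpcr_ratios.tsv")
      write.table(
        data.frame(replicate = c(names(s$ratios), "summary"),
                   ratio = c(unname(s$ratios), s$mean_ratio),
                   sd = c(rep(NA, s$n), s$sd_ratio)),
        f, sep = "\t", quote = FALSE, row.names = FALSE)
      f
    })
  manifest <- write_manifest(config, stage, outputs)
  invisible(c(outputs, manifest))
}

#' End-to-end demonstration on synthetic data
#'
#' Generates a toy genome with planted truth, runs every analysis stage in
#' memory, and scores each stage's recovery against the planted truth:
#' RIP-chip target sensitivity/precision, differential-expression power and
#' realized false-call behaviour, the significance of the planted
#' target/DE overlap, island detection and mutant reduction calls (with the
#' distal subtelomeric sub-blocks expected untouched), and qPCR ratio
#' recovery.
#'
#' @param seed integer master seed.
#' @param config optional [synth_config()]; defaults to
#'   `synth_config(seed = seed)`.
#' @param outdir optional directory; when given, result tables are also
#'   written there via the file-based stages.
#' @return an object of class `hetseq_demo_report` (a nested list of
#'   observed-versus-planted summaries, each with a `pass` flag), printed
#'   as a human-readable report.
#' @export
run_demo <- function(seed = 1, config = NULL, outdir = NULL) {
  sc <- config %||% synth_config(seed = seed)
  catalog <- make_genome(sc)
  truth <- plant_truth(sc, catalog)
  genes <- unique(probe_gene(probe_ids(sc)))

  # RIP-chip recovery
  rip <- simulate_ripchip(sc, truth)
  calls <- call_targets(zscores(mean_centre(rip)),
                        rule = c(2, ncol(rip)))
  called_genes <- unique(probe_gene(calls$called_ids))
  tp <- length(intersect(called_genes, truth$target_ids))
  rip_report <- list(
    n_planted = length(truth$target_ids), n_called = length(called_genes),
    sensitivity = tp / max(1, length(truth$target_ids)),
    precision = if (length(called_genes) > 0) tp / length(called_genes) else NA,
    pass = tp / max(1, length(truth$target_ids)) >= 0.9 &&
      (length(called_genes) == 0 || tp / length(called_genes) >= 0.9))

  # Differential expression
  expr <- simulate_expression(sc, truth)
  if (sc$expression$dye_bias_amplitude != 0)
    expr <- loess_normalize(expr)
  de <- sam_fdr(expr, seed = substream_seed(seed, "sam"))
  de_called <- de$gene_id[de$called]
  de_tp <- length(intersect(probe_gene(de_called), truth$de$gene_id))
  de_report <- list(
    n_planted = nrow(truth$de), n_called = length(de_called),
    power = de_tp / max(1, nrow(truth$de)),
    false_calls = length(de_called) - de_tp,
    pass = de_tp / max(1, nrow(truth$de)) >= 0.9 &&
      (length(de_called) == 0 || de_tp / length(de_called) >= 0.9))

  # Overlap of bound targets with up-regulated genes (planted to overlap)
  up <- unique(probe_gene(de$gene_id[de$direction == "up"]))
  ov <- fisher_overlap(truth$target_ids, up, genes)
  ov_report <- list(observed = ov$observed, expected = ov$expected,
                    p_value = ov$p_value, pass = ov$p_value < 0.01)

  # ChIP occupancy
  reads <- rbind(simulate_chip_reads(sc, truth, catalog, "wt"),
                 simulate_chip_reads(sc, truth, catalog, "mutant"))
  occ <- occupancy_table(reads, catalog)
  enr <- detect_enriched(occ, condition = "wt")
  islands <- features_by_class(catalog, "island")$feature_id
  flagged_islands <- intersect(enr$feature_id[enr$enriched], islands)
  planted_islands <- intersect(truth$methylated_wt, islands)
  cmp <- compare_conditions(occ)
  het <- cmp[cmp$fclass %in% HETEROCHROMATIN_CLASSES, ]
  reduced <- het$feature_id[het$call == "reduced"]
  distal <- grep("_distal$", het$feature_id, value = TRUE)
  chip_report <- list(
    planted_islands = planted_islands, flagged_islands = flagged_islands,
    planted_lost = sort(truth$lost_in_mutant), called_reduced = sort(reduced),
    distal_reduced = intersect(reduced, distal),
    pass = setequal(flagged_islands, planted_islands) &&
      setequal(reduced, truth$lost_in_mutant) &&
      length(intersect(reduced, distal)) == 0)

  # qPCR recovery
  qp <- ddct_summary(simulate_qpcr(sc))
  qpcr_report <- list(true_ratio = truth$qpcr_true_ratio,
                      recovered = qp$mean_ratio,
                      pass = abs(qp$mean_ratio / truth$qpcr_true_ratio - 1)
                        < 0.1)

  report <- structure(list(seed = seed, ripchip = rip_report,
                           diffexpr = de_report, overlap = ov_report,
                           chip = chip_report, qpcr = qpcr_report),
                      class = "hetseq_demo_report")
  if (!is.null(outdir)) {
    cfg <- pipeline_config(outdir, seed = seed, params = list(synth = sc))
    run_stage("simulate", cfg)
    cfg$paths$ripchip_matrix <- file.path(outdir, "ripchip_matrix.tsv")
    cfg$paths$expression_matrix <- file.path(outdir, "expression_matrix.tsv")
    cfg$paths$ct_table <- file.path(outdir, "ct_table.tsv")
    run_stage("ripchip", cfg)
    run_stage("diffexpr", cfg)
    run_stage("qpcr", cfg)
  }
  report
}

#' @export
print.hetseq_demo_report <- function(x, ...) {
  ok <- function(p) if (isTRUE(p)) "PASS" else "FAIL"
  cat("hetseq synthetic demonstration (seed ", x$seed, ")\n", sep = "")
  cat(sprintf(
    "  RIP-chip: %d/%d planted targets recovered (precision %.3f)  [%s]\n",
    round(x$ripchip$sensitivity * x$ripchip$n_planted),
    x$ripchip$n_planted, x$ripchip$precision, ok(x$ripchip$pass)))
  cat(sprintf(
    "  DE: power %.3f over %d planted genes, %d false calls  [%s]\n",
    x$diffexpr$power, x$diffexpr$n_planted, x$diffexpr$false_calls,
    ok(x$diffexpr$pass)))
  cat(sprintf(
    "  Target/up-regulated overlap: %d observed (%.2f expected), p = %.3g  [%s]\n",
    x$overlap$observed, x$overlap$expected, x$overlap$p_value,
    ok(x$overlap$pass)))
  cat(sprintf(
    "  ChIP: %d/%d methylated islands flagged; %d/%d lost domains called reduced; %d distal sub-blocks mis-called  [%s]\n",
    length(x$chip$flagged_islands), length(x$chip$planted_islands),
    length(intersect(x$chip$called_reduced, x$chip$planted_lost)),
    length(x$chip$planted_lost), length(x$chip$distal_reduced),
    ok(x$chip$pass)))
  cat(sprintf(
    "  qPCR: recovered ratio %.3f (true %.3f)  [%s]\n",
    x$qpcr$recovered, x$qpcr$true_ratio, ok(x$qpcr$pass)))
  invisible(x)
}
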