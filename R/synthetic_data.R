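#' Configuration for the synthetic-data generators
#'
#' One seeded configuration drives every generator.  Defaults emulate the
#' study conditions of a fission-yeast screen: an array of ~5000 genes with a
#' few tens of bound targets at a strong (8-fold, i.e. 3 log2 units)
#' enrichment, mutant expression changes of ~1.5 log2 units in ~80 genes, a
#' two-chromosome genome carrying 21 candidate heterochromatin islands of
#' which 6 are methylated, subtelomeric blocks with distal nucleation
#' sub-blocks, one centromere and transposon/HOOD blocks, and ChIP read
#' depths giving several hundred reads per island.
#'
#' @param seed integer master seed; all generator substreams derive from it
#'   deterministically, so identical seed + config gives bit-identical
#'   output regardless of call order.
#' @param n_genes number of genes on the array / in the genome.
#' @param n_probes_per_gene probes per gene on the array (rows are probes
#'   when > 1).
#' @param ripchip,expression,chip,qpcr named lists overriding the per-stage
#'   defaults listed below.
#'
#' @section Stage parameters:
#' * `ripchip`: `n_targets` (50), `target_effect` log2 shift (3.0),
#'   `noise_sd` log2 units (0.5), `n_replicates` (2).
#' * `expression`: `n_de` (80), `de_log2fc` (1.5), `noise_sd` (0.3),
#'   `n_replicates` (3), `frac_up` (0.75), `dye_bias_amplitude` (0).
#' * `chip`: `genome_length` (`NULL` = sized from `n_genes`), `read_length`
#'   (50), `n_reads_per_channel` (2e5), `island_me2_enrichment` (8),
#'   `mutant_loss_fraction` (0.2), `n_replicates` (2), `n_islands` (21),
#'   `n_methylated_islands` (6), `n_lost_islands` (5), `h3_profile`
#'   (`"uniform"` or `"variable"`).
#' * `qpcr`: `true_ratio` (8), `ct_noise_sd` (0.1), `n_replicates` (3).
#'
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(seed = 1, n_genes = 5000, n_probes_per_gene = 1,
                         ripchip = list(), expression = list(),
                         chip = list(), qpcr = list()) {
  merge_defaults <- function(user, def, what) {
    unknown <- setdiff(names(user), names(def))
    if (length(unknown) > 0)
      stop("unknown ", what, " parameter(s): ", paste(unknown, collapse = ", "))
    def[names(user)] <- user
    def
  }
  cfg <- structure(list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    n_probes_per_gene = as.integer(n_probes_per_gene),
    ripchip = merge_defaults(ripchip, list(
      n_targets = 50L, target_effect = 3.0, noise_sd = 0.5,
      n_replicates = 2L), "ripchip"),
    expression = merge_defaults(expression, list(
      n_de = 80L, de_log2fc = 1.5, noise_sd = 0.3, n_replicates = 3L,
      frac_up = 0.75, dye_bias_amplitude = 0), "expression"),
    chip = merge_defaults(chip, list(
      genome_length = NULL, read_length = 50L, n_reads_per_channel = 800000L,
      island_me2_enrichment = 8, mutant_loss_fraction = 0.2,
      n_replicates = 2L, n_islands = 21L, n_methylated_islands = 6L,
      n_lost_islands = 5L, h3_profile = "uniform"), "chip"),
    qpcr = merge_defaults(qpcr, list(
      true_ratio = 8, ct_noise_sd = 0.1, n_replicates = 3L), "qpcr")
  ), class = "synth_config")
  if (cfg$ripchip$n_targets > cfg$n_genes)
    stop("n_targets must not exceed n_genes")
  if (cfg$expression$n_de > cfg$n_genes)
    stop("n_de must not exceed n_genes")
  if (cfg$chip$n_lost_islands > cfg$chip$n_methylated_islands ||
      cfg$chip$n_methylated_islands > cfg$chip$n_islands)
    stop("need n_lost_islands <= n_methylated_islands <= n_islands")
  if (cfg$qpcr$true_ratio <= 0) stop("qpcr true_ratio must be positive")
  cfg
}

gene_ids <- function(config) {
  sprintf("gene_%05d", seq_len(config$n_genes))
}

probe_ids <- function(config) {
  g <- gene_ids(config)
  if (config$n_probes_per_gene <= 1) return(g)
  as.vector(vapply(seq_len(config$n_probes_per_gene),
                   function(p) paste0(g, ".p", p),
                   character(config$n_genes)))
}

# Map probe rows back to gene ids.
probe_gene <- function(ids) sub("\\.p[0-9]+$", "", ids)

# Fixed genome geometry (bp).
.GEOM <- list(gene_width = 1200, gene_pitch = 1500, margin = 20000,
              subtel_distal = 5000, subtel_prox = 10000,
              centromere = 16000, transposon = 4000,
              island_pad = 400)

#' Generate a synthetic genome feature catalog
#'
#' Lays out a two-chromosome genome: genes tiled along each chromosome,
#' subtelomeric blocks at all four chromosome ends (each with a distal
#' "nucleation" sub-block and a proximal block), one centromere, one
#' transposon and one HOOD block, and `n_islands` candidate heterochromatin
#' islands placed on top of (overlapping) host genes — a few of which are
#' non-coding, mirroring islands that cover ncRNAs rather than meiotic
#' mRNAs.
#'
#' @param config a [synth_config()].
#' @return a [feature_catalog()] for which [validate_catalog()] is clean.
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  g <- .GEOM
  n <- config$n_genes
  n1 <- ceiling(n / 2); n2 <- n - n1
  seed <- substream_seed(config$seed, "genome")

  build_chrom <- function(chrom, n_genes_here, mid_blocks) {
    # mid_blocks: data.frame(feature_id, fclass, width) inserted between two
    # runs of genes.
    feats <- list()
    cursor <- g$margin
    h <- floor(n_genes_here / 2)
    runs <- list(seq_len(h), seq_len(n_genes_here - h) + h)
    blocks_at <- NULL
    for (r in 1:2) {
      for (i in runs[[r]]) {
        feats[[length(feats) + 1]] <- data.frame(
          feature_id = NA_character_, chrom = chrom,
          start = cursor, end = cursor + g$gene_width,
          strand = if (i %% 2 == 0) "-" else "+", fclass = "mRNA",
          stringsAsFactors = FALSE)
        cursor <- cursor + g$gene_pitch
      }
      if (r == 1 && nrow(mid_blocks) > 0) {
        cursor <- cursor + 2000
        for (b in seq_len(nrow(mid_blocks))) {
          feats[[length(feats) + 1]] <- data.frame(
            feature_id = mid_blocks$feature_id[b], chrom = chrom,
            start = cursor, end = cursor + mid_blocks$width[b],
            strand = ".", fclass = mid_blocks$fclass[b],
            stringsAsFactors = FALSE)
          cursor <- cursor + mid_blocks$width[b] + 2000
        }
      }
    }
    L <- cursor - g$gene_pitch + g$gene_width + g$margin
    list(features = do.call(rbind, feats), length = L)
  }

  chr1 <- build_chrom("chrI", n1, data.frame(
    feature_id = "cen_I", fclass = "centromere", width = g$centromere,
    stringsAsFactors = FALSE))
  chr2 <- build_chrom("chrII", n2, data.frame(
    feature_id = c("tf2_1", "hood_1"), fclass = c("transposon", "HOOD"),
    width = g$transposon, stringsAsFactors = FALSE))

  feats <- rbind(chr1$features, chr2$features)
  sizes <- c(chrI = chr1$length, chrII = chr2$length)
  is_gene <- is.na(feats$feature_id)
  feats$feature_id[is_gene] <- gene_ids(config)

  subtel <- do.call(rbind, lapply(names(sizes), function(ch) {
    L <- sizes[[ch]]
    arm <- sub("chr", "", ch)
    data.frame(
      feature_id = paste0("subtel_", arm, c("L_distal", "L_prox",
                                            "R_prox", "R_distal")),
      chrom = ch,
      start = c(0, g$subtel_distal,
                L - g$subtel_distal - g$subtel_prox, L - g$subtel_distal),
      end = c(g$subtel_distal, g$subtel_distal + g$subtel_prox,
              L - g$subtel_distal, L),
      strand = ".", fclass = "subtelomere", stringsAsFactors = FALSE)
  }))
  feats <- rbind(feats, subtel)

  # Candidate islands overlap host genes, spaced so islands never touch.
  n_isl <- config$chip$n_islands
  if (n_isl > 0 && n > 0) {
    pool <- if (n >= 5) seq(3, n - 2, by = 4) else integer(0)
    if (length(pool) < n_isl)
      stop("configuration error: n_genes too small to place ", n_isl,
           " non-overlapping islands")
    hosts <- with_seed(seed, sort(sample(pool, n_isl)))
    host_rows <- match(gene_ids(config)[hosts], feats$feature_id)
    # Two methylated islands cover non-coding genes rather than mRNAs.
    if (config$chip$n_methylated_islands >= 6)
      feats$fclass[host_rows[5:6]] <- "ncRNA"
    islands <- data.frame(
      feature_id = sprintf("island_%02d", seq_len(n_isl)),
      chrom = feats$chrom[host_rows],
      start = feats$start[host_rows] - g$island_pad,
      end = feats$end[host_rows] + g$island_pad,
      strand = ".", fclass = "island", stringsAsFactors = FALSE)
    feats <- rbind(feats, islands)
  }

  wanted <- config$chip$genome_length
  if (!is.null(wanted) && sum(sizes) > wanted)
    stop("configuration error: genome_length ", wanted,
         " too small for the requested features (need ", sum(sizes), " bp)")
  feature_catalog(feats, chrom_sizes = sizes)
}

#' Plant the ground truth for all generators
#'
#' Draws the bound-target set, the differentially expressed set with signed
#' fold-changes, and the methylated-domain sets per condition.  Targets
#' include the host genes of the methylated islands (bound targets sit under
#' heterochromatin islands); a third of the up-regulated genes are drawn from
#' the target set so that target/DE overlap is planted and detectable.
#' In the mutant condition, `n_lost_islands` of the methylated islands and
#' all proximal subtelomeric blocks lose their methylation excess, while
#' distal (nucleation) sub-blocks and the centromere are unaffected.
#'
#' @param config a [synth_config()].
#' @param catalog the catalog from [make_genome()].
#' @return an object of class `ground_truth` with elements `target_ids`,
#'   `de` (data.frame `gene_id`, `log2fc`), `methylated_wt`,
#'   `lost_in_mutant`, `retained_in_mutant`, `qpcr_true_ratio`.
#' @export
plant_truth <- function(config, catalog) {
  stopifnot(inherits(config, "synth_config"),
            inherits(catalog, "feature_catalog"))
  seed <- substream_seed(config$seed, "truth")
  genes <- features_by_class(catalog, c("mRNA", "ncRNA"))
  islands <- features_by_class(catalog, "island")
  subtel <- features_by_class(catalog, "subtelomere")
  cen <- features_by_class(catalog, "centromere")

  meth_islands <- utils::head(islands$feature_id,
                              config$chip$n_methylated_islands)
  lost_islands <- utils::head(meth_islands, config$chip$n_lost_islands)
  prox <- subtel$feature_id[grepl("_prox$", subtel$feature_id)]
  distal <- subtel$feature_id[grepl("_distal$", subtel$feature_id)]
  methylated_wt <- c(meth_islands, prox, distal, cen$feature_id)
  lost <- c(lost_islands, prox)

  # Host genes of methylated islands (by containment) are bound targets.
  hosts <- character(0)
  if (nrow(islands) > 0 && nrow(genes) > 0) {
    for (i in match(meth_islands, islands$feature_id)) {
      hit <- genes$chrom == islands$chrom[i] &
        genes$start >= islands$start[i] & genes$end <= islands$end[i]
      hosts <- c(hosts, genes$feature_id[hit])
    }
  }
  truth <- with_seed(seed, {
    n_t <- config$ripchip$n_targets
    others <- setdiff(genes$feature_id, hosts)
    target_ids <- if (n_t <= length(hosts)) utils::head(hosts, n_t)
                  else c(hosts, sample(others, n_t - length(hosts)))
    n_de <- config$expression$n_de
    n_up <- round(n_de * config$expression$frac_up)
    n_from_targets <- min(floor(n_up / 3), length(target_ids))
    up <- c(sample(target_ids, n_from_targets),
            sample(setdiff(genes$feature_id, target_ids),
                   n_up - n_from_targets))
    down <- sample(setdiff(genes$feature_id, up), n_de - n_up)
    de <- data.frame(gene_id = c(up, down),
                     log2fc = rep(c(config$expression$de_log2fc,
                                    -config$expression$de_log2fc),
                                  c(length(up), length(down))),
                     stringsAsFactors = FALSE)
    list(target_ids = sort(target_ids), de = de)
  })
  structure(list(
    target_ids = truth$target_ids,
    de = truth$de,
    methylated_wt = methylated_wt,
    lost_in_mutant = lost,
    retained_in_mutant = setdiff(methylated_wt, lost),
    qpcr_true_ratio = config$qpcr$true_ratio
  ), class = "ground_truth")
}

# Shift vector for planted effects, expanded to probe rows.
planted_shift <- function(ids, effect_ids, effects) {
  shift <- numeric(length(ids))
  m <- match(probe_gene(ids), effect_ids)
  shift[!is.na(m)] <- effects[m[!is.na(m)]]
  shift
}

#' Simulate a RIP-chip enrichment matrix
#'
#' Per-probe log2(IP/total) enrichments: non-targets are Gaussian noise
#' around zero, planted targets are shifted up by `target_effect`.
#' Replicates are independent draws.
#'
#' @param config a [synth_config()].
#' @param truth a [plant_truth()] object.
#' @return numeric matrix (probes x replicates) with attribute
#'   `channel_semantics = "rip"`.
#' @export
simulate_ripchip <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"))
  ids <- probe_ids(config)
  k <- config$ripchip$n_replicates
  shift <- planted_shift(ids, truth$target_ids,
                         rep(config$ripchip$target_effect,
                             length(truth$target_ids)))
  m <- with_seed(substream_seed(config$seed, "ripchip"), {
    matrix(rnorm(length(ids) * k, sd = config$ripchip$noise_sd),
           nrow = length(ids)) + shift
  })
  dimnames(m) <- list(ids, paste0("rep", seq_len(k)))
  attr(m, "channel_semantics") <- "rip"
  m
}

#' Simulate a mutant-versus-wild-type expression matrix
#'
#' Per-probe log2(mutant/WT) ratios with planted signed fold-changes, and
#' optionally a smooth intensity-dependent dye bias (an additive trend of
#' the log-ratio along mean spot intensity) to exercise loess
#' normalization.  Mean intensities are attached as attribute
#' `intensities` (same dimensions).
#'
#' @param config a [synth_config()].
#' @param truth a [plant_truth()] object.
#' @return numeric matrix (probes x replicates), `channel_semantics =
#'   "expression"`, with attribute `intensities`.
#' @export
simulate_expression <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"))
  ids <- probe_ids(config)
  k <- config$expression$n_replicates
  shift <- planted_shift(ids, truth$de$gene_id, truth$de$log2fc)
  res <- with_seed(substream_seed(config$seed, "expression"), {
    a <- matrix(runif(length(ids) * k, 8, 16), nrow = length(ids))
    m <- matrix(rnorm(length(ids) * k, sd = config$expression$noise_sd),
                nrow = length(ids)) + shift
    amp <- config$expression$dye_bias_amplitude
    if (amp != 0) m <- m + amp * sin(pi * (a - 8) / 4)
    list(m = m, a = a)
  })
  dimnames(res$m) <- dimnames(res$a) <-
    list(ids, paste0("rep", seq_len(k)))
  attr(res$m, "channel_semantics") <- "expression"
  attr(res$m, "intensities") <- res$a
  res$m
}

# Per-condition weight intervals: piecewise-constant read density along each
# chromosome.  Methylated domains carry `enrich`-fold density; in the mutant,
# lost domains retain `loss_fraction` of the excess over background.
me2_weight_intervals <- function(config, truth, catalog, condition) {
  enrich <- config$chip$island_me2_enrichment
  f <- catalog$features
  dom_ids <- truth$methylated_wt
  w <- setNames(rep(enrich, length(dom_ids)), dom_ids)
  if (condition != "wt") {
    lost <- intersect(dom_ids, truth$lost_in_mutant)
    w[lost] <- 1 + config$chip$mutant_loss_fraction * (enrich - 1)
  }
  out <- list()
  for (ch in names(catalog$chrom_sizes)) {
    L <- catalog$chrom_sizes[[ch]]
    d <- f[f$feature_id %in% dom_ids & f$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    starts <- c(0, d$end); ends <- c(d$start, L)
    gaps <- data.frame(chrom = ch, start = starts, end = ends, weight = 1)
    gaps <- gaps[gaps$end > gaps$start, , drop = FALSE]
    doms <- data.frame(chrom = ch, start = d$start, end = d$end,
                       weight = unname(w[d$feature_id]))
    out[[ch]] <- rbind(gaps, doms)
  }
  iv <- do.call(rbind, out)
  rownames(iv) <- NULL
  iv[order(iv$chrom, iv$start), , drop = FALSE]
}

uniform_weight_intervals <- function(catalog) {
  data.frame(chrom = names(catalog$chrom_sizes), start = 0,
             end = as.numeric(catalog$chrom_sizes), weight = 1,
             stringsAsFactors = FALSE)
}

# Smooth-ish nucleosome occupancy profile: per-50kb multiplicative factor.
apply_h3_profile <- function(iv, catalog, config) {
  if (identical(config$chip$h3_profile, "uniform")) return(iv)
  bin <- 50000
  pieces <- list()
  prof_seed <- substream_seed(config$seed, "h3profile")
  for (ch in names(catalog$chrom_sizes)) {
    L <- catalog$chrom_sizes[[ch]]
    nb <- ceiling(L / bin)
    fac <- with_seed(substream_seed(prof_seed, ch), runif(nb, 0.5, 1.5))
    sub <- iv[iv$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      b0 <- floor(sub$start[i] / bin); b1 <- floor((sub$end[i] - 1) / bin)
      for (b in b0:b1) {
        s <- max(sub$start[i], b * bin); e <- min(sub$end[i], (b + 1) * bin)
        pieces[[length(pieces) + 1]] <-
          data.frame(chrom = ch, start = s, end = e,
                     weight = sub$weight[i] * fac[b + 1])
      }
    }
  }
  do.call(rbind, pieces)
}

sample_reads_from_intervals <- function(n, iv, read_length, chrom_sizes) {
  mass <- iv$weight * (iv$end - iv$start)
  counts <- as.vector(rmultinom(1, n, prob = mass))
  idx <- rep(seq_len(nrow(iv)), counts)
  pos <- floor(iv$start[idx] +
                 runif(length(idx)) * (iv$end[idx] - iv$start[idx]))
  chrom <- iv$chrom[idx]
  pos <- pmin(pos, chrom_sizes[chrom] - read_length)
  pos <- pmax(pos, 0)
  data.frame(chrom = chrom, start = pos, length = read_length,
             strand = sample(c("+", "-"), length(idx), replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Simulate aligned ChIP-seq reads for one condition
#'
#' Emits already-aligned fixed-length reads for three channels: histone H3
#' (uniform nucleosome occupancy by default), H3K9me2 (density
#' `island_me2_enrichment`-fold higher inside the condition's methylated
#' domains than outside) and input (uniform).  In mutant conditions the
#' planted lost domains retain `mutant_loss_fraction` of their excess
#' density while distal subtelomeric sub-blocks and the centromere keep
#' full density.  With `h3_profile = "variable"` a piecewise nucleosome
#' occupancy profile multiplies all chromatin channels, which the
#' H3 normalization must cancel.
#'
#' @param config a [synth_config()].
#' @param truth a [plant_truth()] object.
#' @param catalog the catalog from [make_genome()].
#' @param condition `"wt"` or `"mutant"`.
#' @return data.frame of reads with columns `chrom`, `start` (0-based),
#'   `length`, `strand`, `antibody` (`H3`, `H3K9me2`, `input`),
#'   `condition`, `replicate`.
#' @export
simulate_chip_reads <- function(config, truth, catalog,
                                condition = c("wt", "mutant")) {
  condition <- match.arg(condition)
  stopifnot(inherits(config, "synth_config"),
            inherits(catalog, "feature_catalog"))
  n <- config$chip$n_reads_per_channel
  rl <- config$chip$read_length
  me2_iv <- apply_h3_profile(
    me2_weight_intervals(config, truth, catalog, condition), catalog, config)
  flat_iv <- apply_h3_profile(uniform_weight_intervals(catalog),
                              catalog, config)
  out <- list()
  for (rep_i in seq_len(config$chip$n_replicates)) {
    for (ab in c("H3", "H3K9me2", "input")) {
      iv <- if (ab == "H3K9me2") me2_iv else flat_iv
      sd_seed <- substream_seed(config$seed,
                                paste("chip", condition, rep_i, ab))
      reads <- with_seed(sd_seed,
        sample_reads_from_intervals(n, iv, rl, catalog$chrom_sizes))
      reads$antibody <- ab
      reads$condition <- condition
      reads$replicate <- paste0("rep", rep_i)
      out[[length(out) + 1]] <- reads
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a ChIP-qPCR Ct table
#'
#' Constructs critical-cycle (Ct) values for a target and a reference locus
#' in IP and input fractions such that the standard 2^-ddCt computation
#' recovers `true_ratio` exactly at zero noise; Gaussian cycle noise of sd
#' `ct_noise_sd` is added to every well.
#'
#' @param config a [synth_config()].
#' @return data.frame with columns `gene` (`target`/`reference`),
#'   `fraction` (`IP`/`INPUT`), `replicate`, `ct`.
#' @export
simulate_qpcr <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  r <- config$qpcr$true_ratio
  base <- data.frame(
    gene = c("target", "reference", "target", "reference"),
    fraction = c("IP", "IP", "INPUT", "INPUT"),
    ct = c(27 + 2 - log2(r), 27, 26, 24),
    stringsAsFactors = FALSE)
  with_seed(substream_seed(config$seed, "qpcr"), {
    reps <- lapply(seq_len(config$qpcr$n_replicates), function(i) {
      d <- base
      d$replicate <- paste0("rep", i)
      d$ct <- d$ct + rnorm(nrow(d), sd = config$qpcr$ct_noise_sd)
      d[, c("gene", "fraction", "replicate", "ct")]
    })
    do.call(rbind, reps)
  })
}

#' Write synthetic reads as BED6
#'
#' @param reads read data.frame from [simulate_chip_reads()] (one sample,
#'   i.e. one antibody/condition/replicate combination, or any subset —
#'   sample columns are not stored in BED).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  bed <- data.frame(reads$chrom, reads$start, reads$start + reads$length,
                    paste0("read_", seq_len(nrow(reads))), 0, reads$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read aligned reads from BED6 or SAM
#'
#' SAM ingestion keeps primary alignments only (drops unmapped, secondary
#' and supplementary records) and takes the read length from the query
#' width.  Sample annotations (antibody, condition, replicate) are supplied
#' by the caller since neither format carries them.
#'
#' @param path input file.
#' @param format `"BED"` or `"SAM"`.
#' @param antibody,condition,replicate sample annotation attached to every
#'   read.
#' @return read data.frame as produced by [simulate_chip_reads()].
#' @export
read_aligned_reads <- function(path, format = c("BED", "SAM"),
                               antibody = "H3K9me2", condition = "wt",
                               replicate = "rep1") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "BED") {
    d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    reads <- data.frame(chrom = as.character(d[[1]]),
                        start = as.numeric(d[[2]]),
                        length = as.numeric(d[[3]]) - as.numeric(d[[2]]),
                        strand = if (ncol(d) >= 6) as.character(d[[6]])
                                 else ".",
                        stringsAsFactors = FALSE)
  } else {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
    p <- Rsamtools::ScanBamParam(
      flag = flag, what = c("rname", "pos", "strand", "qwidth"))
    b <- Rsamtools::scanBam(bam, param = p)[[1]]
    reads <- data.frame(chrom = as.character(b$rname),
                        start = b$pos - 1,           # SAM is 1-based
                        length = b$qwidth,
                        strand = as.character(b$strand),
                        stringsAsFactors = FALSE)
  }
  reads$antibody <- antibody
  reads$condition <- condition
  reads$replicate <- replicate
  reads
}
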