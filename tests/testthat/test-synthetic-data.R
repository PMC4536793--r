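test_that("generators are bit-identical under a fixed seed", {
  sc <- small_config(seed = 42)
  cat1 <- make_genome(sc); cat2 <- make_genome(sc)
  expect_identical(cat1, cat2)
  tr1 <- plant_truth(sc, cat1); tr2 <- plant_truth(sc, cat2)
  expect_identical(tr1, tr2)
  expect_identical(simulate_ripchip(sc, tr1), simulate_ripchip(sc, tr2))
  expect_identical(simulate_expression(sc, tr1), simulate_expression(sc, tr2))
  expect_identical(simulate_chip_reads(sc, tr1, cat1, "wt"),
                   simulate_chip_reads(sc, tr2, cat2, "wt"))
  expect_identical(simulate_qpcr(sc), simulate_qpcr(sc))
})

test_that("generated genome is valid and carries the required block structure", {
  sc <- small_config()
  cat_ <- make_genome(sc)
  expect_length(validate_catalog(cat_), 0)
  f <- cat_$features
  expect_gte(sum(f$fclass == "island"), 6)
  expect_equal(sum(f$fclass == "subtelomere"), 8)   # 4 ends x (distal+prox)
  expect_equal(sum(grepl("_distal$", f$feature_id)), 4)
  expect_equal(sum(f$fclass == "centromere"), 1)
  expect_gte(sum(f$fclass %in% c("transposon", "HOOD")), 2)
  # islands overlap their host genes
  isl <- f[f$fclass == "island", ][1, ]
  hosts <- f$fclass %in% c("mRNA", "ncRNA") & f$chrom == isl$chrom &
    f$start >= isl$start & f$end <= isl$end
  expect_true(any(hosts))
})

test_that("a gene-free genome still contains the chromatin blocks", {
  sc <- synth_config(seed = 1, n_genes = 0,
                     ripchip = list(n_targets = 0),
                     expression = list(n_de = 0))
  cat_ <- make_genome(sc)
  expect_length(validate_catalog(cat_), 0)
  expect_equal(sum(cat_$features$fclass %in% c("mRNA", "ncRNA")), 0)
  expect_gte(nrow(cat_$features), 10)
})

test_that("RIP-chip targets sit at the planted effect size", {
  sc <- small_config(seed = 3)
  tr <- plant_truth(sc, make_genome(sc))
  m <- simulate_ripchip(sc, tr)
  tgt <- m[tr$target_ids, ]
  eff <- sc$ripchip$target_effect
  se <- sc$ripchip$noise_sd / sqrt(length(tgt))
  expect_lt(abs(mean(tgt) - eff), 3 * se)
  expect_lt(abs(mean(m[setdiff(rownames(m), tr$target_ids), ])), 0.1)

  # degenerate noise: exact values
  sc0 <- small_config(seed = 3, ripchip = list(noise_sd = 0))
  m0 <- simulate_ripchip(sc0, tr)
  expect_true(all(m0[tr$target_ids, ] == eff))
  expect_true(all(m0[setdiff(rownames(m0), tr$target_ids), ] == 0))
})

test_that("expression simulation plants signed fold-changes and dye bias", {
  sc0 <- small_config(seed = 5, expression = list(noise_sd = 0))
  tr <- plant_truth(sc0, make_genome(sc0))
  m0 <- simulate_expression(sc0, tr)
  up <- tr$de$gene_id[tr$de$log2fc > 0]
  down <- tr$de$gene_id[tr$de$log2fc < 0]
  expect_true(all(m0[up, ] == sc0$expression$de_log2fc))
  expect_true(all(m0[down, ] == -sc0$expression$de_log2fc))
  expect_true(all(m0[setdiff(rownames(m0), tr$de$gene_id), ] == 0))

  scb <- small_config(seed = 5,
                      expression = list(n_de = 0, dye_bias_amplitude = 1))
  trb <- plant_truth(scb, make_genome(scb))
  mb <- simulate_expression(scb, trb)
  a <- attr(mb, "intensities")
  trend <- stats::lowess(a[, 1], mb[, 1], f = 0.3)
  expect_gt(max(abs(trend$y)), 0.5)  # raw bias is visible
})

test_that("ChIP read density matches the planted enrichment and loss", {
  sc <- small_config(seed = 11)
  cat_ <- make_genome(sc)
  tr <- plant_truth(sc, cat_)
  reads <- simulate_chip_reads(sc, tr, cat_, "wt")
  me2 <- reads[reads$antibody == "H3K9me2" & reads$replicate == "rep1", ]
  f <- cat_$features
  dom <- f[f$feature_id %in% tr$methylated_wt, ]
  in_dom <- rep(FALSE, nrow(me2))
  for (i in seq_len(nrow(dom)))
    in_dom <- in_dom | (me2$chrom == dom$chrom[i] &
                          me2$start >= dom$start[i] & me2$start < dom$end[i])
  dom_bp <- sum(dom$end - dom$start)
  genome_bp <- sum(cat_$chrom_sizes)
  dens_in <- sum(in_dom) / dom_bp
  dens_out <- sum(!in_dom) / (genome_bp - dom_bp)
  ratio <- dens_in / dens_out
  expect_gt(ratio, 0.8 * sc$chip$island_me2_enrichment)
  expect_lt(ratio, 1.2 * sc$chip$island_me2_enrichment)
  # H3 channel is uniform: no enrichment
  h3 <- reads[reads$antibody == "H3" & reads$replicate == "rep1", ]
  h3_in <- rep(FALSE, nrow(h3))
  for (i in seq_len(nrow(dom)))
    h3_in <- h3_in | (h3$chrom == dom$chrom[i] &
                        h3$start >= dom$start[i] & h3$start < dom$end[i])
  h3_ratio <- (sum(h3_in) / dom_bp) / (sum(!h3_in) / (genome_bp - dom_bp))
  expect_lt(abs(h3_ratio - 1), 0.25)
})

test_that("mutant_loss_fraction = 1 makes mutant reads statistically identical to WT", {
  sc <- small_config(seed = 13, chip = list(mutant_loss_fraction = 1))
  cat_ <- make_genome(sc)
  tr <- plant_truth(sc, cat_)
  occ <- occupancy_table(
    rbind(simulate_chip_reads(sc, tr, cat_, "wt"),
          simulate_chip_reads(sc, tr, cat_, "mutant")), cat_)
  cmp <- compare_conditions(occ)
  het <- cmp[cmp$fclass %in% HETEROCHROMATIN_CLASSES, ]
  expect_equal(sum(het$call == "reduced"), 0)
  expect_equal(sum(het$call == "increased"), 0)
})

test_that("qPCR generator inverts exactly at zero noise", {
  sc <- small_config(qpcr = list(true_ratio = 8, ct_noise_sd = 0,
                                 n_replicates = 1))
  ct <- simulate_qpcr(sc)
  expect_equal(delta_delta_ct(ct), 8)
  sc1 <- small_config(qpcr = list(true_ratio = 1, ct_noise_sd = 0,
                                  n_replicates = 1))
  expect_equal(delta_delta_ct(simulate_qpcr(sc1)), 1)
})

test_that("reads round-trip through BED and SAM ingestion keeps primary alignments", {
  reads <- make_reads("chrI", c(10, 20, 30), length = 10)
  bed <- tempfile(fileext = ".bed")
  write_reads_bed(reads, bed)
  back <- read_aligned_reads(bed, format = "BED", antibody = "H3K9me2")
  expect_equal(back$start, reads$start)
  expect_equal(back$length, reads$length)

  sam <- tempfile(fileext = ".sam")
  seq10 <- paste(rep("A", 10), collapse = "")
  qual10 <- paste(rep("I", 10), collapse = "")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chrI\tLN:10000",
    paste("r1", 0, "chrI", 101, 60, "10M", "*", 0, 0, seq10, qual10,
          sep = "\t"),
    paste("r2", 16, "chrI", 201, 60, "10M", "*", 0, 0, seq10, qual10,
          sep = "\t"),
    paste("r3", 4, "*", 0, 0, "*", "*", 0, 0, seq10, qual10, sep = "\t"),
    paste("r4", 256, "chrI", 301, 60, "10M", "*", 0, 0, seq10, qual10,
          sep = "\t")), sam)
  got <- read_aligned_reads(sam, format = "SAM")
  expect_equal(nrow(got), 2)          # unmapped + secondary dropped
  expect_equal(sort(got$start), c(100, 200))  # SAM 1-based -> 0-based
  expect_equal(got$length, c(10, 10))
  expect_setequal(got$strand, c("+", "-"))
})
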