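test_that("reads are assigned by start position with half-open boundaries", {
  cat_ <- tiny_catalog()
  # geneA spans [100, 200): starts at 99 miss, 100 and 199 hit, 200 miss
  reads <- make_reads("chr1", c(99, 100, 199, 200))
  counts <- count_reads(reads, cat_)
  expect_equal(counts$count[counts$feature_id == "geneA"], 2)
  expect_equal(counts$count[counts$feature_id == "geneB"], 0)
  lib <- attr(counts, "library_sizes")
  expect_equal(lib$library_size, 4)  # misses still count toward library
})

test_that("overlapping features each receive the read and unknown chroms error", {
  cat_ <- feature_catalog(
    data.frame(feature_id = c("gene1", "isl1"), chrom = "chr1",
               start = c(100, 50), end = c(200, 250), strand = ".",
               fclass = c("mRNA", "island")),
    chrom_sizes = c(chr1 = 1000))
  counts <- count_reads(make_reads("chr1", 150), cat_)
  expect_true(all(counts$count == 1))
  expect_error(count_reads(make_reads("chrX", 10), cat_), "chrX")
})

test_that("counting is proportional to feature share under uniform reads", {
  sc <- small_config(seed = 17)
  cat_ <- make_genome(sc)
  tr <- plant_truth(sc, cat_)
  reads <- simulate_chip_reads(sc, tr, cat_, "wt")
  h3 <- reads[reads$antibody == "H3" & reads$replicate == "rep1", ]
  counts <- count_reads(h3, cat_)
  cen <- cat_$features[cat_$features$feature_id == "cen_I", ]
  frac <- (cen$end - cen$start) / sum(cat_$chrom_sizes)
  expected <- nrow(h3) * frac
  got <- counts$count[counts$feature_id == "cen_I"]
  expect_lt(abs(got - expected), 5 * sqrt(expected))  # Poisson tolerance
})

test_that("rpkm follows count / kb / million and its invariances", {
  cat_ <- feature_catalog(
    data.frame(feature_id = "f", chrom = "c", start = 0, end = 1000,
               strand = ".", fclass = "mRNA"),
    chrom_sizes = c(c = 10000))
  counts <- data.frame(feature_id = "f", antibody = "H3", condition = "wt",
                       replicate = "rep1", count = 10)
  lib <- data.frame(sample = "H3.wt.rep1", library_size = 1e6)
  expect_equal(rpkm(counts, cat_, lib)$rpkm, 10)
  # zero reads -> zero rpkm
  counts0 <- counts; counts0$count <- 0
  expect_equal(rpkm(counts0, cat_, lib)$rpkm, 0)
  # doubling counts and library size leaves rpkm unchanged
  counts2 <- counts; counts2$count <- 20
  lib2 <- lib; lib2$library_size <- 2e6
  expect_equal(rpkm(counts2, cat_, lib2)$rpkm, rpkm(counts, cat_, lib)$rpkm)
  # zero-length feature errors
  bad <- feature_catalog(
    data.frame(feature_id = "f", chrom = "c", start = 5, end = 5,
               strand = ".", fclass = "mRNA"), c(c = 10))
  expect_error(rpkm(counts, bad, lib), "zero-length")
})

test_that("h3_normalize guards division by zero with an undefined flag", {
  expect_equal(h3_normalize(10, 5), 2)
  expect_equal(h3_normalize(0, 5), 0)
  expect_true(is.na(h3_normalize(3, 0)))
  expect_error(h3_normalize(c(1, 2), 1), "aligned")
})

test_that("detect_enriched flags planted islands and is monotone in the factor", {
  sc <- small_config(seed = 19)
  cat_ <- make_genome(sc)
  tr <- plant_truth(sc, cat_)
  occ <- occupancy_table(simulate_chip_reads(sc, tr, cat_, "wt"), cat_)
  islands <- features_by_class(cat_, "island")$feature_id
  planted <- intersect(tr$methylated_wt, islands)
  enr2 <- detect_enriched(occ, enrichment_factor = 2)
  expect_setequal(intersect(enr2$feature_id[enr2$enriched], islands),
                  planted)
  # monotone: a stricter factor can only shrink the flagged set
  enr4 <- detect_enriched(occ, enrichment_factor = 4)
  expect_true(all(enr4$feature_id[enr4$enriched] %in%
                    enr2$feature_id[enr2$enriched]))
  enr_huge <- detect_enriched(occ, enrichment_factor = 1e6)
  expect_equal(sum(enr_huge$enriched), 0)
})

test_that("compare_conditions recovers lost domains and spares distal sub-blocks", {
  sc <- small_config(seed = 23)
  cat_ <- make_genome(sc)
  tr <- plant_truth(sc, cat_)
  occ <- occupancy_table(
    rbind(simulate_chip_reads(sc, tr, cat_, "wt"),
          simulate_chip_reads(sc, tr, cat_, "mutant")), cat_)
  cmp <- compare_conditions(occ)
  het <- cmp[cmp$fclass %in% HETEROCHROMATIN_CLASSES, ]
  reduced <- het$feature_id[het$call == "reduced"]
  expect_setequal(reduced, tr$lost_in_mutant)
  distal <- grep("_distal$", het$feature_id, value = TRUE)
  expect_length(intersect(reduced, distal), 0)
  # methylation loss is not a histone-occupancy loss
  lost <- het[het$feature_id %in% tr$lost_in_mutant, ]
  expect_true(all(abs(log2(lost$h3_fold)) < 0.5))
})

test_that("undefined ratios are reported not-evaluable, never dropped", {
  occ <- data.frame(
    feature_id = rep(c("f1", "f2"), each = 2),
    fclass = "island",
    condition = rep(c("wt", "mutant"), 2),
    replicate = "rep1",
    h3_count = c(10, 10, 0, 10),
    me2_count = c(10, 10, 5, 10),
    h3_rpkm = c(1, 1, 0, 1),
    me2_rpkm = c(1, 1, 0.5, 1),
    me2_h3_ratio = c(1, 1, NA, 1),
    stringsAsFactors = FALSE)
  cmp <- compare_conditions(occ)
  expect_equal(nrow(cmp), 2)
  expect_equal(cmp$call[cmp$feature_id == "f2"], "not_evaluable")
})

test_that("class_summary keeps every feature and labels untouched classes", {
  sc <- small_config(seed = 25)
  cat_ <- make_genome(sc)
  tr <- plant_truth(sc, cat_)
  occ <- occupancy_table(
    rbind(simulate_chip_reads(sc, tr, cat_, "wt"),
          simulate_chip_reads(sc, tr, cat_, "mutant")), cat_)
  cmp <- compare_conditions(occ)
  cs <- class_summary(cmp)
  expect_equal(nrow(cs$features), nrow(cmp))
  cen <- cs$classes[cs$classes$fclass == "centromere", ]
  expect_equal(cen$verdict, "unaffected")
  tf <- cs$classes[cs$classes$fclass %in% c("transposon", "HOOD"), ]
  expect_true(all(tf$verdict == "unaffected"))
  isl <- cs$classes[cs$classes$fclass == "island", ]
  expect_equal(isl$verdict, "affected")
  # centromere fold is ~1
  cen_row <- cs$features[cs$features$feature_id == "cen_I", ]
  expect_lt(abs(log2(cen_row$fold)), 0.5)
})

test_that("H3 normalization cancels a non-uniform nucleosome profile", {
  sc <- small_config(seed = 27, chip = list(h3_profile = "variable"))
  cat_ <- make_genome(sc)
  tr <- plant_truth(sc, cat_)
  occ <- occupancy_table(simulate_chip_reads(sc, tr, cat_, "wt"), cat_)
  islands <- features_by_class(cat_, "island")$feature_id
  planted <- intersect(tr$methylated_wt, islands)
  enr <- detect_enriched(occ)
  expect_setequal(intersect(enr$feature_id[enr$enriched], islands), planted)
})

test_that("bedGraph ratio track is written and importable", {
  sc <- small_config(seed = 29)
  cat_ <- make_genome(sc)
  tr <- plant_truth(sc, cat_)
  reads <- simulate_chip_reads(sc, tr, cat_, "wt")
  reads <- reads[reads$replicate == "rep1", ]
  f <- tempfile(fileext = ".bedGraph")
  write_ratio_bedgraph(reads, cat_$chrom_sizes, f, bin_size = 5000)
  gr <- rtracklayer::import(f, format = "bedGraph")
  expect_gt(length(gr), 0)
  expect_true(all(gr$score >= 0))
})
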