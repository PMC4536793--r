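# Small configurations used across tests: desk-scale versions of the
# generator, with the same structure as the full defaults.

small_config <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(
    seed = seed, n_genes = 400,
    ripchip = list(n_targets = 20),
    expression = list(n_de = 30),
    chip = list(n_reads_per_channel = 50000L))
  for (nm in names(args)) {
    if (nm %in% c("ripchip", "expression", "chip", "qpcr")) {
      defaults[[nm]] <- utils::modifyList(defaults[[nm]] %||% list(),
                                          args[[nm]])
    } else defaults[[nm]] <- args[[nm]]
  }
  do.call(synth_config, defaults)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A tiny hand-built catalog for interval tests.
tiny_catalog <- function() {
  feature_catalog(
    data.frame(
      feature_id = c("geneA", "geneB", "isl1"),
      chrom = c("chr1", "chr1", "chr2"),
      start = c(100, 500, 50),
      end = c(200, 800, 150),
      strand = c("+", "-", "."),
      fclass = c("mRNA", "mRNA", "island")),
    chrom_sizes = c(chr1 = 1000, chr2 = 400))
}

# Read table builder for counting tests.
make_reads <- function(chrom, start, length = 50, antibody = "H3K9me2",
                       condition = "wt", replicate = "rep1") {
  data.frame(chrom = chrom, start = start, length = length,
             strand = "+", antibody = antibody, condition = condition,
             replicate = replicate, stringsAsFactors = FALSE)
}
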