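sample_key <- function(reads) {
  paste(reads$antibody, reads$condition, reads$replicate, sep = ".")
}

#' Count reads per feature and sample
#'
#' Assigns each read to every feature whose interval contains the read's
#' start position (single-point rule: counts are additive and boundary
#' behaviour is exact; overlapping features each receive the read).  Reads
#' hitting no feature still count toward the library size.
#'
#' @param reads read data.frame (`chrom`, `start`, `length`, `strand`,
#'   `antibody`, `condition`, `replicate`), e.g. from
#'   [simulate_chip_reads()] or [read_aligned_reads()].
#' @param catalog a [feature_catalog()]; read chromosomes must be known to
#'   it.
#' @param assign `"start"` (default) or `"midpoint"`: which single point of
#'   the read determines feature membership.
#' @return data.frame in long form: `feature_id`, `antibody`, `condition`,
#'   `replicate`, `count`, with attribute `library_sizes` (data.frame of
#'   total aligned reads per sample).
#' @export
count_reads <- function(reads, catalog, assign = c("start", "midpoint")) {
  assign <- match.arg(assign)
  stopifnot(inherits(catalog, "feature_catalog"))
  unknown <- setdiff(unique(reads$chrom), names(catalog$chrom_sizes))
  if (length(unknown) > 0)
    stop("reads on chromosome(s) unknown to the catalog: ",
         paste(unknown, collapse = ", "))
  gr_feat <- catalog_granges(catalog)
  pt <- if (assign == "start") reads$start
        else reads$start + floor(reads$length / 2)
  keys <- sample_key(reads)
  uk <- unique(keys)
  rows <- lapply(uk, function(k) {
    sel <- keys == k
    gr_pt <- GenomicRanges::GRanges(
      seqnames = reads$chrom[sel],
      ranges = IRanges::IRanges(start = pt[sel] + 1, width = 1))
    cnt <- GenomicRanges::countOverlaps(gr_feat, gr_pt, ignore.strand = TRUE)
    first <- which(sel)[1]
    data.frame(feature_id = catalog$features$feature_id,
               antibody = reads$antibody[first],
               condition = reads$condition[first],
               replicate = reads$replicate[first],
               count = as.numeric(cnt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  lib <- data.frame(sample = uk,
                    library_size = as.numeric(table(keys)[uk]),
                    stringsAsFactors = FALSE)
  attr(out, "library_sizes") <- lib
  out
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count / (feature length in kb) / (library size in millions)`.
#' The library size is the total number of aligned reads in the sample, not
#' only the in-feature reads.
#'
#' @param counts long-form count table from [count_reads()].
#' @param catalog the matching [feature_catalog()].
#' @param library_sizes data.frame (`sample`, `library_size`); defaults to
#'   the attribute attached by [count_reads()].
#' @return `counts` with an added `rpkm` column.
#' @export
rpkm <- function(counts, catalog, library_sizes = attr(counts, "library_sizes")) {
  stopifnot(inherits(catalog, "feature_catalog"))
  if (is.null(library_sizes))
    stop("library sizes are required (none attached to the count table)")
  if (any(library_sizes$library_size <= 0))
    stop("library sizes must be positive")
  f <- catalog$features
  len <- setNames(f$end - f$start, f$feature_id)
  if (any(len <= 0))
    stop("zero-length feature(s): ",
         paste(names(len)[len <= 0], collapse = ", "))
  key <- paste(counts$antibody, counts$condition, counts$replicate, sep = ".")
  lib <- setNames(library_sizes$library_size, library_sizes$sample)
  if (any(!key %in% names(lib)))
    stop("missing library size for sample(s): ",
         paste(unique(key[!key %in% names(lib)]), collapse = ", "))
  counts$rpkm <- counts$count / (len[counts$feature_id] / 1000) /
    (lib[key] / 1e6)
  counts
}

#' H3-normalized methylation density
#'
#' Divides the H3K9me2 RPKM of each feature by its histone H3 RPKM,
#' cancelling nucleosome occupancy.  Where the H3 RPKM is zero the ratio is
#' undefined and reported as `NA` (never coerced to zero).
#'
#' @param me2_rpkm,h3_rpkm aligned numeric vectors of RPKM values.
#' @return numeric vector of ratios (`NA` = undefined).
#' @export
h3_normalize <- function(me2_rpkm, h3_rpkm) {
  if (length(me2_rpkm) != length(h3_rpkm))
    stop("me2 and H3 RPKM vectors must be aligned (same length)")
  ifelse(h3_rpkm > 0, me2_rpkm / h3_rpkm, NA_real_)
}

#' Per-feature occupancy table
#'
#' The full feature-level quantification: read counts and RPKM per channel,
#' and the H3-normalized H3K9me2 density, per condition and replicate.
#'
#' @param reads read data.frame covering the `H3` and `H3K9me2` channels
#'   (the `input` channel, if present, is counted but not used in the
#'   ratio).
#' @param catalog a [feature_catalog()].
#' @param assign point-assignment rule, see [count_reads()].
#' @return data.frame of class `occupancy_table`: `feature_id`, `fclass`,
#'   `condition`, `replicate`, `h3_count`, `me2_count`, `h3_rpkm`,
#'   `me2_rpkm`, `me2_h3_ratio`; attribute `library_sizes`.
#' @export
occupancy_table <- function(reads, catalog, assign = "start") {
  counts <- rpkm(count_reads(reads, catalog, assign = assign), catalog)
  h3 <- counts[counts$antibody == "H3", ]
  me2 <- counts[counts$antibody == "H3K9me2", ]
  if (nrow(h3) == 0 || nrow(me2) == 0)
    stop("both H3 and H3K9me2 channels are required")
  key <- function(d) paste(d$feature_id, d$condition, d$replicate, sep = "|")
  m <- match(key(me2), key(h3))
  if (any(is.na(m)))
    stop("H3 and H3K9me2 samples are not aligned across conditions/replicates")
  f <- catalog$features
  out <- data.frame(
    feature_id = me2$feature_id,
    fclass = f$fclass[match(me2$feature_id, f$feature_id)],
    condition = me2$condition,
    replicate = me2$replicate,
    h3_count = h3$count[m],
    me2_count = me2$count,
    h3_rpkm = h3$rpkm[m],
    me2_rpkm = me2$rpkm,
    me2_h3_ratio = h3_normalize(me2$rpkm, h3$rpkm[m]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "library_sizes") <- attr(counts, "library_sizes")
  class(out) <- c("occupancy_table", "data.frame")
  out
}

#' Feature classes treated as heterochromatin
#'
#' The classes excluded from background estimation and summarized in the
#' per-class occupancy reports.
#'
#' @export
HETEROCHROMATIN_CLASSES <- c("island", "subtelomere", "centromere",
                             "transposon", "HOOD")

#' Detect features enriched above background
#'
#' The background methylation level is the median H3-normalized ratio over
#' all non-heterochromatin features (genes and other euchromatic
#' intervals), estimated per replicate.  A feature is flagged enriched when
#' its ratio is at least `enrichment_factor` times the background in every
#' replicate of the condition ("reproducible"); `min_replicates` relaxes
#' this to a k-of-n rule.
#'
#' @param occ an [occupancy_table()].
#' @param condition condition to evaluate (default `"wt"`).
#' @param enrichment_factor fold over background required (default 2).
#' @param background_classes feature classes that define the background.
#' @param min_replicates number of replicates in which the cutoff must
#'   hold; default all replicates present.
#' @return data.frame `feature_id`, `fclass`, `mean_ratio`, `n_replicates`,
#'   `n_above`, `enriched`; attribute `background` (per-replicate medians).
#' @export
detect_enriched <- function(occ, condition = "wt", enrichment_factor = 2,
                            background_classes = c("mRNA", "ncRNA", "other"),
                            min_replicates = NULL) {
  d <- occ[occ$condition == condition, ]
  if (nrow(d) == 0) stop("no samples for condition '", condition, "'")
  reps <- unique(d$replicate)
  bg_rows <- d$fclass %in% background_classes
  if (!any(bg_rows))
    stop("cannot estimate background: no features of class ",
         paste(background_classes, collapse = "/"))
  bg <- vapply(reps, function(r)
    median(d$me2_h3_ratio[bg_rows & d$replicate == r], na.rm = TRUE),
    numeric(1))
  if (is.null(min_replicates)) min_replicates <- length(reps)
  above <- vapply(reps, function(r) {
    dr <- d[d$replicate == r, ]
    ok <- !is.na(dr$me2_h3_ratio) &
      dr$me2_h3_ratio >= enrichment_factor * bg[[r]]
    setNames(ok, dr$feature_id)
  }, logical(sum(d$replicate == reps[1])))
  ids <- rownames(above)
  n_above <- rowSums(above)
  mean_tab <- tapply(d$me2_h3_ratio, d$feature_id,
                     function(x) mean(x, na.rm = TRUE))
  res <- data.frame(
    feature_id = ids,
    fclass = d$fclass[match(ids, d$feature_id)],
    mean_ratio = unname(mean_tab[ids]),
    n_replicates = length(reps),
    n_above = unname(n_above),
    enriched = unname(n_above >= min_replicates),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "background") <- bg
  res
}

#' Compare H3K9me2 occupancy between conditions
#'
#' For every feature, forms the mutant/wild-type ratio of H3-normalized
#' H3K9me2 densities over all replicate pairings.  A feature is called
#' `reduced` when the fold is at most `1/reduction_factor` in every pairing
#' ("clear and reproducible"), `increased` symmetrically, otherwise
#' `unchanged`; a feature with an undefined ratio in either condition is
#' reported `not_evaluable`, never silently dropped.  Histone H3 RPKM folds
#' are computed in parallel so that methylation loss can be distinguished
#' from loss of nucleosome occupancy.
#'
#' @param occ an [occupancy_table()] containing both conditions.
#' @param wt,mutant condition labels.
#' @param reduction_factor fold threshold (default 2).
#' @return data.frame: `feature_id`, `fclass`, `ratio_wt`, `ratio_mutant`
#'   (geometric means over replicates), `fold` (geometric mean over
#'   pairings), `h3_fold`, `call`.
#' @export
compare_conditions <- function(occ, wt = "wt", mutant = "mutant",
                               reduction_factor = 2) {
  a <- occ[occ$condition == wt, ]
  b <- occ[occ$condition == mutant, ]
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("both conditions must be present in the occupancy table")
  ids <- unique(occ$feature_id)
  if (!setequal(unique(a$feature_id), unique(b$feature_id)))
    stop("conditions do not cover the same feature set")
  fcl <- setNames(occ$fclass, occ$feature_id)[ids]
  # feature x replicate matrices per condition
  to_mat <- function(d, col) {
    reps <- sort(unique(d$replicate))
    m <- vapply(reps, function(r) {
      dr <- d[d$replicate == r, ]
      setNames(dr[[col]], dr$feature_id)[ids]
    }, numeric(length(ids)))
    matrix(m, nrow = length(ids), dimnames = list(ids, reps))
  }
  ra <- to_mat(a, "me2_h3_ratio"); rb <- to_mat(b, "me2_h3_ratio")
  h3a <- to_mat(a, "h3_rpkm"); h3b <- to_mat(b, "h3_rpkm")
  # all wt x mutant replicate pairings, as feature x pairing matrices
  pairings <- expand.grid(i = seq_len(ncol(rb)), j = seq_len(ncol(ra)))
  folds <- vapply(seq_len(nrow(pairings)),
                  function(p) rb[, pairings$i[p]] / ra[, pairings$j[p]],
                  numeric(length(ids)))
  h3_folds <- vapply(seq_len(nrow(pairings)),
                     function(p) h3b[, pairings$i[p]] / h3a[, pairings$j[p]],
                     numeric(length(ids)))
  folds <- matrix(folds, nrow = length(ids))
  h3_folds <- matrix(h3_folds, nrow = length(ids))
  evaluable <- rowSums(!is.finite(folds)) == 0
  gm_rows <- function(m) exp(rowMeans(log(m)))
  fold <- ifelse(evaluable, gm_rows(folds), NA_real_)
  call <- rep("not_evaluable", length(ids))
  red <- evaluable & rowSums(folds > 1 / reduction_factor) == 0
  inc <- evaluable & rowSums(folds < reduction_factor) == 0
  call[evaluable] <- "unchanged"
  call[red] <- "reduced"
  call[inc] <- "increased"
  out <- data.frame(
    feature_id = ids,
    fclass = unname(fcl),
    ratio_wt = exp(rowMeans(log(ra), na.rm = TRUE)),
    ratio_mutant = exp(rowMeans(log(rb), na.rm = TRUE)),
    fold = fold,
    h3_fold = ifelse(rowSums(!is.finite(h3_folds)) == 0,
                     gm_rows(h3_folds), NA_real_),
    call = call,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-class summary of condition comparisons
#'
#' One row per feature grouped by feature class, with a per-class verdict:
#' a class with no reduced or increased calls is reported `unaffected`.
#'
#' @param comparison data.frame from [compare_conditions()].
#' @return list with `features` (the comparison rows ordered by class) and
#'   `classes` (data.frame `fclass`, `n`, `n_reduced`, `n_increased`,
#'   `n_not_evaluable`, `verdict`).
#' @export
class_summary <- function(comparison) {
  ord <- order(factor(comparison$fclass, levels = FEATURE_CLASSES))
  feats <- comparison[ord, ]
  rownames(feats) <- NULL
  cls <- lapply(split(feats, factor(feats$fclass, levels = unique(feats$fclass))),
                function(d) data.frame(
                  fclass = d$fclass[1], n = nrow(d),
                  n_reduced = sum(d$call == "reduced"),
                  n_increased = sum(d$call == "increased"),
                  n_not_evaluable = sum(d$call == "not_evaluable"),
                  verdict = if (any(d$call %in% c("reduced", "increased")))
                    "affected" else "unaffected",
                  stringsAsFactors = FALSE))
  classes <- do.call(rbind, cls)
  rownames(classes) <- NULL
  list(features = feats, classes = classes)
}

#' Binned me2/H3 ratio track
#'
#' Bins the genome, computes the H3-normalized H3K9me2 read-density ratio
#' per bin from raw reads, and writes a bedGraph track for genome-browser
#' comparison of conditions.  Bins without H3 reads get no record.
#'
#' @param reads read data.frame (one condition) with `H3` and `H3K9me2`
#'   channels; replicates are pooled.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param path output bedGraph file.
#' @param bin_size bin width in bp.
#' @return `path`, invisibly.
#' @export
write_ratio_bedgraph <- function(reads, chrom_sizes, path, bin_size = 500) {
  bins <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    starts <- seq(0, chrom_sizes[[ch]] - 1, by = bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, chrom_sizes[[ch]]),
               stringsAsFactors = FALSE)
  }))
  count_in_bins <- function(r) {
    if (nrow(r) == 0) return(numeric(nrow(bins)))
    key <- paste(r$chrom, floor(r$start / bin_size))
    bk <- paste(bins$chrom, floor(bins$start / bin_size))
    as.numeric(table(factor(key, levels = bk)))
  }
  me2 <- count_in_bins(reads[reads$antibody == "H3K9me2", ])
  h3 <- count_in_bins(reads[reads$antibody == "H3", ])
  score <- ifelse(h3 > 0, (me2 / sum(me2)) / (h3 / sum(h3)), NA)
  keep <- !is.na(score)
  gr <- GenomicRanges::GRanges(
    seqnames = bins$chrom[keep],
    ranges = IRanges::IRanges(start = bins$start[keep] + 1,
                              end = bins$end[keep]),
    score = score[keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write an occupancy table as TSV
#'
#' @param occ an [occupancy_table()] or any result data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_occupancy_tsv <- function(occ, path) {
  write.table(as.data.frame(occ), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
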