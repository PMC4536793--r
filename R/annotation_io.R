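#' Recognised genomic feature classes
#'
#' The feature classes used throughout the package: protein-coding and
#' non-coding genes, heterochromatin islands, subtelomeric blocks, centromere
#' blocks, transposons and HOODs (heterochromatin domains that appear upon
#' nuclear-exosome inactivation), plus a catch-all.
#'
#' @export
FEATURE_CLASSES <- c("mRNA", "ncRNA", "island", "subtelomere", "centromere",
                     "transposon", "HOOD", "other")

#' Construct a feature catalog
#'
#' A feature catalog is the unit of all interval-based quantification: an
#' ordered table of labelled genomic intervals (0-based, half-open
#' coordinates, BED convention) together with chromosome lengths.
#'
#' @param features data.frame with columns `feature_id`, `chrom`, `start`,
#'   `end`, `strand` (one of `+`, `-`, `.`) and `fclass`
#'   (one of [FEATURE_CLASSES]).
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#'   If `NULL`, lengths are inferred as the maximum feature end per
#'   chromosome.
#' @return An object of class `feature_catalog`: a list with elements
#'   `features` and `chrom_sizes`.
#' @seealso [validate_catalog()] for invariant checking,
#'   [load_features()] / [write_features()] for file I/O.
#' @export
feature_catalog <- function(features, chrom_sizes = NULL) {
  required <- c("feature_id", "chrom", "start", "end", "strand", "fclass")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols) > 0)
    stop("features is missing columns: ", paste(missing_cols, collapse = ", "))
  features <- as.data.frame(features)[, required]
  features$feature_id <- as.character(features$feature_id)
  features$chrom <- as.character(features$chrom)
  features$start <- as.numeric(features$start)
  features$end <- as.numeric(features$end)
  features$strand <- as.character(features$strand)
  features$fclass <- as.character(features$fclass)
  bad_strand <- !features$strand %in% c("+", "-", ".")
  if (any(bad_strand))
    stop("invalid strand for feature(s): ",
         paste(features$feature_id[bad_strand], collapse = ", "))
  bad_class <- !features$fclass %in% FEATURE_CLASSES
  if (any(bad_class))
    stop("unknown feature class for: ",
         paste(features$feature_id[bad_class], collapse = ", "))
  if (is.null(chrom_sizes)) {
    chrom_sizes <- if (nrow(features) > 0)
      vapply(split(features$end, features$chrom), max, numeric(1))
    else numeric(0)
  }
  rownames(features) <- NULL
  structure(list(features = features, chrom_sizes = chrom_sizes),
            class = "feature_catalog")
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat("feature_catalog:", nrow(x$features), "features on",
      length(x$chrom_sizes), "chromosome(s)\n")
  tab <- table(factor(x$features$fclass, levels = FEATURE_CLASSES))
  tab <- tab[tab > 0]
  if (length(tab) > 0)
    cat(paste0("  ", names(tab), ": ", as.integer(tab), collapse = "\n"), "\n")
  invisible(x)
}

#' Class-restricted view of a catalog
#'
#' Returns the features of one or more classes, preserving catalog order.
#'
#' @param catalog a [feature_catalog()].
#' @param fclass character vector of classes to keep.
#' @return data.frame of matching features, in input order.
#' @export
features_by_class <- function(catalog, fclass) {
  stopifnot(inherits(catalog, "feature_catalog"))
  catalog$features[catalog$features$fclass %in% fclass, , drop = FALSE]
}

#' Check a catalog against its invariants
#'
#' Verifies that coordinates are ordered (`0 <= start < end`), that feature
#' ids are unique, and that every feature lies within its chromosome bounds.
#' Violations are returned, not raised, so a catalog can be audited in full.
#'
#' @param catalog a [feature_catalog()].
#' @return character vector of violation descriptions; empty if all
#'   invariants hold.
#' @export
validate_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "feature_catalog"))
  f <- catalog$features
  out <- character(0)
  bad <- f$start < 0 | f$start >= f$end
  if (any(bad))
    out <- c(out, paste0("feature '", f$feature_id[bad],
                         "' has invalid coordinates [", f$start[bad], ", ",
                         f$end[bad], ")"))
  dup <- unique(f$feature_id[duplicated(f$feature_id)])
  if (length(dup) > 0)
    out <- c(out, paste0("duplicate feature_id '", dup, "'"))
  known <- f$chrom %in% names(catalog$chrom_sizes)
  if (any(!known))
    out <- c(out, paste0("feature '", f$feature_id[!known],
                         "' on unknown chromosome '", f$chrom[!known], "'"))
  if (any(known)) {
    k <- which(known)
    over <- f$end[k] > catalog$chrom_sizes[f$chrom[k]]
    if (any(over))
      out <- c(out, paste0("feature '", f$feature_id[k][over],
                           "' extends past the end of chromosome '",
                           f$chrom[k][over], "'"))
  }
  out
}

# Internal: catalog -> GRanges (1-based closed, as GRanges requires).
catalog_granges <- function(catalog) {
  f <- catalog$features
  sl <- catalog$chrom_sizes
  gr <- GenomicRanges::GRanges(
    seqnames = f$chrom,
    ranges = IRanges::IRanges(start = f$start + 1, end = f$end),
    strand = ifelse(f$strand == ".", "*", f$strand),
    feature_id = f$feature_id,
    fclass = f$fclass,
    seqlengths = if (length(sl) > 0) sl else NULL)
  gr
}

#' Read a feature catalog from BED6, GFF3 or TSV
#'
#' Coordinates are converted to the internal 0-based half-open convention at
#' the boundary: BED is kept as is, GFF3 (1-based closed) start positions are
#' decremented, and TSV input is expected to already use the internal
#' convention (columns `feature_id`, `chrom`, `start`, `end`, `strand`,
#' `fclass`).  BED carries no feature class, so all BED features load as
#' class `"other"` unless `default_class` says otherwise; GFF3 round-trips
#' the class through the `type` column.
#'
#' @param path input file.
#' @param format one of `"BED"`, `"GFF"`, `"TSV"`.
#' @param chrom_sizes optional named vector of chromosome lengths, or the
#'   path to a two-column TSV (chrom, length); inferred from the features if
#'   omitted.
#' @param default_class feature class assigned when the format does not
#'   carry one (BED).
#' @return a [feature_catalog()].
#' @export
load_features <- function(path, format = c("BED", "GFF", "TSV"),
                          chrom_sizes = NULL, default_class = "other") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1)
    chrom_sizes <- read_chrom_sizes(chrom_sizes)

  lines <- readLines(path)
  if (!any(nzchar(lines) & !grepl("^(#|track|browser)", lines))) {
    empty <- data.frame(feature_id = character(0), chrom = character(0),
                        start = numeric(0), end = numeric(0),
                        strand = character(0), fclass = character(0))
    return(feature_catalog(empty, chrom_sizes = chrom_sizes %||% numeric(0)))
  }

  if (format == "BED") {
    check_bed_lines(path)
    gr <- rtracklayer::import(path, format = "BED")
    f <- data.frame(
      feature_id = if (!is.null(gr$name)) as.character(gr$name)
                   else paste0("feature_", seq_along(gr)),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = GenomicRanges::end(gr),
      strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
      fclass = default_class,
      stringsAsFactors = FALSE)
  } else if (format == "GFF") {
    gr <- rtracklayer::import(path, format = "gff3")
    id <- if (!is.null(gr$ID)) as.character(gr$ID)
          else if (!is.null(gr$Name)) as.character(gr$Name)
          else paste0("feature_", seq_along(gr))
    cls <- if (!is.null(gr$type)) as.character(gr$type) else default_class
    cls[!cls %in% FEATURE_CLASSES] <- default_class
    f <- data.frame(
      feature_id = id,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,   # 1-based closed -> 0-based half-open
      end = GenomicRanges::end(gr),
      strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
      fclass = cls,
      stringsAsFactors = FALSE)
  } else {
    f <- read.delim(path, stringsAsFactors = FALSE)
    req <- c("feature_id", "chrom", "start", "end", "strand", "fclass")
    if (!all(req %in% names(f)))
      stop("TSV feature file must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(f) > 0 && any(f$start >= f$end)) {
    bad <- which(f$start >= f$end)
    stop("validation error: start >= end after conversion for feature(s): ",
         paste(f$feature_id[bad], collapse = ", "))
  }
  feature_catalog(f, chrom_sizes = chrom_sizes)
}

# Light line-level validation so malformed BED is reported by line number.
check_bed_lines <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  for (i in which(keep)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3 ||
        is.na(suppressWarnings(as.numeric(fields[2]))) ||
        is.na(suppressWarnings(as.numeric(fields[3]))))
      stop("parse error in ", path, " at line ", i)
  }
  invisible(TRUE)
}

#' Write a feature catalog to BED6 or GFF3
#'
#' Round-trip property: reloading the written file with [load_features()]
#' reproduces coordinates and feature ids exactly.  BED does not carry the
#' feature class; GFF3 preserves it in the `type` column.
#'
#' @param catalog a [feature_catalog()].
#' @param path output file.
#' @param format `"BED"` or `"GFF"`.
#' @return `path`, invisibly.
#' @export
write_features <- function(catalog, path, format = c("BED", "GFF")) {
  format <- match.arg(format)
  stopifnot(inherits(catalog, "feature_catalog"))
  gr <- catalog_granges(catalog)
  if (format == "BED") {
    names(gr) <- NULL
    gr$name <- gr$feature_id
    gr$score <- 0
    gr$feature_id <- NULL
    gr$fclass <- NULL
    rtracklayer::export(gr, path, format = "BED")
  } else {
    names(gr) <- NULL
    gr$type <- gr$fclass
    gr$ID <- gr$feature_id
    gr$source <- "hetseq"
    gr$feature_id <- NULL
    gr$fclass <- NULL
    rtracklayer::export(gr, path, format = "gff3")
  }
  invisible(path)
}

#' Read / write chromosome sizes
#'
#' Two-column headerless TSV: chromosome name, length in bp.
#'
#' @param path file path.
#' @return named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("chrom sizes file must have two columns")
  setNames(as.numeric(d[[2]]), as.character(d[[1]]))
}

#' @rdname read_chrom_sizes
#' @param chrom_sizes named numeric vector to write.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  write.table(data.frame(names(chrom_sizes), as.numeric(chrom_sizes)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
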