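#' Construct an enrichment matrix
#'
#' An enrichment matrix is a plain numeric matrix of log2 two-channel ratios
#' with probe/gene ids as row names and replicate sample ids as column
#' names, tagged with its channel semantics: `"rip"` (IP versus total RNA)
#' or `"expression"` (mutant versus wild type).  Missing values (`NA`) are
#' permitted and preserved by all transformations.
#'
#' @param values numeric matrix with row and column names.
#' @param channel_semantics `"rip"` or `"expression"`.
#' @return the matrix with a `channel_semantics` attribute.
#' @export
enrichment_matrix <- function(values, channel_semantics = c("rip", "expression")) {
  channel_semantics <- match.arg(channel_semantics)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("enrichment matrix needs row (gene/probe) and column (sample) names")
  attr(values, "channel_semantics") <- channel_semantics
  values
}

check_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expected a numeric matrix of log2 ratios")
  invisible(m)
}

#' Mean-centre each array
#'
#' Subtracts from each column (array) its mean over non-missing cells, the
#' first step of RIP-chip enrichment calling on log-transformed ratios.
#' Idempotent; missing cells stay missing.
#'
#' @param m enrichment matrix (log2 scale).
#' @return the centred matrix.
#' @export
mean_centre <- function(m) {
  check_matrix(m)
  n_ok <- colSums(!is.na(m))
  if (any(n_ok < 2))
    stop("cannot centre column(s) with fewer than 2 non-missing values: ",
         paste(colnames(m)[n_ok < 2], collapse = ", "))
  centred <- sweep(m, 2, colMeans(m, na.rm = TRUE))
  attributes_keep(centred, m)
}

attributes_keep <- function(new, old) {
  for (a in c("channel_semantics", "intensities"))
    attr(new, a) <- attr(old, a)
  new
}

#' Per-array z-scores
#'
#' Standardizes each column: `z = (value - column mean) / column SD`, using
#' the sample standard deviation (n - 1 denominator) over non-missing cells.
#' On a mean-centred matrix this reduces to `value / SD`.  A zero-SD
#' (constant) column yields all-zero z-scores by convention.
#'
#' @param m enrichment matrix, normally already [mean_centre()]d.
#' @return matrix of z-scores, same shape as `m`.
#' @export
zscores <- function(m) {
  check_matrix(m)
  n_ok <- colSums(!is.na(m))
  if (any(n_ok < 2))
    stop("cannot compute z-scores for column(s) with fewer than 2 ",
         "non-missing values: ", paste(colnames(m)[n_ok < 2], collapse = ", "))
  mu <- colMeans(m, na.rm = TRUE)
  s <- apply(m, 2, sd, na.rm = TRUE)
  z <- sweep(m, 2, mu)
  z <- sweep(z, 2, ifelse(s > 0, s, 1), "/")
  z[, s == 0] <- 0
  dimnames(z) <- dimnames(m)
  z
}

#' Call bound targets from replicate z-scores
#'
#' A gene/probe is called a target when its z-score exceeds `threshold`
#' (strictly) in at least `k` of the `n` replicates — both of two
#' duplicates, or two out of three triplicates, in the canonical uses.
#' Rows with a missing z-score in some replicates are evaluated on the
#' remaining replicates against the same `k` (an undetected probe cannot
#' contribute evidence).
#'
#' @param z matrix of z-scores (rows = genes/probes, columns = replicates).
#' @param threshold z-score cutoff (default 2.5).
#' @param rule integer vector `c(k, n)`; `n` must equal the number of
#'   replicate columns.  Defaults to `c(2, ncol(z))`, i.e. 2-of-2 for
#'   duplicates and 2-of-3 for triplicates.
#' @return an object of class `target_call_set`: list with `called_ids`,
#'   `zscores`, `threshold`, `rule`.
#' @export
call_targets <- function(z, threshold = 2.5, rule = c(2, ncol(z))) {
  check_matrix(z)
  k <- rule[1]; n <- rule[2]
  if (k > n) stop("rule k must not exceed n")
  if (n != ncol(z))
    stop("rule n (", n, ") must equal the number of replicate columns (",
         ncol(z), ")")
  hits <- rowSums(z > threshold, na.rm = TRUE)
  called <- rownames(z)[hits >= k]
  structure(list(called_ids = called, zscores = z,
                 threshold = threshold, rule = c(k = k, n = n)),
            class = "target_call_set")
}

#' @export
print.target_call_set <- function(x, ...) {
  cat("target_call_set:", length(x$called_ids), "of", nrow(x$zscores),
      "rows called (z >", x$threshold, "in >=", x$rule["k"], "of",
      x$rule["n"], "replicates)\n")
  invisible(x)
}

#' Enrichment relative to a reference gene
#'
#' Subtracts the reference gene's log2 enrichment from each query gene,
#' per replicate — the display convention of per-target enrichment
#' normalized to a housekeeping reference (e.g. actin) — and reports the
#' median over queries per replicate.
#'
#' @param m enrichment matrix (log2 scale).
#' @param reference_id row id of the reference gene.
#' @param query_ids row ids of the query genes.
#' @return list with `relative` (queries x replicates matrix of log2
#'   enrichment relative to the reference) and `median` (per-replicate
#'   median over queries).
#' @export
relative_enrichment <- function(m, reference_id, query_ids) {
  check_matrix(m)
  if (!reference_id %in% rownames(m))
    stop("reference gene '", reference_id, "' not present in the matrix")
  missing_q <- setdiff(query_ids, rownames(m))
  if (length(missing_q) > 0)
    stop("query gene(s) not present: ", paste(missing_q, collapse = ", "))
  rel <- sweep(m[query_ids, , drop = FALSE], 2, m[reference_id, ])
  list(relative = rel, median = apply(rel, 2, median, na.rm = TRUE))
}

#' Read / write an enrichment matrix as TSV
#'
#' Rows are gene/probe ids, columns replicate samples, values log2 ratios;
#' empty cells are missing values.
#'
#' @param path file path.
#' @param channel_semantics semantics tag applied on read.
#' @return the matrix ([read_enrichment_tsv()]) or `path`
#'   ([write_enrichment_tsv()]), invisibly for the writer.
#' @export
read_enrichment_tsv <- function(path, channel_semantics = c("rip", "expression")) {
  d <- read.delim(path, row.names = 1, check.names = FALSE)
  enrichment_matrix(as.matrix(d), match.arg(channel_semantics))
}

#' @rdname read_enrichment_tsv
#' @param m matrix to write.
#' @export
write_enrichment_tsv <- function(m, path) {
  d <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
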