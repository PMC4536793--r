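#' Delta-delta-Ct relative quantification
#'
#' Computes the relative abundance of a target locus versus a reference
#' locus between IP and input fractions from a complete quartet of qPCR
#' critical cycles:
#' `ddCt = (Ct_target_IP - Ct_ref_IP) - (Ct_target_INPUT - Ct_ref_INPUT)`
#' and `ratio = 2^-ddCt` (PCR efficiency fixed at 2, as the formula
#' assumes).  The `"literal"` variant instead exponentiates
#' `-(Ct_target_IP - Ct_ref_IP) - (Ct_target_INPUT - Ct_ref_INPUT)`,
#' i.e. the sum rather than the difference of the two deltas, for
#' comparison with sources whose printed exponent groups the terms that
#' way.
#'
#' @param ct data.frame with columns `gene` (`target`/`reference`),
#'   `fraction` (`IP`/`INPUT`) and `ct` (cycles), holding exactly one
#'   complete quartet (one replicate).
#' @param variant `"ddct"` (standard difference-of-differences, default) or
#'   `"literal"`.
#' @return linear-scale ratio (dimensionless).
#' @export
delta_delta_ct <- function(ct, variant = c("ddct", "literal")) {
  variant <- match.arg(variant)
  need <- expand.grid(gene = c("target", "reference"),
                      fraction = c("IP", "INPUT"),
                      stringsAsFactors = FALSE)
  get_ct <- function(g, f) {
    v <- ct$ct[ct$gene == g & ct$fraction == f]
    if (length(v) == 0)
      stop("missing Ct cell: gene '", g, "', fraction '", f, "'")
    if (length(v) > 1)
      stop("more than one Ct for gene '", g, "', fraction '", f,
           "': pass one replicate at a time (see ddct_summary)")
    v
  }
  for (i in seq_len(nrow(need))) get_ct(need$gene[i], need$fraction[i])
  if (any(ct$ct <= 0)) stop("Ct values must be positive cycle counts")
  d_ip <- get_ct("target", "IP") - get_ct("reference", "IP")
  d_in <- get_ct("target", "INPUT") - get_ct("reference", "INPUT")
  expo <- if (variant == "ddct") -(d_ip - d_in) else -d_ip - d_in
  2^expo
}

#' Summarize replicated delta-delta-Ct quantifications
#'
#' Computes the per-replicate ratio first, then aggregates: geometric mean
#' by default (ratios live on a log scale), with the across-replicate
#' standard deviation of the ratios (NA for a single replicate).
#'
#' @param ct data.frame with columns `gene`, `fraction`, `replicate`, `ct`.
#' @param aggregate `"geometric"` or `"arithmetic"` mean.
#' @param variant passed to [delta_delta_ct()].
#' @return list with `ratios` (named per-replicate vector), `mean_ratio`,
#'   `sd_ratio`, `n`.
#' @export
ddct_summary <- function(ct, aggregate = c("geometric", "arithmetic"),
                         variant = "ddct") {
  aggregate <- match.arg(aggregate)
  if (is.null(ct$replicate)) ct$replicate <- "rep1"
  reps <- unique(ct$replicate)
  ratios <- vapply(reps, function(r)
    delta_delta_ct(ct[ct$replicate == r, ], variant = variant), numeric(1))
  names(ratios) <- reps
  if (length(ratios) == 0) stop("no complete replicate quartet found")
  mean_ratio <- if (aggregate == "geometric") exp(mean(log(ratios)))
                else mean(ratios)
  list(ratios = ratios, mean_ratio = mean_ratio,
       sd_ratio = if (length(ratios) > 1) sd(ratios) else NA_real_,
       n = length(ratios))
}

#' Read / write qPCR Ct tables
#'
#' TSV with columns `gene`, `fraction`, `replicate`, `ct`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_ct_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "fraction", "replicate", "ct")
  if (!all(req %in% names(d)))
    stop("Ct table must have columns: ", paste(req, collapse = ", "))
  d
}

#' @rdname read_ct_tsv
#' @param ct data.frame to write.
#' @export
write_ct_tsv <- function(ct, path) {
  write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
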