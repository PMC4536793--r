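#' Loess-normalize two-channel log-ratios
#'
#' Removes intensity-dependent dye bias per array: the locally weighted
#' regression of the log-ratio (M) on the mean spot intensity (A) is fitted
#' and subtracted, column by column.  The workhorse fit is
#' [limma::loessFit()], the standard implementation for two-colour arrays.
#'
#' @param m enrichment matrix of log2 ratios.
#' @param intensities matrix of mean spot intensities, same dimensions as
#'   `m`; defaults to the `intensities` attribute attached by
#'   [simulate_expression()].
#' @param span loess span (fraction of points in each local window).
#' @return the normalized matrix (missing cells preserved).
#' @export
loess_normalize <- function(m, intensities = attr(m, "intensities"),
                            span = 0.3) {
  check_matrix(m)
  if (is.null(intensities))
    stop("no intensities supplied and none attached to the matrix")
  if (!all(dim(intensities) == dim(m)))
    stop("intensities must have the same dimensions as the ratio matrix")
  out <- m
  for (j in seq_len(ncol(m))) {
    ok <- is.finite(m[, j]) & is.finite(intensities[, j])
    if (sum(ok) < 10)
      stop("cannot fit loess for array '", colnames(m)[j],
           "': fewer than 10 finite points")
    fit <- limma::loessFit(m[ok, j], intensities[ok, j], span = span)
    out[ok, j] <- fit$residuals
  }
  attributes_keep(out, m)
}

#' Median-centre each array
#'
#' Subtracts each column's median over non-missing cells, the normalization
#' used for RNA-stability expression ratios.  Idempotent.
#'
#' @param m enrichment matrix (log2 scale).
#' @return the centred matrix.
#' @export
median_centre <- function(m) {
  check_matrix(m)
  n_ok <- colSums(!is.na(m))
  if (any(n_ok == 0))
    stop("cannot centre empty column(s): ",
         paste(colnames(m)[n_ok == 0], collapse = ", "))
  med <- apply(m, 2, median, na.rm = TRUE)
  attributes_keep(sweep(m, 2, med), m)
}

row_mean_se <- function(m) {
  n <- rowSums(!is.na(m))
  mean <- rowMeans(m, na.rm = TRUE)
  dev <- m - mean
  ss <- rowSums(dev * dev, na.rm = TRUE)
  sdv <- sqrt(ss / pmax(n - 1, 1))
  se <- sdv / sqrt(n)
  mean[n < 2] <- NA
  se[n < 2] <- NA
  list(mean = mean, se = se, n = n)
}

# SAM's s0 selection: choose the se-quantile that minimizes the coefficient
# of variation of the d-statistic's spread across strata of se.
choose_s0_cv <- function(mean, se, probs = seq(0, 1, by = 0.05)) {
  ok <- is.finite(mean) & is.finite(se)
  cand <- unique(quantile(se[ok], probs, na.rm = TRUE))
  strata <- cut(se[ok], breaks = unique(quantile(se[ok], seq(0, 1, 0.1))),
                include.lowest = TRUE)
  cv <- vapply(cand, function(s0) {
    d <- mean[ok] / (se[ok] + s0)
    v <- tapply(d, strata, mad)
    v <- v[is.finite(v) & v > 0]
    if (length(v) < 2) return(Inf)
    sd(v) / base::mean(v)
  }, numeric(1))
  if (all(!is.finite(cv))) return(median(se[ok]))
  cand[which.min(cv)]
}

#' SAM-style moderated statistic
#'
#' One-class relative-difference statistic on replicate log-ratios:
#' `d = mean / (se + s0)` per gene, where `se` is the standard error of the
#' replicates and the exchangeability constant `s0` damps genes with
#' accidentally tiny variance.  By default `s0` is chosen the way the SAM
#' method tunes it: among quantiles of the gene-wise standard errors, pick
#' the one minimizing the coefficient of variation of the d-statistic's
#' spread across strata of `se`; alternatively use a fixed quantile or an
#' explicit value.
#'
#' @param m enrichment matrix (replicate log2 ratios; one-class design, the
#'   null hypothesis is mean log-ratio zero).
#' @param s0 explicit exchangeability constant; overrides `s0_method`.
#' @param s0_method `"cv"` (SAM tuning, default) or `"quantile"`.
#' @param s0_quantile quantile of gene-wise standard errors used when
#'   `s0_method = "quantile"`.
#' @return named numeric vector of d-statistics (NA for genes with fewer
#'   than 2 finite replicates), with attributes `s0`, `mean_log2fc`, `se`.
#' @export
sam_statistic <- function(m, s0 = NULL, s0_method = c("cv", "quantile"),
                          s0_quantile = 0.05) {
  check_matrix(m)
  s0_method <- match.arg(s0_method)
  st <- row_mean_se(m)
  if (is.null(s0)) {
    if (all(!is.finite(st$se)))
      stop("no gene has >= 2 finite replicates; cannot derive s0")
    s0 <- if (s0_method == "cv") choose_s0_cv(st$mean, st$se)
          else quantile(st$se, s0_quantile, na.rm = TRUE)
  }
  d <- st$mean / (st$se + s0)
  names(d) <- rownames(m)
  attr(d, "s0") <- unname(s0)
  attr(d, "mean_log2fc") <- st$mean
  attr(d, "se") <- st$se
  d
}

#' Differential-expression calls with a permutation FDR
#'
#' Builds the null distribution of the SAM d-statistic by sign-flipping
#' whole arrays (the one-class permutation: each permutation multiplies
#' every column by an independent random sign, which under symmetric ratio
#' noise is an exchangeable null).  The per-gene q-value is the median,
#' across permutations, of the number of null `|d*|` values at or above
#' the gene's `|d|`, divided by the number of observed `|d|` values at or
#' above it, capped at 1.  Genes with `q < fdr_threshold` are called and
#' split by sign of the mean log-ratio.
#'
#' @param m enrichment matrix of replicate log2 ratios (mutant / wild type).
#' @param n_permutations number of sign-flip permutations (>= 50).
#' @param seed integer seed; mandatory, the permutation null is stochastic.
#' @param fdr_threshold FDR at which genes are called (default 0.005).
#' @param s0,s0_method,s0_quantile passed to [sam_statistic()]; the same
#'   `s0` is used for observed and null statistics.
#' @return data.frame with one row per gene: `gene_id`, `mean_log2fc`,
#'   `fold_change` (linear scale), `d_stat`, `q_value`, `direction`
#'   (`up`/`down`/`none`), `called`; attribute `s0`.
#' @export
sam_fdr <- function(m, n_permutations = 100, seed = NULL,
                    fdr_threshold = 0.005, s0 = NULL,
                    s0_method = c("cv", "quantile"), s0_quantile = 0.05) {
  check_matrix(m)
  if (is.null(seed))
    stop("a seed is required: the permutation null is stochastic and ",
         "results must be reproducible")
  if (n_permutations < 50)
    stop("need at least 50 permutations for a usable null")
  d <- sam_statistic(m, s0 = s0, s0_method = match.arg(s0_method),
                     s0_quantile = s0_quantile)
  s0_used <- attr(d, "s0")
  mean_fc <- attr(d, "mean_log2fc")
  ad <- abs(as.numeric(d))
  fin <- is.finite(ad)
  sorted_obs <- sort(ad[fin])
  # #{|d| >= x} with exact tie handling.
  count_ge <- function(x, sorted) length(sorted) -
    findInterval(x, sorted, left.open = TRUE)
  obs_count <- rep(NA_real_, length(ad))
  obs_count[fin] <- count_ge(ad[fin], sorted_obs)

  k <- ncol(m)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      signs <- sample(c(-1, 1), k, replace = TRUE)
      db <- sam_statistic(sweep(m, 2, signs, "*"), s0 = s0_used)
      sorted_null <- sort(abs(as.numeric(db)))
      out <- rep(NA_real_, length(ad))
      out[fin] <- count_ge(ad[fin], sorted_null)
      out
    }, numeric(length(ad)))
  })
  null_counts <- matrix(null_counts, nrow = length(ad))
  med_null <- apply(null_counts, 1, median, na.rm = TRUE)
  q <- pmin(1, med_null / obs_count)
  called <- !is.na(q) & q < fdr_threshold
  direction <- ifelse(!called, "none", ifelse(mean_fc > 0, "up", "down"))
  res <- data.frame(
    gene_id = rownames(m),
    mean_log2fc = mean_fc,
    fold_change = 2^mean_fc,
    d_stat = as.numeric(d),
    q_value = q,
    direction = direction,
    called = called,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "s0") <- s0_used
  res
}

#' Linear-scale fold change for one gene
#'
#' `2^(mean log2 ratio)` across replicates.
#'
#' @param m enrichment matrix of log2 ratios.
#' @param gene_id row id.
#' @return linear fold change.
#' @export
fold_change <- function(m, gene_id) {
  check_matrix(m)
  if (!gene_id %in% rownames(m))
    stop("gene '", gene_id, "' not present in the matrix")
  v <- m[gene_id, ]
  if (all(is.na(v))) stop("all replicates missing for gene '", gene_id, "'")
  2^mean(v, na.rm = TRUE)
}

#' Write differential-expression results as TSV
#'
#' @param res data.frame from [sam_fdr()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_de_tsv <- function(res, path) {
  write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
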