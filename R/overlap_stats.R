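#' Expected overlap of two random gene lists
#'
#' The mean overlap of two randomly drawn lists of sizes `n_a` and `n_b`
#' from a universe of `n_universe` genes — the hypergeometric mean
#' `n_a * n_b / n_universe`, the number quoted in parentheses next to
#' observed Venn overlaps.
#'
#' @param n_a,n_b list sizes.
#' @param n_universe universe size (> 0).
#' @return expected overlap (real-valued count).
#' @export
expected_overlap <- function(n_a, n_b, n_universe) {
  if (n_universe <= 0) stop("universe size must be positive")
  if (n_a > n_universe || n_b > n_universe)
    stop("list sizes must not exceed the universe size")
  if (n_a < 0 || n_b < 0) stop("list sizes must be non-negative")
  n_a * n_b / n_universe
}

#' Fisher's exact test for gene-set overlap
#'
#' One-sided (enrichment) Fisher's exact test on the 2x2 membership table
#' of two gene sets within an explicit universe; the p-value equals the
#' hypergeometric upper tail `P(X >= observed)`.  The universe is a
#' mandatory input — all comparisons depend on it, and no hidden default is
#' sensible.
#'
#' @param set_a,set_b character vectors of gene ids; must be subsets of
#'   `universe`.
#' @param universe character vector of all gene ids under consideration.
#' @return an object of class `overlap_result`: list with `set_a_size`,
#'   `set_b_size`, `universe_size`, `observed`, `expected`, `p_value`.
#' @export
fisher_overlap <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  set_a <- unique(set_a); set_b <- unique(set_b)
  stray <- setdiff(c(set_a, set_b), universe)
  if (length(stray) > 0)
    stop("ids not in the universe: ", paste(stray, collapse = ", "))
  n <- length(universe)
  a <- length(set_a); b <- length(set_b)
  obs <- length(intersect(set_a, set_b))
  tab <- matrix(c(obs, a - obs, b - obs, n - a - b + obs), nrow = 2)
  p <- fisher.test(tab, alternative = "greater")$p.value
  structure(list(set_a_size = a, set_b_size = b, universe_size = n,
                 observed = obs, expected = expected_overlap(a, b, n),
                 p_value = p),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap: %d observed (%.3g expected) | sets %d & %d in universe %d | p = %.3g\n",
    x$observed, x$expected, x$set_a_size, x$set_b_size, x$universe_size,
    x$p_value))
  invisible(x)
}

#' Pairwise overlap summary
#'
#' Computes [fisher_overlap()] for every unordered pair of named gene sets
#' against a common universe — the tabular form of a panel of pairwise
#' Venn comparisons.
#'
#' @param named_sets named list of character vectors (>= 2 sets, unique
#'   names).
#' @param universe character vector of all gene ids.
#' @return data.frame with one row per pair: `set_a`, `set_b`,
#'   `set_a_size`, `set_b_size`, `universe_size`, `observed`, `expected`,
#'   `p_value`.
#' @export
overlap_summary <- function(named_sets, universe) {
  if (length(named_sets) < 2) stop("need at least 2 sets")
  nm <- names(named_sets)
  if (is.null(nm) || any(!nzchar(nm))) stop("all sets must be named")
  if (anyDuplicated(nm)) stop("duplicate set names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  pairs <- utils::combn(nm, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    r <- fisher_overlap(named_sets[[pairs[1, i]]], named_sets[[pairs[2, i]]],
                        universe)
    data.frame(set_a = pairs[1, i], set_b = pairs[2, i],
               set_a_size = r$set_a_size, set_b_size = r$set_b_size,
               universe_size = r$universe_size, observed = r$observed,
               expected = r$expected, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read / write gene lists
#'
#' One gene id per line, the interchange format for overlap inputs.
#'
#' @param path file path.
#' @return character vector of ids.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @param ids character vector to write.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}
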