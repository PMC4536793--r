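mat <- function(..., ids = NULL) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  rownames(m) <- ids %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- paste0("rep", seq_len(ncol(m)))
  m
}

test_that("mean_centre subtracts per-column means and is idempotent", {
  m <- mat(c(1, 2, 3))
  expect_equal(unname(mean_centre(m)[, 1]), c(-1, 0, 1))
  expect_equal(mean_centre(mean_centre(m)), mean_centre(m))
  # missing cells: mean over non-missing, NA preserved
  m2 <- mat(c(5, NA, 7))
  expect_equal(unname(mean_centre(m2)[, 1]), c(-1, NA, 1))
  # under-populated column errors and names the column
  m3 <- mat(c(1, NA, NA))
  expect_error(mean_centre(m3), "rep1")
})

test_that("zscores standardize with the sample SD and handle degenerate columns", {
  m <- mat(c(-1, 0, 1))
  expect_equal(unname(zscores(m)[, 1]), c(-1, 0, 1))  # SD of {-1,0,1} = 1
  m2 <- mat(c(-2, -2, 4))
  expect_equal(unname(zscores(m2)[, 1]),
               c(-2, -2, 4) / sd(c(-2, -2, 4)), tolerance = 1e-12)
  expect_equal(unname(zscores(m2)[, 1]),
               c(-0.57735, -0.57735, 1.154701), tolerance = 1e-5)
  const <- mat(c(2, 2, 2))
  expect_true(all(zscores(const) == 0))
})

test_that("call_targets applies the k-of-n replicate-consistency rule", {
  z <- mat(c(2.6, 2.6, 2.4), c(2.7, 2.4, 2.6), ids = c("a", "b", "c"))
  got <- call_targets(z, threshold = 2.5, rule = c(2, 2))
  expect_equal(got$called_ids, "a")   # both replicates above for a only

  z3 <- mat(c(2.6, 2.4), c(2.4, 2.4), c(2.6, 2.45), ids = c("a", "b"))
  got3 <- call_targets(z3, threshold = 2.5, rule = c(2, 3))
  expect_equal(got3$called_ids, "a")  # two out of three

  # exactly at the threshold does not count (strictly above)
  z_eq <- mat(c(2.5), c(2.5), ids = "a")
  expect_length(call_targets(z_eq, rule = c(2, 2))$called_ids, 0)

  # missing replicate: remaining replicates evaluated against the same k
  z_na <- mat(c(2.6, 2.6), c(NA, 2.6), c(2.6, NA), ids = c("a", "b"))
  expect_equal(call_targets(z_na, rule = c(2, 3))$called_ids, c("a", "b"))

  expect_error(call_targets(z, rule = c(3, 2)), "k must not exceed")
  expect_error(call_targets(z, rule = c(2, 5)), "must equal the number")
})

test_that("calls are invariant to column shifts and scalings", {
  sc <- small_config(seed = 8)
  tr <- plant_truth(sc, make_genome(sc))
  m <- simulate_ripchip(sc, tr)
  base <- call_targets(zscores(mean_centre(m)))$called_ids

  shifted <- sweep(m, 2, c(3, -1), "+")
  expect_equal(call_targets(zscores(mean_centre(shifted)))$called_ids, base)

  scaled <- sweep(m, 2, c(2.5, 0.3), "*")
  expect_equal(zscores(mean_centre(scaled)), zscores(mean_centre(m)),
               tolerance = 1e-12)
})

test_that("noise-free input recovers the planted target set exactly", {
  sc <- small_config(seed = 9, ripchip = list(noise_sd = 0))
  tr <- plant_truth(sc, make_genome(sc))
  m <- simulate_ripchip(sc, tr)
  called <- call_targets(zscores(mean_centre(m)))$called_ids
  expect_setequal(called, tr$target_ids)
})

test_that("relative enrichment normalizes to the reference gene", {
  m <- mat(c(3, 2, 4, 6, 1), c(3, 2, 4, 6, 1),
           ids = c("q0", "q1", "q2", "q3", "ref"))
  r <- relative_enrichment(m, "ref", c("q1", "q2", "q3"))
  expect_equal(unname(r$relative[, 1]), c(1, 3, 5))
  expect_equal(unname(r$median), c(3, 3))  # median of {1,3,5} per replicate
  self <- relative_enrichment(m, "ref", "ref")
  expect_true(all(self$relative == 0))
  expect_error(relative_enrichment(m, "nope", "q1"), "not present")
})

test_that("enrichment matrices round-trip through TSV with missing cells", {
  m <- mat(c(1.5, NA, -0.25), c(0, 2, NA), ids = c("a", "b", "c"))
  f <- tempfile(fileext = ".tsv")
  write_enrichment_tsv(m, f)
  back <- read_enrichment_tsv(f, "rip")
  expect_identical(dimnames(back), dimnames(m))
  attr(back, "channel_semantics") <- NULL
  expect_equal(back, m)
})
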