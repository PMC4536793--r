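demat <- function(..., ids = NULL) {
  m <- do.call(cbind, list(...))
  rownames(m) <- ids %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- paste0("rep", seq_len(ncol(m)))
  m
}

test_that("median_centre zeroes each column's median and is idempotent", {
  m <- demat(c(1, 2, 4))
  expect_equal(unname(median_centre(m)[, 1]), c(-1, 0, 2))
  m4 <- demat(c(-5, 0, 5, 100))
  expect_equal(unname(median_centre(m4)[, 1]), c(-7.5, -2.5, 2.5, 97.5))
  expect_equal(median_centre(median_centre(m4)), median_centre(m4))
  expect_error(median_centre(demat(c(NA_real_, NA_real_))), "empty")
})

test_that("loess normalization removes a planted intensity-dependent bias", {
  sc <- small_config(seed = 21, n_genes = 2000,
                     expression = list(n_de = 0, dye_bias_amplitude = 1))
  tr <- plant_truth(sc, make_genome(sc))
  m <- simulate_expression(sc, tr)
  a <- attr(m, "intensities")
  raw_trend <- stats::lowess(a[, 1], m[, 1], f = 0.3)
  expect_gt(max(abs(raw_trend$y)), 0.5)
  norm <- loess_normalize(m)
  norm_trend <- stats::lowess(a[, 1], norm[, 1], f = 0.3)
  expect_lt(max(abs(norm_trend$y)), 0.1)
  # a constant offset is a trend: output comes back centred near 0
  flat <- m * 0 + 2
  out <- loess_normalize(flat, intensities = a)
  expect_lt(max(abs(out)), 1e-6)
  expect_error(loess_normalize(m[1:5, , drop = FALSE],
                               intensities = a[1:5, , drop = FALSE]),
               "fewer than 10")
})

test_that("the SAM d statistic follows mean / (se + s0)", {
  m <- demat(c(2, 0, 1), c(4, 0, 1), ids = c("a", "b", "c"))
  d <- sam_statistic(m, s0 = 0.1)
  # {2,4}: mean 3, se 1 -> 3/1.1
  expect_equal(unname(d["a"]), 3 / 1.1, tolerance = 1e-12)
  expect_equal(unname(d["b"]), 0)
  # zero variance: d = mean/s0
  expect_equal(unname(d["c"]), 1 / 0.1, tolerance = 1e-12)
  # gene with < 2 finite replicates gets NA
  m2 <- demat(c(1, NA), c(NA, NA), ids = c("a", "b"))
  expect_true(is.na(sam_statistic(m2, s0 = 0.1)["b"]))
})

test_that("fold_change is 2^(mean log2 ratio) and ignores replicate order", {
  m <- demat(c(0.7, 0), c(1.0, 1), ids = c("a", "b"))
  expect_equal(fold_change(m, "a"), 2^0.85, tolerance = 1e-12)
  expect_equal(fold_change(m[, c(2, 1)], "a"), fold_change(m, "a"))
  expect_equal(fold_change(demat(c(0), c(0), ids = "a"), "a"), 1)
  expect_error(fold_change(m, "zz"), "not present")
})

test_that("sam_fdr is reproducible under a fixed seed and requires one", {
  sc <- small_config(seed = 31)
  tr <- plant_truth(sc, make_genome(sc))
  m <- simulate_expression(sc, tr)
  expect_error(sam_fdr(m), "seed")
  r1 <- sam_fdr(m, seed = 5)
  r2 <- sam_fdr(m, seed = 5)
  expect_identical(r1, r2)
  expect_true(all(r1$q_value >= 0 & r1$q_value <= 1, na.rm = TRUE))
  expect_true(all(r1$q_value[r1$called] < 0.005))
})

test_that("a single all-zero gene gets q = 1 and is not called", {
  m <- demat(c(0), c(0), c(0), ids = "a")
  r <- sam_fdr(m, seed = 1, s0 = 0.1)
  expect_equal(r$q_value, 1)
  expect_false(r$called)
})

test_that("planted effects are recovered and split by direction", {
  sc <- small_config(seed = 33)
  tr <- plant_truth(sc, make_genome(sc))
  r <- sam_fdr(simulate_expression(sc, tr), seed = 9)
  up_planted <- tr$de$gene_id[tr$de$log2fc > 0]
  down_planted <- tr$de$gene_id[tr$de$log2fc < 0]
  expect_gt(mean(up_planted %in% r$gene_id[r$direction == "up"]), 0.9)
  expect_gt(mean(down_planted %in% r$gene_id[r$direction == "down"]), 0.9)
  expect_false(any(r$direction[r$called] == "none"))
})
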