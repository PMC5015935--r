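test_that("normalization scales every column to the total and keeps proportions", {
  m <- matrix(c(1, 1, 2, 10, 20, 70), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  cm <- count_matrix(m)
  norm <- normalize_counts(cm, total = 4)
  expect_equal(unname(norm$counts[, "s1"]), c(1, 1, 2))
  expect_true(norm$normalized)
  norm6 <- normalize_counts(cm)
  expect_equal(unname(colSums(norm6$counts)), c(1e6, 1e6), tolerance = 1e-6)
  # proportion-preservation oracle: direct column shares
  expect_equal(unname(norm6$counts[, "s2"] / 1e6), c(0.1, 0.2, 0.7))
  zero <- count_matrix(matrix(0, 2, 1, dimnames = list(c("a", "b"), "s")))
  expect_error(normalize_counts(zero), "zero-sum")
})

test_that("log2 fold change handles pseudocounts and misalignment", {
  expect_equal(unname(log2fc(c(a = 5, b = 9), c(a = 5, b = 9))), c(0, 0))
  expect_equal(unname(log2fc(c(a = 100), c(a = 400), pseudocount = 0)), 2)
  expect_equal(unname(log2fc(c(a = 0), c(a = 0), pseudocount = 1)), 0)
  expect_error(log2fc(c(a = 1, b = 2), c(a = 1, z = 2)), "differ")
  # name-order mismatch is realigned, not misread
  expect_equal(unname(log2fc(c(a = 1, b = 2), c(b = 2, a = 1))), c(0, 0))
})

test_that("normalize then log2fc of identical samples is identically zero", {
  set.seed(2)
  m <- matrix(rpois(40, 300), nrow = 20)
  m <- cbind(m[, 1], m[, 1] * 3)  # same proportions, different depth
  dimnames(m) <- list(sprintf("e%02d", 1:20), c("ref", "end"))
  norm <- normalize_counts(count_matrix(m))
  expect_equal(unname(log2fc(norm$counts[, 1], norm$counts[, 2])),
               rep(0, 20))
})

test_that("barcode concordance reports sign agreement per ORF group", {
  out <- barcode_concordance(c(1.2, 0.8, 2.0, 1, -1, 0.5),
                             c("A", "A", "A", "B", "B", "C"))
  expect_equal(out$sign_agreement[out$orf_id == "A"], 1.0)
  expect_equal(out$sign_agreement[out$orf_id == "B"], 0.5)
  expect_true(is.na(out$sign_agreement[out$orf_id == "C"]))
  expect_error(barcode_concordance(numeric(0), character(0)), "empty")
})

test_that("recombination frequency counts non-library pairings", {
  lib <- assay_library()
  est <- measured_recombination_frequency(observed_pairs(lib, 65, 17), lib)
  expect_equal(est$f_measured, 17 / 65)
  expect_equal(est$n_recombined, 17)
  # unknown ids rejected
  bad <- data.frame(orf_id = "NOPE", bc_id = lib$clones$bc_id[1])
  expect_error(measured_recombination_frequency(bad, lib), "unknown id")
})

test_that("homozygous-virion correction follows the printed formula", {
  expect_equal(round(100 * correct_recombination_frequency(0.2615, 1 / 11), 2),
               28.53)
  expect_equal(round(100 * correct_recombination_frequency(0.0545, 1 / 11), 2),
               5.95)
  expect_equal(correct_recombination_frequency(0.3, 0), 0.3)
  # linear in f, bounded by 2x
  f <- seq(0, 0.5, 0.1)
  expect_equal(correct_recombination_frequency(f, 0.3), f * 1.3)
  expect_true(all(correct_recombination_frequency(f, 1) <= 2 * f))
})

test_that("rate comparison matches the published order of magnitude", {
  p <- compare_recombination(17, 65, 3, 55)
  expect_lt(p, 0.001)
  expect_gt(p, 1e-5)  # same order as 1.5e-4
  expect_equal(compare_recombination(10, 100, 10, 100), 1)
  expect_equal(compare_recombination(0, 33, 0, 20), 1)
  pf <- compare_recombination(17, 65, 3, 55, method = "fisher")
  expect_lt(pf, 0.01)
})

test_that("gc bias test matches the textbook Pearson formula", {
  # 5-point hand-computable dataset
  gc <- c(0.40, 0.45, 0.50, 0.55, 0.60)
  lfc <- c(0.1, -0.2, -0.1, -0.6, -0.5)
  manual_r <- sum((gc - mean(gc)) * (lfc - mean(lfc))) /
    sqrt(sum((gc - mean(gc))^2) * sum((lfc - mean(lfc))^2))
  report <- gc_bias_test(lfc, gc)
  expect_equal(report$pearson_r, manual_r)
  tstat <- manual_r * sqrt(3 / (1 - manual_r^2))
  expect_equal(report$p_value, 2 * pt(-abs(tstat), df = 3))
  # exact anti-correlation
  expect_equal(gc_bias_test(-gc, gc)$pearson_r, -1)
  # constant input reported as NA with a note
  cst <- gc_bias_test(rep(1, 5), gc)
  expect_true(is.na(cst$pearson_r))
  expect_match(cst$note, "constant")
})

test_that("gc bias r is affine-invariant and sign-flips under negation", {
  set.seed(4)
  gc <- runif(50, 0.3, 0.7)
  lfc <- -2 * gc + rnorm(50, sd = 0.2)
  r0 <- gc_bias_test(lfc, gc)$pearson_r
  expect_equal(gc_bias_test(3 * lfc + 1, gc)$pearson_r, r0)
  expect_equal(gc_bias_test(lfc, 0.5 * gc + 0.1)$pearson_r, r0)
  expect_equal(gc_bias_test(-lfc, gc)$pearson_r, -r0)
})

test_that("permuted gc labels show no correlation", {
  set.seed(9)
  gc <- rep(c(0.40, 0.45, 0.50, 0.55, 0.60), each = 200)
  lfc <- -3 * gc + rnorm(1000, sd = 0.3)
  hits <- vapply(1:40, function(i) {
    abs(gc_bias_test(lfc, sample(gc))$pearson_r) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("binned summaries use strata for discrete GC ladders", {
  gc <- rep(c(0.40, 0.45, 0.50, 0.55, 0.60), each = 10)
  lfc <- rep(1:5, each = 10) + rep(c(-0.1, 0.1), 25)
  rep5 <- gc_bias_test(lfc, gc)
  expect_equal(nrow(rep5$binned), 5)
  expect_equal(rep5$binned$n, rep(10, 5))
  expect_equal(rep5$binned$median, 1:5)
})

test_that("subpool distortion reports spread and rank correlation vs titer", {
  titers <- c(p1 = 1e6, p2 = 5e5, p3 = 1e5)
  # low-titer pools overrepresented: inverse relation
  reads <- c(rep(100, 4), rep(300, 4), rep(900, 4))
  pool <- rep(c("p1", "p2", "p3"), each = 4)
  out <- subpool_distortion(reads, pool, titers)
  expect_equal(out$spread, 9)
  expect_equal(out$spearman_rho, -1)
  flat <- subpool_distortion(rep(5, 6), rep(c("p1", "p2"), 3), titers)
  expect_equal(flat$spread, 1)
  expect_true(is.na(flat$spearman_rho))
  expect_error(subpool_distortion(reads, pool, titers[1:2]), "missing titer")
})
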