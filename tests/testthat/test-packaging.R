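test_that("homozygosity fraction matches brute-force pair enumeration", {
  expect_equal(homozygosity_fraction(1), 1)
  expect_equal(homozygosity_fraction(c(0.5, 0.5)), 0.5)
  set.seed(11)
  for (i in 1:5) {
    p <- runif(5)
    p <- p / sum(p)
    # enumerate all ordered genome pairs (i, j) and sum P(i) P(j) [i == j]
    brute <- sum(outer(p, p) * diag(5))
    expect_equal(homozygosity_fraction(p), brute)
  }
  expect_error(homozygosity_fraction(c(0.5, 0.2)), "sum to 1")
})

test_that("switch probability follows each model form and is monotone", {
  m <- recombination_model()
  expect_equal(switch_probability(m, default_design("5BC")), 0.2877)
  expect_equal(switch_probability(m, default_design("3BC")), 0.0600)
  expect_error(switch_probability(m, vector_design("other", 300)),
               "no fixed rate")

  lam <- 4e-4
  lin <- recombination_model("per_base_linear", lam)
  expect_equal(switch_probability(lin, vector_design("x", 0)), 0)
  expect_equal(switch_probability(lin, vector_design("x", 96)), lam * 96)
  expo <- recombination_model("per_base_exponential", lam)
  expect_equal(switch_probability(expo, vector_design("x", 0)), 0)
  expect_equal(switch_probability(expo, vector_design("x", 720)),
               1 - exp(-lam * 720))
  for (mod in list(lin, expo)) {
    bps <- c(0, 50, 96, 300, 720, 5000)
    ps <- vapply(bps, function(b) switch_probability(mod, vector_design("x", b)),
                 numeric(1))
    expect_true(all(diff(ps) >= 0))
    expect_true(all(ps >= 0 & ps <= 1))
  }
})

test_that("fitted per-base models pass near both calibration points", {
  expo <- recombination_model("per_base_exponential")
  p720 <- switch_probability(expo, vector_design("x", 720))
  p96 <- switch_probability(expo, vector_design("x", 96))
  expect_lt(abs(p720 - 0.2877), 0.05)
  expect_lt(abs(p96 - 0.0600), 0.05)
})

test_that("virion packaging converges to the analytic homozygous fraction", {
  lib <- assay_library()
  set.seed(123)
  v <- package_virions(lib, 1e5)
  h <- 1 / 11
  se <- sqrt(h * (1 - h) / 1e5)
  expect_lt(abs(mean(v$homozygous) - h), 3 * se)

  lib1 <- tiny_library(1)
  set.seed(1)
  expect_true(all(package_virions(lib1, 100)$homozygous))
  # degenerate abundance concentrates all mass on one clone
  libd <- tiny_library(3, abundance = c(1, 0, 0))
  set.seed(1)
  vd <- package_virions(libd, 200)
  expect_true(all(vd$genome_a == 1 & vd$genome_b == 1))
})

test_that("reverse transcription yields chimeras only from heterozygous virions", {
  lib <- assay_library()
  set.seed(5)
  hom <- reverse_transcribe(3, 3, p_switch = 1, lib)
  expect_false(hom$chimeric)
  het <- reverse_transcribe(3, 7, p_switch = 1, lib)
  expect_true(het$chimeric)
  # binomial check at p = 0.3 on heterozygous virions
  set.seed(5)
  n <- 1e5
  ga <- sample(1:11, n, replace = TRUE)
  gb <- ((ga + sample(1:10, n, replace = TRUE) - 1) %% 11) + 1  # always != ga
  res <- reverse_transcribe(ga, gb, p_switch = 0.3, lib)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mean(res$chimeric) - 0.3), 3 * se)
})

test_that("transduction drops the Poisson zero class and respects modes", {
  lib <- assay_library()
  set.seed(21)
  n_cells <- 1e5
  pt <- transduce(lib, n_cells, moi = 0.5)
  surviving <- length(unique(pt$cell_id)) / n_cells
  p_surv <- 1 - exp(-0.5)
  se <- sqrt(p_surv * (1 - p_surv) / n_cells)
  expect_lt(abs(surviving - p_surv), 3 * se)

  # individual-then-pooled can never produce a chimera, at any switch rate
  set.seed(22)
  m1 <- recombination_model("fixed_per_design", c("5BC" = 1))
  pt_ind <- transduce(lib, 2e4, 0.5, "individual_then_pooled", model = m1)
  expect_equal(sum(pt_ind$chimeric), 0)

  # pooled with zero switch probability: no chimeras either
  set.seed(23)
  m0 <- recombination_model("fixed_per_design", c("5BC" = 0))
  pt0 <- transduce(lib, 2e4, 0.5, "pooled", model = m0)
  expect_equal(sum(pt0$chimeric), 0)
  expect_error(transduce(lib, 0, 0.5), "n_cells")
})

test_that("detectable chimera rate equals p_switch times heterozygous fraction", {
  lib <- assay_library()
  p <- 0.2877
  h <- 1 / 11
  set.seed(31)
  pt <- transduce(lib, 3e5, 0.5, "pooled")
  expected <- p * (1 - h)
  se <- sqrt(expected * (1 - expected) / nrow(pt))
  expect_lt(abs(mean(pt$chimeric) - expected), 3 * se)
  # every chimeric row comes from a heterozygous virion
  expect_true(all(pt$genome_a[pt$chimeric] != pt$genome_b[pt$chimeric]))
})
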