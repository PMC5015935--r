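test_that("ORF-BC library generator honours shape, uniqueness and determinism", {
  set.seed(1)
  lib <- make_orf_bc_library(11, 1, 30, design = "5BC")
  expect_equal(nrow(lib$clones), 11)
  expect_equal(unique(nchar(lib$clones$bc_seq)), 30)
  expect_false(anyDuplicated(lib$clones$bc_seq) > 0)

  set.seed(2)
  lib5 <- make_orf_bc_library(8, 5)
  expect_true(all(table(lib5$clones$orf_id) == 5))

  set.seed(3)
  a <- make_orf_bc_library(6, 2)
  set.seed(3)
  b <- make_orf_bc_library(6, 2)
  expect_identical(a$clones, b$clones)
  set.seed(4)
  c_ <- make_orf_bc_library(6, 2)
  expect_false(any(c_$clones$bc_seq %in% a$clones$bc_seq))
  expect_error(make_orf_bc_library(10, 2, bc_len = 2), "exceed")
})

test_that("mock shRNA library has exact stratified composition", {
  lib <- mock_library_cached()
  expect_equal(nrow(lib$clones), 1000)
  tab <- table(lib$clones$gc_fraction)
  expect_equal(as.numeric(tab), rep(200, 5))
  expect_equal(as.numeric(names(tab)), c(0.40, 0.45, 0.50, 0.55, 0.60))
  # stratum GC is exact in the generated template sequences
  measured <- vapply(strsplit(lib$clones$bc_seq, ""), function(x) {
    mean(x %in% c("G", "C"))
  }, numeric(1))
  expect_equal(measured, lib$clones$gc_fraction)
})

test_that("growth expectation follows 2^(pds * s) and drift shrinks with representation", {
  a0 <- rep(0.1, 10)
  expect_equal(simulate_growth(a0, 0, 10, mode = "expectation"), a0)
  s <- c(0.1, rep(0, 9))
  out <- simulate_growth(a0, s, 10, mode = "expectation")
  expect_equal(out[1] / out[2], 2^(10 * 0.1) * (a0[1] / a0[2]))

  # resampling-variance oracle: drift variance ~ 1/representation
  drift_var <- function(repr, n_seeds = 40) {
    vals <- vapply(seq_len(n_seeds), function(i) {
      set.seed(1000 + i)
      simulate_growth(rep(1 / 50, 50), 0, 10, representation = repr)[1]
    }, numeric(1))
    var(vals)
  }
  v_small <- drift_var(50)
  v_big <- drift_var(500)
  ratio <- v_small / v_big
  expect_gt(ratio, 3)
  expect_lt(ratio, 30)
  expect_error(simulate_growth(a0, 0, 10, representation = 0.5),
               "representation")
})

test_that("screen scenarios are deterministic under a fixed seed", {
  lib <- mock_library_cached()
  cfg <- scenario_config(representation = 50, seed = 77)
  d1 <- run_screen_scenario(cfg, lib)
  d2 <- run_screen_scenario(cfg, lib)
  expect_identical(d1$counts$counts, d2$counts$counts)
  expect_identical(d1$provirus, d2$provirus)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_screen_dataset(d1, dir1)
  write_screen_dataset(d2, dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
})

test_that("clean scenarios recover graded ground-truth fold changes", {
  set.seed(55)
  lib <- make_orf_bc_library(100, 2, bc_len = 20)
  s <- fitness_spec(unique(lib$clones$orf_id))
  s[] <- runif(100, -0.15, 0.15)
  rhos <- vapply(1:5, function(seed) {
    cfg <- scenario_config(representation = 1000, seed = seed,
                           reference_mode = "equilibrated_cells")
    ds <- run_screen_scenario(cfg, lib, fitness = s)
    ncm <- normalize_counts(ds$counts)
    lfc <- log2fc(ncm$counts[, "reference"], ncm$counts[, "endpoint"])
    cor(ds$truth, lfc, method = "spearman", use = "complete.obs")
  }, numeric(1))
  expect_gte(median(rhos), 0.95)
})

test_that("higher recombination erodes barcode concordance for strong ORFs", {
  set.seed(66)
  lib <- make_orf_bc_library(20, 4, bc_len = 20)
  orfs <- unique(lib$clones$orf_id)
  s <- fitness_spec(orfs, enrichers = orfs[1:5], depleters = orfs[6:10])
  mean_agreement <- function(p_switch, seed) {
    model <- recombination_model("fixed_per_design",
                                 c("3BC" = p_switch))
    cfg <- scenario_config(representation = 300, seed = seed)
    ds <- run_screen_scenario(cfg, lib, fitness = s, model = model)
    ncm <- normalize_counts(ds$counts)
    lfc <- log2fc(ncm$counts[, "reference"], ncm$counts[, "endpoint"])
    bc <- barcode_concordance(lfc, lib$clones$orf_id)
    mean(bc$sign_agreement[bc$orf_id %in% orfs[1:10]], na.rm = TRUE)
  }
  diffs <- vapply(1:8, function(seed) {
    mean_agreement(0.06, seed) - mean_agreement(0.45, seed)
  }, numeric(1))
  # paired over seeds: lower switching rate gives higher concordance
  expect_gt(mean(diffs), 0)
  expect_gte(mean(diffs > 0), 0.75)
})

test_that("contaminated subpool references distort reads inversely to titer", {
  set.seed(77)
  titers <- c(pool1 = 1.6e6, pool2 = 8e5, pool3 = 4e5, pool4 = 2.8e5,
              pool5 = 2e5)
  lib <- make_orf_bc_library(100, 1, bc_len = 20, subpools = 5,
                             subpool_titers = titers)
  cfg <- scenario_config(representation = 200, seed = 5,
                         reference_mode = "early_cells")
  ds <- run_screen_scenario(cfg, lib)
  out <- subpool_distortion(ds$counts$counts[, "reference"],
                            lib$clones$subpool_id, titers)
  expect_lt(out$spearman_rho, 0)
  expect_gt(out$spread, 2)
  expect_lt(out$spread, 10)
})

test_that("recombination assay scenario reproduces both assay arms", {
  set.seed(10)
  ctrl <- run_recomb_assay_scenario(11, "5BC", "individual_then_pooled",
                                    n_sequenced = 33, p_switch = 0.9)
  expect_equal(ctrl$estimate$f_measured, 0)
  set.seed(11)
  pooled <- run_recomb_assay_scenario(11, "5BC", "pooled",
                                      n_sequenced = 1e5, p_switch = 0.2877)
  expected <- 0.2877 * (1 - 1 / 11)
  se <- sqrt(expected * (1 - expected) / 1e5)
  expect_lt(abs(pooled$estimate$f_measured - expected), 3 * se)
  set.seed(12)
  solo <- run_recomb_assay_scenario(1, "5BC", "pooled", n_sequenced = 50,
                                    p_switch = 0.9)
  expect_equal(solo$estimate$f_measured, 0)
})
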