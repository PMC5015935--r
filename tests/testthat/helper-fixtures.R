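# Small in-code fixtures shared across test files.

tiny_library <- function(n = 3, design = "3BC", abundance = NULL) {
  set.seed(99)
  make_orf_bc_library(n, 1, bc_len = 10, design = design,
                      abundance = abundance)
}

assay_library <- function(design = "5BC") {
  set.seed(7)
  make_orf_bc_library(11, 1, bc_len = 30, design = design)
}

# observed-pairs table with a chosen number of shuffled (recombined) rows
observed_pairs <- function(lib, n_total, n_recombined) {
  cl <- lib$clones
  n_ok <- n_total - n_recombined
  ok <- data.frame(
    orf_id = rep_len(cl$orf_id, n_ok),
    bc_id = rep_len(cl$bc_id, n_ok),
    stringsAsFactors = FALSE
  )
  # shift barcode by one clone: guaranteed non-library pairing (1 bc/orf)
  shift <- c(seq_len(nrow(cl))[-1], 1L)
  bad_idx <- rep_len(seq_len(nrow(cl)), n_recombined)
  bad <- data.frame(
    orf_id = cl$orf_id[bad_idx],
    bc_id = cl$bc_id[shift[bad_idx]],
    stringsAsFactors = FALSE
  )
  rbind(ok, bad)
}

mock_library_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(42)
      cache <<- make_mock_shrna_library()
    }
    cache
  }
})

run_mock_scenario <- function(reference_mode, seed = 1, benzonase_units = 0,
                              dna_input_fraction = 1, representation = 200,
                              fitness = NULL) {
  cfg <- scenario_config(representation = representation, seed = seed,
                         reference_mode = reference_mode,
                         benzonase_units = benzonase_units,
                         dna_input_fraction = dna_input_fraction)
  ds <- run_screen_scenario(cfg, mock_library_cached(), fitness = fitness)
  ncm <- normalize_counts(ds$counts)
  lfc <- log2fc(ncm$counts[, "reference"], ncm$counts[, "endpoint"])
  list(dataset = ds, lfc = lfc, gc = ncm$gc,
       report = gc_bias_test(lfc, ncm$gc))
}
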