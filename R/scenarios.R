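#' Fitness specification for a screen
#'
#' Per-ORF selection coefficients `s`, in units of relative growth per
#' population doubling: a clone with coefficient `s` grows `2^(1 + s)`-fold
#' per doubling of the neutral population, so its expected relative
#' abundance changes by `2^(pds * s)` over a screen. Presets model a potent
#' proliferation driver (enricher, CCND1-like), a growth suppressor
#' (depleter, CDKN1A-like), and neutral elements subject only to drift.
#'
#' @param orf_ids Character vector of ORF ids.
#' @param s Baseline coefficient for all ORFs (default 0, neutral).
#' @param enrichers,depleters ORF ids to assign the preset coefficients.
#' @param s_enrich,s_deplete Preset coefficients; defaults +0.1 / -0.1
#'   (a 2-fold expected shift over 10 doublings).
#' @return Named numeric vector of class `fitness_spec`.
#' @export
fitness_spec <- function(orf_ids, s = 0, enrichers = character(),
                         depleters = character(), s_enrich = 0.1,
                         s_deplete = -0.1) {
  vals <- stats::setNames(rep_len(s, length(orf_ids)), orf_ids)
  vals[enrichers] <- s_enrich
  vals[depleters] <- s_deplete
  if (any(1 + vals <= 0)) {
    stop("selection coefficients must satisfy 1 + s > 0", call. = FALSE)
  }
  structure(vals, class = c("fitness_spec", "numeric"))
}

random_unique_seqs <- function(n, len, gc_count = NULL) {
  seen <- character(0)
  out <- character(n)
  i <- 1L
  while (i <= n) {
    seq <- if (is.null(gc_count)) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    } else {
      chars <- c(sample(c("G", "C"), gc_count, replace = TRUE),
                 sample(c("A", "T"), len - gc_count, replace = TRUE))
      paste(sample(chars), collapse = "")
    }
    if (!seq %in% seen) {
      out[i] <- seq
      seen <- c(seen, seq)
      i <- i + 1L
    }
  }
  out
}

#' Generate a barcoded ORF library
#'
#' Random collision-free barcodes of uniform length (default 30 bp) paired
#' with ORFs, several barcodes per ORF, subpools assigned round-robin.
#'
#' @param n_orfs Number of ORFs.
#' @param bcs_per_orf Barcodes per ORF.
#' @param bc_len Barcode length (bp); default 30.
#' @param design Design label (`"5BC"`, `"3BC"`, `"TRE"`) or a
#'   [vector_design()].
#' @param subpools Number of subpools (round-robin over ORFs) or a character
#'   vector of subpool ids.
#' @param abundance Optional clone abundances (default equimolar).
#' @param subpool_titers Optional named titer vector.
#' @return A [screen_library()] with `n_orfs * bcs_per_orf` clones.
#' @examples
#' set.seed(1)
#' make_orf_bc_library(11, 1, design = "5BC") # the recombination-assay shape
#' @export
make_orf_bc_library <- function(n_orfs, bcs_per_orf = 1, bc_len = 30,
                                design = "3BC", subpools = 1,
                                abundance = NULL, subpool_titers = NULL) {
  stopifnot(n_orfs >= 1, bcs_per_orf >= 1, bc_len >= 1)
  n <- n_orfs * bcs_per_orf
  if (n > 4^min(bc_len, 30)) {
    stop("requested barcodes exceed 4^bc_len", call. = FALSE)
  }
  if (inherits(design, "vector_design")) {
    designs <- stats::setNames(list(design), design$name)
    design_label <- design$name
  } else {
    designs <- stats::setNames(list(default_design(design)), design)
    design_label <- design
  }
  pool_ids <- if (is.character(subpools)) subpools else
    paste0("pool", seq_len(subpools))
  orf_ids <- sprintf("ORF%03d", seq_len(n_orfs))
  clones <- data.frame(
    element_id = sprintf("EL%05d", seq_len(n)),
    orf_id = rep(orf_ids, each = bcs_per_orf),
    bc_id = sprintf("BC%05d", seq_len(n)),
    bc_seq = random_unique_seqs(n, bc_len),
    subpool_id = rep(pool_ids, length.out = n_orfs)[
      rep(seq_len(n_orfs), each = bcs_per_orf)],
    design = design_label,
    stringsAsFactors = FALSE
  )
  screen_library(clones, abundance = abundance,
                 subpool_titers = subpool_titers, designs = designs)
}

#' Generate the mock nontargeting shRNA library
#'
#' 1000 nontargeting shRNAs in five pools of 200, each pool of uniform GC
#' content (40, 45, 50, 55 or 60% GC in the hairpin template). Template
#' sequences have exactly the stratum's GC count; subpools correspond to the
#' GC strata.
#'
#' @param n_per_stratum shRNAs per GC stratum; default 200.
#' @param gc_strata GC fractions; default `c(0.40, 0.45, 0.50, 0.55, 0.60)`.
#' @param template_len Hairpin template length (bp); default 40, chosen so
#'   every stratum's GC count is a whole number of bases.
#' @return A [screen_library()] (TRE design, equimolar) with exact
#'   `gc_fraction` annotations.
#' @export
make_mock_shrna_library <- function(n_per_stratum = 200,
                                    gc_strata = c(0.40, 0.45, 0.50, 0.55, 0.60),
                                    template_len = 40) {
  gc_counts <- gc_strata * template_len
  if (any(abs(gc_counts - round(gc_counts)) > 1e-9)) {
    stop("template_len must make every stratum's GC count integral",
         call. = FALSE)
  }
  pieces <- lapply(seq_along(gc_strata), function(i) {
    data.frame(
      gc_fraction = gc_strata[i],
      bc_seq = random_unique_seqs(n_per_stratum, template_len,
                                  gc_count = round(gc_counts[i])),
      subpool_id = sprintf("GC%02d", round(100 * gc_strata[i])),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, pieces)
  n <- nrow(tab)
  clones <- data.frame(
    element_id = sprintf("SH%04d", seq_len(n)),
    orf_id = sprintf("SH%04d", seq_len(n)),   # nontargeting: one bc each
    bc_id = sprintf("BC%04d", seq_len(n)),
    bc_seq = tab$bc_seq,
    subpool_id = tab$subpool_id,
    design = "TRE",
    gc_fraction = tab$gc_fraction,
    stringsAsFactors = FALSE
  )
  screen_library(clones)
}

#' Simulate growth under selection with drift
#'
#' Expected endpoint weight of element `i` is proportional to
#' `initial_i * 2^(pds * s_i)` (the common `2^pds` neutral growth cancels on
#' renormalisation). In stochastic mode the population is resampled
#' multinomially at each doubling with size `representation * n_elements`,
#' which introduces drift whose variance shrinks as `1/representation`.
#'
#' @param initial Initial abundance (normalised internally).
#' @param s Per-element selection coefficients (recycled).
#' @param pds Population doublings (integer in stochastic mode).
#' @param representation Cells per element maintained at each passage.
#' @param mode `"stochastic"` or `"expectation"`.
#' @return Endpoint abundance vector (sums to 1).
#' @export
simulate_growth <- function(initial, s = 0, pds = 10, representation = 1000,
                            mode = c("stochastic", "expectation")) {
  mode <- match.arg(mode)
  initial <- unlist(initial)
  stopifnot(pds >= 0, all(initial >= 0), sum(initial) > 0)
  if (representation < 1) stop("representation must be >= 1", call. = FALSE)
  s <- rep_len(as.numeric(s), length(initial))
  if (any(1 + s <= 0)) stop("need 1 + s > 0", call. = FALSE)
  a <- initial / sum(initial)
  if (mode == "expectation") {
    w <- a * 2^(pds * s)
    return(stats::setNames(w / sum(w), names(initial)))
  }
  size <- round(representation * length(initial))
  counts <- as.numeric(stats::rmultinom(1, size, a))
  steps <- floor(pds)
  frac <- pds - steps
  for (k in seq_len(steps)) {
    w <- counts * 2^s
    if (sum(w) <= 0) stop("population went extinct", call. = FALSE)
    counts <- as.numeric(stats::rmultinom(1, size, w))
  }
  if (frac > 0) {
    w <- counts * 2^(frac * s)
    counts <- as.numeric(stats::rmultinom(1, size, w))
  }
  stats::setNames(counts / sum(counts), names(initial))
}

# Per-element distribution of carried-over plasmid. Low-titer subpools need
# more supernatant volume for equal viral representation, so they carry
# proportionally more plasmid (weight ~ 1/titer).
plasmid_distribution <- function(lib) {
  w <- lib$abundance
  if (!is.null(lib$subpool_titers)) {
    inv <- 1 / as.numeric(lib$subpool_titers[lib$clones$subpool_id])
    w <- w * inv / mean(inv)
  }
  w / sum(w)
}

scenario_contamination_params <- function(config) {
  contamination_params(
    c0_std = 70,
    dna_input_fraction = config$dna_input_fraction,
    benzonase_log_reduction = if (config$benzonase_units > 0) 3 else 0
  )
}

#' Run a full synthetic screen scenario
#'
#' Wires the pipeline end to end: pooled transduction with template
#' switching, construction of the reference sample (proviral templates plus
#' carried-over plasmid according to the reference mode), growth under
#' selection with drift, a shared PCR parameterisation for both samples
#' (same nominal cycles and capacity, so template-abundance differences
#' surface as effective-cycle differences), and multinomial sequencing.
#'
#' @param config A [scenario_config()].
#' @param lib A [screen_library()].
#' @param fitness A [fitness_spec()] over the library's ORFs (default all
#'   neutral). For inducible (TRE) designs the uninduced arm is this with
#'   all coefficients zero.
#' @param model A [recombination_model()] for the transduction step.
#' @param efficiency An [efficiency_params()] shared by both PCRs.
#' @param pcr_mode `"expectation"` (default) or `"stochastic"` amplification.
#' @param plasmid_len_bp Plasmid length used in the mass-matched reference
#'   arithmetic; default 10000 (a working assumption, not a measured value).
#' @return An object of class `screen_dataset`: `library`, `provirus`
#'   (provirus table), `counts` (raw [count_matrix()] with samples
#'   `reference` and `endpoint`), `truth` (expected per-element log2 fold
#'   change in the infinite-population limit), `config`.
#' @export
run_screen_scenario <- function(config, lib, fitness = NULL,
                                model = recombination_model(),
                                efficiency = efficiency_params(),
                                pcr_mode = "expectation",
                                plasmid_len_bp = 10000) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(lib, "screen_library"))
  clones <- lib$clones
  n_el <- nrow(clones)
  if (is.null(fitness)) fitness <- fitness_spec(unique(clones$orf_id))
  miss <- setdiff(unique(clones$orf_id), names(fitness))
  if (length(miss)) {
    stop("fitness_spec missing ORF(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  template_total <- config$representation * n_el   # PCR input normalised by
  # gDNA mass to screen coverage

  pt <- with_substream(config$seed, "transduce",
                       transduce(lib, ceiling(template_total / config$moi),
                                 moi = config$moi, mode = "pooled",
                                 model = model))
  el_of_bc <- stats::setNames(clones$element_id, clones$bc_id)
  row_element <- el_of_bc[pt$bc_id]        # reads report the barcode
  row_s <- as.numeric(fitness[pt$orf_id])  # growth follows the expressed ORF

  tab0 <- tabulate(match(row_element, clones$element_id), nbins = n_el)
  a0 <- tab0 / sum(tab0)

  # growth at integrant resolution so chimeric proviruses propagate the
  # wrong ORF's fitness into their barcode's trajectory
  size <- round(template_total)
  counts_rows <- rep(1, nrow(pt))
  counts_rows <- with_substream(config$seed, "growth", {
    cr <- as.numeric(stats::rmultinom(1, size, counts_rows))
    for (k in seq_len(floor(config$pds))) {
      cr <- as.numeric(stats::rmultinom(1, size, cr * 2^row_s))
    }
    frac <- config$pds - floor(config$pds)
    if (frac > 0) cr <- as.numeric(stats::rmultinom(1, size, cr * 2^(frac * row_s)))
    cr
  })
  end_el <- tapply(counts_rows, factor(row_element, levels = clones$element_id),
                   sum, default = 0)
  end_init <- as.numeric(end_el)

  # reference sample templates
  cp <- scenario_contamination_params(config)
  pdist <- plasmid_distribution(lib)
  prov_ref <- a0 * template_total
  pg_per_bp <- 650 / 6.02214076e23 * 1e12
  plasmid_vec <- switch(config$reference_mode,
    early_cells = template_total *
      dilute_plasmid(initial_plasmid_load(cp), config$pds_ref,
                     cp$decay_per_pd) * pdist,
    equilibrated_cells = template_total *
      dilute_plasmid(initial_plasmid_load(cp), max(config$pds, 10),
                     cp$decay_per_pd) * pdist,
    plasmid_mass_matched = {
      # naked plasmid at gDNA-equivalent mass: copies per genome-equivalent
      copies_per_genome <- 6.6 / (plasmid_len_bp * pg_per_bp)
      prov_ref <- rep(0, n_el)
      template_total * copies_per_genome * (lib$abundance / sum(lib$abundance))
    },
    linearized_plasmid_in_gdna = {
      # one template per diploid-genome-equivalent of carrier gDNA
      prov_ref <- rep(0, n_el)
      template_total * (lib$abundance / sum(lib$abundance))
    }
  )
  ref_init <- prov_ref + plasmid_vec

  gc <- clones$gc_fraction
  runs <- with_substream(config$seed, "pcr", list(
    ref = amplify(ref_init, gc, n_cycles = config$pcr_cycles,
                  capacity = config$pcr_capacity, params = efficiency,
                  mode = pcr_mode),
    end = amplify(end_init, gc, n_cycles = config$pcr_cycles,
                  capacity = config$pcr_capacity, params = efficiency,
                  mode = pcr_mode)
  ))
  depth <- round(config$depth_per_element * n_el)
  counts <- with_substream(config$seed, "sequence", cbind(
    reference = sequence_sample(runs$ref$realized, depth),
    endpoint = sequence_sample(runs$end$realized, depth)
  ))
  rownames(counts) <- clones$element_id
  cm <- count_matrix(counts, gc = stats::setNames(gc, clones$element_id))

  # ground truth on expected abundances (infinite-population limit)
  w_rows <- 2^(config$pds * row_s)
  end_exp <- tapply(w_rows, factor(row_element, levels = clones$element_id),
                    sum, default = 0)
  end_exp <- as.numeric(end_exp) / sum(w_rows)
  truth <- log2(end_exp / a0)
  truth[a0 == 0] <- NA_real_

  structure(
    list(library = lib, provirus = pt, counts = cm,
         truth = stats::setNames(truth, clones$element_id),
         n_eff = c(reference = runs$ref$n_eff, endpoint = runs$end$n_eff),
         config = config),
    class = "screen_dataset"
  )
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat("screen_dataset:", nrow(x$library$clones), "elements, reference mode",
      x$config$reference_mode,
      sprintf("| n_eff ref %.1f vs end %.1f\n", x$n_eff["reference"],
              x$n_eff["endpoint"]))
  invisible(x)
}

#' Write a screen dataset to a directory
#'
#' Emits `library.tsv`, `provirus.tsv`, `counts_ref.tsv`, `counts_end.tsv`,
#' `truth.tsv` and `config.yaml`.
#'
#' @param ds A `screen_dataset` from [run_screen_scenario()].
#' @param dir Output directory (created if absent).
#' @param header Optional provenance comment for the TSV files.
#' @return `dir`, invisibly.
#' @export
write_screen_dataset <- function(ds, dir, header = NULL) {
  stopifnot(inherits(ds, "screen_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_library(ds$library, file.path(dir, "library.tsv"), header)
  write_tsv_with_header(ds$provirus, file.path(dir, "provirus.tsv"), header)
  m <- ds$counts$counts
  for (nm in c("reference", "endpoint")) {
    cm1 <- count_matrix(m[, nm, drop = FALSE], gc = ds$counts$gc)
    write_counts(cm1, file.path(dir, paste0(
      "counts_", if (nm == "reference") "ref" else "end", ".tsv")), header)
  }
  write_tsv_with_header(
    data.frame(element_id = names(ds$truth), truth_log2fc = unname(ds$truth),
               stringsAsFactors = FALSE),
    file.path(dir, "truth.tsv"), header)
  yaml::write_yaml(unclass(ds$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Simulate the barcode-ORF recombination assay
#'
#' Reproduces the sublibrary assay: clones packaged pooled (recombination
#' test) or individually then pooled after transduction (PCR control, in
#' which chimeras are impossible), followed by sequencing of sampled
#' proviruses and frequency estimation with the homozygous-virion
#' correction.
#'
#' @param n_clones Clones in the sublibrary; default 11.
#' @param design Design label or [vector_design()]; default `"5BC"`.
#' @param mode `"pooled"` or `"individual_then_pooled"`.
#' @param n_sequenced Proviruses sampled for sequencing.
#' @param model A [recombination_model()]; overridden by `p_switch`.
#' @param p_switch Optional per-virion switch probability overriding the
#'   model for this design.
#' @param moi Multiplicity of infection for the transduction; default 0.5.
#' @return A list: `sample` (the sequenced provirus rows), `estimate`
#'   (a [recomb_estimate()]), `library`.
#' @export
run_recomb_assay_scenario <- function(n_clones = 11, design = "5BC",
                                      mode = c("pooled",
                                               "individual_then_pooled"),
                                      n_sequenced = 65,
                                      model = recombination_model(),
                                      p_switch = NULL, moi = 0.5) {
  mode <- match.arg(mode)
  stopifnot(n_sequenced >= 1)
  lib <- make_orf_bc_library(n_clones, 1, 30, design = design)
  design_name <- lib$clones$design[1]
  if (!is.null(p_switch)) {
    model <- recombination_model("fixed_per_design",
                                 stats::setNames(p_switch, design_name))
  }
  n_cells <- ceiling(n_sequenced / moi * 1.3) + 20
  pt <- transduce(lib, n_cells, moi = moi, mode = mode, model = model)
  if (nrow(pt) < n_sequenced) {
    stop("transduction yielded too few proviruses; increase moi", call. = FALSE)
  }
  idx <- sample.int(nrow(pt), n_sequenced)
  sampled <- pt[idx, , drop = FALSE]
  est <- measured_recombination_frequency(sampled, lib)
  list(sample = sampled, estimate = est, library = lib)
}
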