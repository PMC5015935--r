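#' Lentiviral vector design
#'
#' Describes the layout features of a library expression vector that matter
#' for recombination: the length of homologous sequence separating the ORF
#' from its barcode, and whether the promoter is inducible. Template switching
#' by reverse transcriptase in the ORF-barcode interval uncouples the pair;
#' the switch probability grows with the homology length, so vector designs
#' that place the barcode close to the ORF (short homology) are safer.
#'
#' @param name Design label, unique within a run. The two designs studied in
#'   depth are `"5BC"` (barcode 5' of the ORF, 720 bp of homologous sequence
#'   in between) and `"3BC"` (barcode 3' of the ORF, 96 bp).
#' @param homology_bp Nonnegative integer length (bp) of homologous sequence
#'   between ORF and barcode.
#' @param inducible Logical; `TRUE` for tetracycline-inducible (TRE) designs.
#' @param promoter_label Promoter name (informational).
#' @return An object of class `vector_design`.
#' @examples
#' vector_design("5BC", 720)
#' vector_design("3BC", 96)
#' @export
vector_design <- function(name, homology_bp, inducible = FALSE,
                          promoter_label = "CMV") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  homology_bp <- as.numeric(homology_bp)
  if (length(homology_bp) != 1L || is.na(homology_bp) || homology_bp < 0) {
    stop("`homology_bp` must be a single nonnegative number", call. = FALSE)
  }
  structure(
    list(name = name, homology_bp = homology_bp,
         inducible = isTRUE(inducible), promoter_label = promoter_label),
    class = "vector_design"
  )
}

#' Built-in vector designs
#'
#' The two barcode placements characterised by the recombination assay:
#' 720 bp of ORF-barcode homology for the 5' placement, 96 bp for the 3'
#' placement, plus the inducible TRE variant of the 3' design.
#'
#' @param name One of `"5BC"`, `"3BC"`, `"TRE"`.
#' @return A [vector_design()].
#' @export
default_design <- function(name = c("3BC", "5BC", "TRE")) {
  name <- match.arg(name)
  switch(name,
    "5BC" = vector_design("5BC", 720, FALSE, "CMV"),
    "3BC" = vector_design("3BC", 96, FALSE, "CMV"),
    "TRE" = vector_design("TRE", 96, TRUE, "TRE")
  )
}

gc_of <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)
  vapply(chars, function(x) sum(x %in% c("G", "C")) / length(x), numeric(1))
}

#' Screen library
#'
#' A pooled library: one row per clone (element), each pairing an ORF with a
#' unique barcode, annotated with the GC fraction of the amplified template,
#' a subpool assignment and a vector design. Abundance is the plasmid-pool
#' composition used for packaging (renormalised to sum to one).
#'
#' @param clones `data.frame` with columns `element_id`, `orf_id`, `bc_id`,
#'   `bc_seq`, `subpool_id`, `design`; optional `gc_fraction` (computed from
#'   `bc_seq` when absent).
#' @param abundance Optional nonnegative weights, one per clone; uniform when
#'   `NULL`. Renormalised to sum to one.
#' @param subpool_titers Optional named vector of viral titers (CFU/ml), one
#'   entry per subpool present in `clones`.
#' @param designs Named list of [vector_design()] objects covering every
#'   design label in `clones`; defaults are filled in for `"5BC"`, `"3BC"`
#'   and `"TRE"`.
#' @return An object of class `screen_library` with elements `clones`
#'   (data.frame), `abundance` (numeric, sums to one), `subpool_titers`,
#'   `designs`.
#' @export
screen_library <- function(clones, abundance = NULL, subpool_titers = NULL,
                           designs = NULL) {
  req <- c("element_id", "orf_id", "bc_id", "bc_seq", "subpool_id", "design")
  missing_cols <- setdiff(req, names(clones))
  if (length(missing_cols)) {
    stop("clones is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  clones <- as.data.frame(clones, stringsAsFactors = FALSE)
  if (anyDuplicated(clones$element_id)) {
    stop("duplicate element_id: ",
         paste(unique(clones$element_id[duplicated(clones$element_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad <- grepl("[^ACGT]", toupper(clones$bc_seq))
  if (any(bad)) {
    stop("non-ACGT barcode at row(s) ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(nchar(clones$bc_seq))) > 1L) {
    stop("barcode length must be uniform within a library", call. = FALSE)
  }
  if (is.null(clones$gc_fraction)) clones$gc_fraction <- gc_of(clones$bc_seq)
  n <- nrow(clones)
  if (is.null(abundance)) abundance <- rep(1 / n, n)
  abundance <- as.numeric(abundance)
  if (length(abundance) != n || any(is.na(abundance)) || any(abundance < 0)) {
    stop("abundance must be ", n, " nonnegative numbers", call. = FALSE)
  }
  if (sum(abundance) <= 0) stop("abundance sums to zero", call. = FALSE)
  abundance <- abundance / sum(abundance)
  if (is.null(designs)) designs <- list()
  for (d in setdiff(unique(clones$design), names(designs))) {
    designs[[d]] <- if (d %in% c("5BC", "3BC", "TRE")) default_design(d) else
      stop("no vector_design supplied for design label '", d, "'",
           call. = FALSE)
  }
  if (!is.null(subpool_titers)) {
    miss <- setdiff(unique(clones$subpool_id), names(subpool_titers))
    if (length(miss)) {
      stop("missing titer for subpool(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(
    list(clones = clones, abundance = abundance,
         subpool_titers = subpool_titers, designs = designs),
    class = "screen_library"
  )
}

#' @export
print.screen_library <- function(x, ...) {
  cat("screen_library:", nrow(x$clones), "clones,",
      length(unique(x$clones$orf_id)), "ORFs,",
      length(unique(x$clones$subpool_id)), "subpool(s)\n")
  invisible(x)
}

#' Read / write a library definition table
#'
#' Tab-delimited, UTF-8, header row; columns `element_id`, `orf_id`, `bc_id`,
#' `bc_seq`, `subpool_id`, `design` and optionally `abundance` and
#' `gc_fraction`. Lines starting with `#` are ignored. Abundance is
#' renormalised on read (uniform when the column is absent); clone order is
#' file order.
#'
#' @param path File path.
#' @param lib A [screen_library()].
#' @param header Optional provenance comment (without the leading `#`)
#'   written as the first line.
#' @return `read_library` returns a [screen_library()]; `write_library`
#'   returns `path` invisibly.
#' @export
read_library <- function(path) {
  tab <- read_tsv_checked(path)
  ab <- if ("abundance" %in% names(tab)) as.numeric(tab$abundance)
  tab$abundance <- NULL
  screen_library(tab, abundance = ab)
}

#' @rdname read_library
#' @export
write_library <- function(lib, path, header = NULL) {
  stopifnot(inherits(lib, "screen_library"))
  out <- lib$clones
  out$abundance <- lib$abundance
  write_tsv_with_header(out, path, header)
  invisible(path)
}

#' Count matrix of elements by samples
#'
#' The analysis backbone: nonnegative read counts with one row per library
#' element and one column per sample, plus a per-element GC annotation.
#'
#' @param counts Numeric matrix (or object coercible to one) with rownames
#'   (element ids) and colnames (sample ids); all entries nonnegative.
#' @param gc Optional numeric vector of per-element GC fractions, recycled or
#'   matched by name.
#' @param normalized Logical; `TRUE` when columns have been scaled to a
#'   common total.
#' @param total The per-column total when `normalized`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gc = NULL, normalized = FALSE, total = NA) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts))) {
    stop("counts must have element ids as rownames", call. = FALSE)
  }
  if (is.null(colnames(counts)) || ncol(counts) == 0L) {
    stop("counts must have at least one named sample column", call. = FALSE)
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be nonnegative and non-missing", call. = FALSE)
  }
  if (!is.null(gc)) {
    if (!is.null(names(gc))) gc <- gc[rownames(counts)]
    gc <- as.numeric(gc)
    if (length(gc) != nrow(counts)) {
      stop("gc must have one entry per element", call. = FALSE)
    }
  }
  structure(
    list(counts = counts, gc = gc, normalized = isTRUE(normalized),
         total = total),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "elements x", ncol(x$counts),
      "samples", if (x$normalized) sprintf("(normalized to %g)", x$total),
      "\n")
  invisible(x)
}

#' Read / write a count matrix
#'
#' TSV with first column `element_id` and one column per sample; integer
#' counts round-trip losslessly. A `gc_fraction` column, when present, is
#' carried as the GC annotation rather than as a sample.
#'
#' @param path File path.
#' @param cm A [count_matrix()].
#' @param header Optional provenance comment written as a `#` first line.
#' @return `read_counts` returns a [count_matrix()]; `write_counts` returns
#'   `path` invisibly.
#' @export
read_counts <- function(path) {
  tab <- read_tsv_checked(path)
  if (names(tab)[1] != "element_id") {
    stop("first column must be element_id in ", path, call. = FALSE)
  }
  gc <- NULL
  if ("gc_fraction" %in% names(tab)) {
    gc <- as.numeric(tab$gc_fraction)
    tab$gc_fraction <- NULL
  }
  if (ncol(tab) < 2L) stop("no sample columns in ", path, call. = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(is.na(m))) stop("non-numeric count in ", path, call. = FALSE)
  if (any(m < 0)) {
    bad <- which(rowSums(m < 0) > 0)[1]
    stop("negative count at data row ", bad, " of ", path, call. = FALSE)
  }
  rownames(m) <- tab$element_id
  count_matrix(m, gc = gc)
}

#' @rdname read_counts
#' @export
write_counts <- function(cm, path, header = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  out <- data.frame(element_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(cm$gc)) out$gc_fraction <- cm$gc
  write_tsv_with_header(out, path, header)
  invisible(path)
}

#' Export barcodes as FASTA
#'
#' One record per clone, `element_id` as the record id.
#'
#' @param lib A [screen_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_barcode_fasta <- function(lib, path) {
  stopifnot(inherits(lib, "screen_library"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0(">", lib$clones$element_id, "\n", lib$clones$bc_seq), con)
  invisible(path)
}

# Shared TSV plumbing: comment-tolerant reader with located errors, and a
# writer that emits the provenance header line used by the CLI.
read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) stop("empty table: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    stop("ragged row at line ", bad, " of ", path, " (", nf[bad],
         " fields, expected ", nf[1], ")", call. = FALSE)
  }
  header <- fields[[1]]
  body <- fields[-1]
  cols <- lapply(seq_along(header), function(j) {
    vapply(body, `[[`, character(1), j)
  })
  names(cols) <- header
  out <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_along(out)) {
    suppressWarnings(num <- as.numeric(out[[j]]))
    if (!anyNA(num)) out[[j]] <- num
  }
  out
}

write_tsv_with_header <- function(df, path, header = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  # fixed-notation numbers so identical inputs give byte-identical files
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) format(col, trim = TRUE, scientific = FALSE,
                                digits = 15) else as.character(col)
  }, FUN.VALUE = character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L, dimnames = list(NULL, names(df)))
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(apply(fmt, 1L, paste, collapse = "\t"), con)
}

#' Scenario configuration
#'
#' Bundles the experimental parameters of one simulated screen. Defaults are
#' the standard screen protocol: MOI 0.5, 1000 cells per element, 10
#' population doublings, full plasmid input, no nuclease treatment, the
#' reference sample collected shortly after transduction.
#'
#' @param moi Multiplicity of infection (mean integrations per cell offered).
#' @param representation Cells per library element (coverage).
#' @param pds Population doublings between reference and endpoint.
#' @param dna_input_fraction Fraction of standard transfection plasmid mass
#'   (1.0 standard, 0.2 or 0.1 for reduced-input protocols).
#' @param benzonase_units Nuclease dose (units/ml) applied to the viral
#'   supernatant; 0 = untreated, 500 = the standard treated protocol.
#' @param seed Integer seed; expanded into per-stage substreams.
#' @param reference_mode How the normalisation reference is built:
#'   `"early_cells"` (cells shortly after transduction, plasmid carryover
#'   still present), `"equilibrated_cells"` (cells passaged until plasmid has
#'   diluted out, e.g. the uninduced 10 PD arm), `"plasmid_mass_matched"`
#'   (naked library plasmid at gDNA-equivalent mass: a vast template excess),
#'   or `"linearized_plasmid_in_gdna"` (linearised plasmid diluted into
#'   carrier gDNA at one template per diploid genome).
#' @param pds_ref Doublings elapsed before the reference sample is taken
#'   (0 for the standard early reference).
#' @param depth_per_element Mean sequencing reads per element.
#' @param pcr_cycles Nominal PCR cycle count per sample.
#' @param pcr_capacity Molecule capacity of one PCR reaction.
#' @return An object of class `scenario_config` (a validated list).
#' @export
scenario_config <- function(moi = 0.5, representation = 1000, pds = 10,
                            dna_input_fraction = 1.0, benzonase_units = 0,
                            seed = 1L, reference_mode = c(
                              "early_cells", "equilibrated_cells",
                              "plasmid_mass_matched",
                              "linearized_plasmid_in_gdna"),
                            pds_ref = 0, depth_per_element = 500,
                            pcr_cycles = 30, pcr_capacity = 1e12) {
  reference_mode <- match.arg(reference_mode)
  stopifnot(moi > 0, representation >= 1, pds >= 0,
            dna_input_fraction > 0, dna_input_fraction <= 1,
            benzonase_units >= 0, pds_ref >= 0, depth_per_element >= 0,
            pcr_cycles >= 0, pcr_capacity > 0)
  structure(
    list(moi = moi, representation = representation, pds = pds,
         dna_input_fraction = dna_input_fraction,
         benzonase_units = benzonase_units, seed = as.integer(seed),
         reference_mode = reference_mode, pds_ref = pds_ref,
         depth_per_element = depth_per_element, pcr_cycles = pcr_cycles,
         pcr_capacity = pcr_capacity),
    class = "scenario_config"
  )
}

#' Read a scenario configuration file
#'
#' Flat key/value YAML; unknown keys are rejected, absent keys take the
#' standard-protocol defaults of [scenario_config()].
#'
#' @param path YAML file path.
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(scenario_config, vals)
}
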