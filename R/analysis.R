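#' Normalize a count matrix to a fixed per-sample total
#'
#' Counts-per-fixed-total scaling (reads per million by default): each sample
#' column is multiplied so it sums to `total`, which preserves within-sample
#' proportions exactly.
#'
#' @param cm A [count_matrix()].
#' @param total Target column sum; default 1e6.
#' @return A normalized [count_matrix()].
#' @export
normalize_counts <- function(cm, total = 1e6) {
  stopifnot(inherits(cm, "count_matrix"), total > 0)
  sums <- colSums(cm$counts)
  if (any(sums <= 0)) {
    stop("zero-sum sample column(s): ",
         paste(colnames(cm$counts)[sums <= 0], collapse = ", "),
         call. = FALSE)
  }
  count_matrix(sweep(cm$counts, 2, sums / total, `/`), gc = cm$gc,
               normalized = TRUE, total = total)
}

#' Per-element log2 fold change
#'
#' `log2((end + pseudocount) / (ref + pseudocount))`, the screen's basic
#' enrichment/depletion statistic. Inputs should be normalized to a common
#' total first; the pseudocount guards elements that drop to zero.
#'
#' @param ref,end Named numeric vectors of (normalized) counts over the same
#'   elements.
#' @param pseudocount Added to both numerator and denominator; default 1.
#' @return Named numeric vector of log2 fold changes.
#' @export
log2fc <- function(ref, end, pseudocount = 1) {
  ref <- unlist(ref)
  end <- unlist(end)
  if (length(ref) != length(end)) {
    stop("ref and end must cover the same elements", call. = FALSE)
  }
  if (!is.null(names(ref)) && !is.null(names(end))) {
    if (!identical(names(ref), names(end))) {
      if (!setequal(names(ref), names(end))) {
        stop("ref and end element sets differ", call. = FALSE)
      }
      end <- end[names(ref)]
    }
  }
  stopifnot(pseudocount >= 0)
  log2((end + pseudocount) / (ref + pseudocount))
}

#' Barcode concordance within ORF groups
#'
#' When one ORF carries several independent barcodes, their log2 fold
#' changes should agree; recombination uncouples barcodes from their ORFs
#' and erodes this agreement, most visibly for ORFs with strong fitness
#' effects. Sign agreement is `max(#positive, #negative) / n` per group.
#'
#' @param lfc Named numeric vector of per-element log2 fold changes.
#' @param orf Character vector mapping each element to its ORF.
#' @return `data.frame` with one row per ORF: `orf_id`, `n`,
#'   `sign_agreement` (`NA` for singleton groups), `mean`, `sd`.
#' @export
barcode_concordance <- function(lfc, orf) {
  lfc <- unlist(lfc)
  if (length(lfc) == 0L) stop("empty group set", call. = FALSE)
  if (length(orf) != length(lfc)) {
    stop("orf labels must match lfc length", call. = FALSE)
  }
  groups <- split(lfc, orf)
  out <- data.frame(
    orf_id = names(groups),
    n = lengths(groups),
    sign_agreement = vapply(groups, function(g) {
      if (length(g) < 2L) return(NA_real_)
      max(sum(g > 0), sum(g < 0)) / length(g)
    }, numeric(1)),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, stats::sd, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Recombination-frequency estimate
#'
#' Bundles the assay counts with the homozygous-virion correction. Observed
#' barcode-ORF shuffling underestimates the true template-switch frequency
#' because switches inside homozygous virions (two genomes from the same
#' clone, a fraction `h` of virions) are invisible; the corrected estimate
#' adds the inferred invisible events: `f_true = f_measured * (1 + h)`.
#'
#' @param n_analyzed Number of sequences analysed.
#' @param n_recombined Number with a non-library barcode-ORF pairing.
#' @param h Homozygous-virion fraction (see [homozygosity_fraction()]).
#' @return An object of class `recomb_estimate` with fields `n_analyzed`,
#'   `n_recombined`, `f_measured`, `h`, `f_true_est`.
#' @examples
#' recomb_estimate(65, 17, h = 1 / 11) # measured 26.15%, corrected 28.53%
#' @export
recomb_estimate <- function(n_analyzed, n_recombined, h = 0) {
  stopifnot(n_analyzed >= 1, n_recombined >= 0, n_recombined <= n_analyzed,
            h >= 0, h <= 1)
  f <- n_recombined / n_analyzed
  structure(
    list(n_analyzed = n_analyzed, n_recombined = n_recombined,
         f_measured = f, h = h,
         f_true_est = correct_recombination_frequency(f, h)),
    class = "recomb_estimate"
  )
}

#' @export
print.recomb_estimate <- function(x, ...) {
  cat(sprintf(
    "recomb_estimate: %d/%d recombined, measured %.2f%%, corrected %.2f%% (h = %.4f)\n",
    x$n_recombined, x$n_analyzed, 100 * x$f_measured, 100 * x$f_true_est,
    x$h))
  invisible(x)
}

#' Measured recombination frequency from observed pairs
#'
#' Counts observed barcode-ORF pairings absent from the library's pairing
#' map. Both ids must exist in the library.
#'
#' @param pairs `data.frame` with columns `orf_id` and `bc_id` (a provirus
#'   table or a sequenced-clone list).
#' @param lib A [screen_library()] providing the true pairing map.
#' @param h Homozygous-virion fraction used for the corrected estimate;
#'   default computed from `lib` abundances.
#' @return A [recomb_estimate()].
#' @export
measured_recombination_frequency <- function(pairs, lib,
                                             h = homozygosity_fraction(lib$abundance)) {
  stopifnot(inherits(lib, "screen_library"))
  if (!all(c("orf_id", "bc_id") %in% names(pairs))) {
    stop("pairs needs orf_id and bc_id columns", call. = FALSE)
  }
  if (nrow(pairs) == 0L) stop("no observed pairs", call. = FALSE)
  bad_orf <- setdiff(pairs$orf_id, lib$clones$orf_id)
  bad_bc <- setdiff(pairs$bc_id, lib$clones$bc_id)
  if (length(bad_orf) || length(bad_bc)) {
    stop("unknown id(s): ", paste(c(bad_orf, bad_bc), collapse = ", "),
         call. = FALSE)
  }
  valid <- paste(lib$clones$orf_id, lib$clones$bc_id)
  n_rec <- sum(!(paste(pairs$orf_id, pairs$bc_id) %in% valid))
  recomb_estimate(nrow(pairs), n_rec, h = h)
}

#' Homozygous-virion correction
#'
#' `f_measured * (1 + h)`: the measured shuffling frequency plus the
#' inferred frequency of undetected switches inside homozygous virions.
#' Identity at `h = 0`, bounded by twice the measured frequency.
#'
#' @param f_measured Measured recombination fraction.
#' @param h Homozygous-virion fraction.
#' @return Corrected (estimated true) recombination fraction.
#' @examples
#' correct_recombination_frequency(17 / 65, 1 / 11) # 0.2853
#' @export
correct_recombination_frequency <- function(f_measured, h) {
  stopifnot(all(f_measured >= 0), all(f_measured <= 1),
            all(h >= 0), all(h <= 1))
  f_measured * (1 + h)
}

#' Compare two recombination rates
#'
#' Tests whether two assay arms share an underlying recombination rate.
#' The default is a two-sided exact binomial test of the second arm's count
#' against the first arm's observed rate (for the assay's 17/65 vs 3/55 this
#' gives p of order 1e-4); `"fisher"` treats both counts as random via the
#' exact test on the 2x2 table.
#'
#' @param k1,n1 Recombined and total counts in arm 1.
#' @param k2,n2 Recombined and total counts in arm 2.
#' @param method `"binomial"` or `"fisher"`.
#' @return Two-sided p-value.
#' @export
compare_recombination <- function(k1, n1, k2, n2,
                                  method = c("binomial", "fisher")) {
  method <- match.arg(method)
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  if (method == "binomial") {
    p0 <- k1 / n1
    if (p0 == 0) {
      # degenerate reference rate: only k2 = 0 is consistent
      return(if (k2 == 0) 1 else 0)
    }
    stats::binom.test(k2, n2, p = p0)$p.value
  } else {
    m <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2)
    stats::fisher.test(m)$p.value
  }
}

#' GC-bias diagnostic
#'
#' Pearson product-moment correlation (two-sided t-test p-value) between
#' per-element GC content and log2 fold change, plus per-GC-bin summary
#' statistics for boxplot-style reporting. A significantly negative `r`
#' indicates artifactual depletion of GC-rich elements, the signature of
#' unequal template abundance (e.g. plasmid-contaminated references).
#'
#' @param lfc Named numeric vector of per-element log2 fold changes.
#' @param gc GC fraction per element (aligned with `lfc`).
#' @param bins Optional bin edges over GC. By default, discrete strata
#'   (<= 8 unique GC values) are binned per stratum; otherwise equal-width
#'   bins of 2.5 GC percentage points across the observed range.
#' @return An object of class `gc_bias_report`: `pearson_r`, `p_value`,
#'   `n`, and `binned` (`data.frame` with per-bin `n`, `median`, `q1`,
#'   `q3`).
#' @export
gc_bias_test <- function(lfc, gc, bins = NULL) {
  lfc <- unlist(lfc)
  gc <- unlist(gc)
  if (length(lfc) != length(gc)) stop("lfc and gc must align", call. = FALSE)
  if (length(lfc) < 3L) stop("need at least 3 elements", call. = FALSE)
  if (stats::sd(gc) == 0 || stats::sd(lfc) == 0) {
    r <- NA_real_
    p <- NA_real_
    note <- "constant input: correlation undefined"
  } else {
    ct <- stats::cor.test(gc, lfc, method = "pearson")
    r <- unname(ct$estimate)
    p <- ct$p.value
    note <- NULL
  }
  u <- sort(unique(gc))
  if (is.null(bins)) {
    if (length(u) <= 8L) {
      grp <- factor(gc, levels = u)
      labels <- format(u)
    } else {
      bins <- seq(min(gc), max(gc) + 1e-9, by = 0.025)
      if (max(bins) < max(gc)) bins <- c(bins, max(gc) + 1e-9)
      grp <- cut(gc, bins, include.lowest = TRUE)
      labels <- levels(grp)
    }
  } else {
    grp <- cut(gc, bins, include.lowest = TRUE)
    labels <- levels(grp)
  }
  by_bin <- split(lfc, grp)
  binned <- data.frame(
    bin = labels,
    n = lengths(by_bin),
    median = vapply(by_bin, function(x) if (length(x)) stats::median(x) else NA_real_, numeric(1)),
    q1 = vapply(by_bin, function(x) if (length(x)) unname(stats::quantile(x, 0.25)) else NA_real_, numeric(1)),
    q3 = vapply(by_bin, function(x) if (length(x)) unname(stats::quantile(x, 0.75)) else NA_real_, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(binned) <- NULL
  structure(list(pearson_r = r, p_value = p, n = length(lfc),
                 binned = binned, note = note),
            class = "gc_bias_report")
}

#' @export
print.gc_bias_report <- function(x, ...) {
  if (is.na(x$pearson_r)) {
    cat("gc_bias_report:", x$note, "\n")
  } else {
    cat(sprintf("gc_bias_report: r = %.3f, p = %.3g (n = %d)\n",
                x$pearson_r, x$p_value, x$n))
  }
  invisible(x)
}

#' Subpool-distortion diagnostic
#'
#' Libraries packaged as separately titered subpools and combined at equal
#' viral representation receive more supernatant volume — and hence more
#' carried-over plasmid — for low-titer subpools. In contaminated reference
#' samples the mean reads per subpool then correlate inversely with titer,
#' with subpool abundances spread several-fold apart.
#'
#' @param reads Per-element read counts.
#' @param subpool Subpool label per element.
#' @param titers Named titer vector (CFU/ml), one entry per subpool.
#' @return A list: `spread` (max/min of subpool mean reads), `spearman_rho`
#'   (rank correlation of subpool mean reads vs titer; `NA` when degenerate),
#'   `per_subpool` (`data.frame` of mean reads and titer).
#' @export
subpool_distortion <- function(reads, subpool, titers) {
  reads <- unlist(reads)
  if (length(subpool) != length(reads)) {
    stop("subpool labels must match reads", call. = FALSE)
  }
  pools <- unique(subpool)
  if (length(pools) < 2L) stop("need at least 2 subpools", call. = FALSE)
  miss <- setdiff(pools, names(titers))
  if (length(miss)) {
    stop("missing titer for subpool(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  mean_reads <- vapply(split(reads, subpool), mean, numeric(1))
  t <- as.numeric(titers[names(mean_reads)])
  rho <- if (stats::sd(mean_reads) == 0 || stats::sd(t) == 0) NA_real_ else
    suppressWarnings(stats::cor(mean_reads, t, method = "spearman"))
  list(
    spread = max(mean_reads) / min(mean_reads),
    spearman_rho = rho,
    per_subpool = data.frame(subpool_id = names(mean_reads),
                             mean_reads = unname(mean_reads),
                             titer = t, stringsAsFactors = FALSE)
  )
}
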