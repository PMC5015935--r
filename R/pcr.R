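#' GC-dependent PCR efficiency parameters
#'
#' Per-cycle duplication efficiency declines linearly with template GC
#' content above a reference, with clipping:
#' `clip(e_max - slope * (gc - gc_ref), floor, e_max)`. The field observation
#' is directional (high-GC templates amplify less efficiently); the linear
#' form and its defaults are modelling choices, not measured constants.
#'
#' @param e_max Efficiency at the reference GC (probability a molecule is
#'   duplicated in one unsaturated cycle); default 0.95.
#' @param slope Efficiency loss per unit GC fraction above `gc_ref`;
#'   default 0.5 (so a 40% vs 60% GC template differ by 0.10 per cycle).
#' @param gc_ref Reference GC fraction; default 0.40.
#' @param floor Minimum efficiency; default 0.5.
#' @return An object of class `efficiency_params`.
#' @export
efficiency_params <- function(e_max = 0.95, slope = 0.5, gc_ref = 0.40,
                              floor = 0.5) {
  stopifnot(e_max > 0, e_max <= 1, slope >= 0, gc_ref >= 0, gc_ref <= 1,
            floor >= 0, floor <= e_max)
  structure(list(e_max = e_max, slope = slope, gc_ref = gc_ref,
                 floor = floor),
            class = "efficiency_params")
}

#' Per-cycle amplification efficiency for a GC fraction
#'
#' @param gc GC fraction(s) in `[0, 1]`.
#' @param params An [efficiency_params()].
#' @return Efficiency in `[floor, e_max]`, nonincreasing in `gc`.
#' @examples
#' pcr_efficiency(0.60, efficiency_params()) # 0.85
#' @export
pcr_efficiency <- function(gc, params = efficiency_params()) {
  stopifnot(inherits(params, "efficiency_params"),
            all(gc >= 0), all(gc <= 1))
  pmin(params$e_max,
       pmax(params$floor, params$e_max - params$slope * (gc - params$gc_ref)))
}

#' Multi-template PCR with saturation
#'
#' Amplifies a pool of species over `n_cycles`. Each cycle, species `i`
#' gains `n_i * e_i * s` molecules, where `e_i` is its GC-dependent
#' efficiency and `s` a shared saturation damping. With `saturation =
#' "smooth"` (default), `s = max(0, 1 - total/capacity)` — a logistic-style
#' soft approach to reagent depletion; `"abrupt"` switches amplification off
#' once capacity is reached. The effective cycle count `n_eff` is the sum of
#' `s` over cycles: samples that start with more template consume their
#' cycles sooner, which is the mechanism coupling template overabundance to
#' GC bias.
#'
#' @param initial Named nonnegative copies per species.
#' @param gc GC fraction per species.
#' @param n_cycles Nominal cycle count.
#' @param capacity Total molecule cap of the reaction; must exceed
#'   `sum(initial)`.
#' @param params An [efficiency_params()].
#' @param mode `"expectation"` (deterministic per-cycle expectations) or
#'   `"stochastic"` (binomial per-molecule duplication).
#' @param saturation `"smooth"` or `"abrupt"`.
#' @return An object of class `pcr_run`: `initial`, `gc`, `realized`,
#'   `n_cycles`, `capacity`, `n_eff`.
#' @export
amplify <- function(initial, gc, n_cycles = 30, capacity,
                    params = efficiency_params(),
                    mode = c("expectation", "stochastic"),
                    saturation = c("smooth", "abrupt")) {
  mode <- match.arg(mode)
  saturation <- match.arg(saturation)
  initial <- unlist(initial)
  stopifnot(all(initial >= 0), length(gc) == length(initial),
            n_cycles >= 0, n_cycles == round(n_cycles))
  if (capacity <= sum(initial)) {
    stop("capacity must exceed total initial copies", call. = FALSE)
  }
  e <- pcr_efficiency(gc, params)
  n <- as.numeric(initial)
  n_eff <- 0
  for (cyc in seq_len(n_cycles)) {
    s <- if (saturation == "smooth") {
      max(0, 1 - sum(n) / capacity)
    } else {
      as.numeric(sum(n) < capacity)
    }
    if (s == 0) break
    inc <- if (mode == "expectation") {
      n * e * s
    } else {
      rbinom_big(n, e * s)
    }
    n <- n + inc
    n_eff <- n_eff + s
  }
  structure(
    list(initial = initial, gc = gc, realized = stats::setNames(n, names(initial)),
         n_cycles = n_cycles, capacity = capacity, n_eff = n_eff),
    class = "pcr_run"
  )
}

# Binomial draws with sizes beyond integer range: exact rbinom below 1e7,
# normal approximation above (relative error negligible at that scale).
rbinom_big <- function(size, prob) {
  size <- round(size)
  out <- numeric(length(size))
  prob <- rep_len(prob, length(size))
  small <- size <= 1e7
  if (any(small)) {
    out[small] <- stats::rbinom(sum(small), size[small], prob[small])
  }
  if (any(!small)) {
    m <- size[!small] * prob[!small]
    v <- sqrt(size[!small] * prob[!small] * (1 - prob[!small]))
    out[!small] <- pmax(0, pmin(size[!small], round(stats::rnorm(sum(!small), m, v))))
  }
  out
}

#' @export
print.pcr_run <- function(x, ...) {
  cat("pcr_run:", length(x$initial), "species,", x$n_cycles,
      sprintf("nominal cycles, n_eff = %.2f, total %.3g / capacity %.3g\n",
              x$n_eff, sum(x$realized), x$capacity))
  invisible(x)
}

#' Unsaturated cycles before reaching capacity
#'
#' Closed-form count of cycles a sample with total template `t0` and mean
#' efficiency `e` amplifies before hitting the reaction capacity:
#' `log(capacity / t0) / log(1 + e)`. Strictly decreasing in `t0`: a
#' 70-fold template excess at `e = 0.95` costs `log(70)/log(1.95)`, about
#' 6.4 effective cycles.
#'
#' @param t0 Total initial copies (`0 < t0`).
#' @param capacity Reaction capacity.
#' @param e Mean per-cycle efficiency.
#' @return Effective cycle count (0 when `t0 >= capacity`).
#' @export
effective_cycles <- function(t0, capacity, e) {
  stopifnot(t0 > 0, capacity > 0, e > 0)
  if (t0 >= capacity) return(0)
  log(capacity / t0) / log(1 + e)
}

#' Sample sequencing reads from an amplified pool
#'
#' Multinomial read sampling with probabilities proportional to realized
#' copies — the deep-sequencing readout.
#'
#' @param realized Nonnegative copies per species (not all zero).
#' @param depth Total reads to draw.
#' @return Integer read counts per species (named like `realized`).
#' @export
sequence_sample <- function(realized, depth) {
  realized <- unlist(realized)
  stopifnot(depth >= 0, all(realized >= 0))
  if (sum(realized) <= 0) stop("all-zero template pool", call. = FALSE)
  if (depth == 0) return(stats::setNames(numeric(length(realized)), names(realized)))
  counts <- as.numeric(stats::rmultinom(1, depth, realized / sum(realized)))
  stats::setNames(counts, names(realized))
}
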