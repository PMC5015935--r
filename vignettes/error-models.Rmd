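---
title: "Error models for pooled genetic screens: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error models for pooled genetic screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenerr)
```

# Scope

`screenerr` models three systematic error sources in pooled retroviral and
lentiviral screens and provides the statistics used to detect and correct
them:

1. **Barcode–ORF uncoupling by reverse-transcriptase template switching.**
   Virions package two genomes; in a pooled library these are usually from
   different clones, and a template switch between the ORF and its barcode
   produces a chimeric provirus whose barcode reports the wrong ORF.
2. **Packaging-plasmid carryover.** Residual transfection plasmid rides along
   with viral supernatant into transduced cells and is co-purified with
   genomic DNA, inflating the template pool of early reference samples until
   it dilutes out with cell division.
3. **GC-dependent PCR bias amplified by template overabundance.** Per-cycle
   amplification efficiency declines with template GC content. This cancels
   between two samples amplified for the same number of *effective* cycles,
   but a contaminated reference saturates its reaction sooner, experiences
   fewer effective cycles, and therefore under-penalises GC-rich elements —
   which then appear to deplete during the screen.

Each mechanism is implemented both as a generative simulation and as the
analysis that an experimentalist would run on count data.

# Recombination model

## Homozygous virions and the correction

With clone abundances $p_i$, the probability that both independently drawn
genomes of a virion come from the same clone is $h = \sum_i p_i^2$; for 11
equimolar clones $h = 1/11 \approx 9.09\%$. A switch inside such a virion is
invisible, so the measured shuffling frequency $f$ underestimates the true
switch frequency. The reported corrected estimate is

$$ f_\mathrm{true} = f \,(1 + h), $$

implemented in `correct_recombination_frequency()`. Note a deliberate
asymmetry: the *generative* model produces detectable chimeras at rate
$f = p\,(1-h)$ for per-virion switch probability $p$, whose exact inverse is
$p = f/(1-h)$, not $f(1+h)$. For the 720 bp assay ($f = 26.15\%$) the two
differ by about 0.24 percentage points (28.77% vs 28.53%). The analysis side
implements the $(1+h)$ form because that is the convention the corrected
frequencies are reported in; the simulator is calibrated through the exact
inverse (default per-design switch probabilities 0.2877 and 0.0600 solve
$p(1-1/11) = 0.2615$ and $0.0545$), and the two conventions are documented
rather than reconciled. First-order in $h$ they agree.

## Switch probability vs homology length

Only two (homology length, frequency) pairs constrain the model — 720 bp and
96 bp — so `recombination_model()` offers a calibrated lookup
(`fixed_per_design`, the default) plus two one-parameter extrapolation forms
(`per_base_linear`, `per_base_exponential`) fitted to those points by least
squares. No functional form is asserted as mechanistically correct; all are
monotone nondecreasing in homology length.

## Transduction

Integrations per cell are Poisson(MOI); zero-integrant cells are removed,
emulating antibiotic selection (the standard low-MOI screen assumption, MOI
0.5). Multi-integrant cells contribute each provirus independently. Virion
genome pairing ignores producer-cell co-transfection structure: pooled
transfection delivers many plasmids per producer cell, so free mixing is a
reasonable approximation. Recombination is modelled as at most one effective
switch per virion in the ORF–barcode interval — a Bernoulli event, not a
per-base crossover walk — because the data constrain only the aggregate
uncoupling probability.

# Contamination model

Carryover starts at `c0_std` copies per cell (default 70, the only
quantitative anchor: ~5.8 pg plasmid per 50 ng extracted DNA equals a >70-fold
copy excess over single-copy proviral integrants; `plasmid_copy_ratio()`
reproduces this arithmetic with 650 Da/bp and a 6.6 pg diploid genome, both
exposed as arguments). The load scales linearly with transfection input
(`dna_input_fraction` 1.0, 0.2, 0.1) and is reduced $10^3$-fold by nuclease
treatment of the supernatant (a configurable log-reduction; the default 3
corresponds to the 500 units/ml protocol and drives residual copies below
0.1/cell, i.e. below practical detection). In scenario configurations any
positive `benzonase_units` maps to the full default log-reduction; the dose–
response curve itself is not modelled because only detection limits, not
rates, are reported for the treatment.

Dilution over population doublings is
$c(t) = c_0\, 2^{-t} e^{-\delta t}$ with `decay_per_pd` $\delta = 0.5$ by
default: passive halving alone is too slow to match the observed fast early
loss (most carryover gone by 2 doublings, essentially all by 6), and the
extra exponential term is an explicitly phenomenological stand-in — whether
the early loss reflects degradation or uneven uptake is unresolved.

`qpcr_relative_signal()` models a vector-targeted qPCR that sees proviral and
plasmid template additively, normalised to a genomic control locus so that
one provirus per genome with no plasmid defines baseline 1 (hence 2 at equal
plasmid and proviral copies, 71 at the 70-fold excess).

# PCR and sequencing model

Per-cycle efficiency is clipped-linear in GC:
$e(g) = \mathrm{clip}(e_{\max} - \beta (g - g_\mathrm{ref}),\ e_{\min},
e_{\max})$ with defaults $e_{\max} = 0.95$, $\beta = 0.5$,
$g_\mathrm{ref} = 0.40$, $e_{\min} = 0.5$ — direction is observed, the form
and magnitude are free modelling parameters, which is why GC-bias acceptance
is property-based (sign and significance) rather than numeric.

Each cycle, species $i$ gains $n_i e_i s$ molecules where
$s = \max(0, 1 - N/C)$ is a shared saturation damping ($N$ total molecules,
$C$ reaction capacity). This smooth logistic-style approach to reagent
depletion is differentiable and avoids an arbitrary hard stop; an abrupt
variant (`saturation = "abrupt"`) is provided for sensitivity analysis. The
effective cycle count $n_\mathrm{eff} = \sum_\mathrm{cycles} s$ makes the
mechanism explicit: `effective_cycles()` gives the closed-form unsaturated
count $\log(C/t_0)/\log(1+e)$, so a 70-fold template excess at $e = 0.95$
costs $\log 70 / \log 1.95 \approx 6.4$ cycles. Samples are run to a fixed
nominal cycle count (default 30) with fixed capacity (default $10^{12}$), so
template-abundance differences surface *only* as $n_\mathrm{eff}$
differences. The three-round nested PCR of the laboratory protocol is
collapsed into one amplification: later rounds re-amplify an already
saturated pool, and the bias mechanism lives in the first round.

Sequencing is a multinomial draw over realized copies (`sequence_sample()`),
i.e. index-hopping, read errors and PCR chimeras are out of scope.

Under these defaults the simulated GC ladder (40–60% GC) spans roughly a
1.4-fold endpoint/reference recovery distortion at the 70-fold carryover gap
and close to 3-fold against a mass-matched naked-plasmid reference — the
directional behaviour the diagnostics are designed to flag. With the
efficiency slope fixed at 0.5 the 70-fold gap alone does not reproduce the
strongest fold-depletions seen in real screens; heavier contamination or a
steeper slope does, and both remain user-settable.

# Screen scenarios

`run_screen_scenario()` wires the pipeline: pooled transduction → reference
construction → growth → shared PCR parameterisation → sequencing. The
reference sample's template composition is the experiment's key degree of
freedom (`reference_mode`):

* `early_cells` — proviral templates plus carryover at `pds_ref` doublings
  (default 0, the standard early reference; the few days between
  transduction and collection are not mapped to doubling units).
* `equilibrated_cells` — the same cells after enough doublings (≥ 10) for
  the plasmid to dilute out, e.g. an uninduced 10-doubling arm of an
  inducible screen.
* `plasmid_mass_matched` — naked library plasmid at gDNA-equivalent mass.
  Mass arithmetic at 10 kb gives ~6×10^5 templates per genome-equivalent, a
  vast unmatched excess (the qualitative point — plasmid references must be
  copy-matched, not mass-matched — does not depend on the exact factor).
* `linearized_plasmid_in_gdna` — linearised plasmid diluted into carrier
  gDNA at one template per diploid-genome equivalent: copy-matched, hence
  unbiased.

The plasmid length (10 kb) is a stated working assumption, not a measured
value. Carried-over plasmid is apportioned across subpools inversely to
titer — equal viral representation requires more supernatant volume from
low-titer pools — which reproduces the inverse reads-vs-titer relation and
the several-fold subpool distortion in contaminated references.

Growth runs at integrant resolution: each provirus row carries the fitness
of its *expressed ORF* while reads report its *barcode*, so chimeric
integrants automatically inject discordance into barcode groups. Selection
coefficients are per doubling ($2^{1+s}$ relative growth); the population is
multinomially resampled at each doubling with size `representation` ×
elements, giving drift variance that scales as 1/representation. Ground
truth is defined on expected abundances (infinite-population limit) so
stochastic runs can be scored against it. The ground-truth-recovery check
uses a graded fitness landscape (coefficients spread over ±0.15) rather than
a sparse neutral-plus-enrichers mix: with almost all elements exactly
neutral, their true fold changes are tied and rank correlation is dominated
by noise among ties, so a rank-recovery criterion is only meaningful when
the truth actually orders the elements.

## What the generator does and does not emulate

Emulated: co-packaging and template switching; Poisson transduction with
selection; plasmid carryover, its protocol dependence and dilution; subpool
titer structure; selection with drift; saturation-limited GC-biased PCR;
multinomial sequencing. Not emulated: sequence-level reverse transcription,
episomal replication or plasmid integration, cell-cycle structure, PCR
chimera formation, read-level sequencing error, primer thermodynamics.
Passing tests therefore demonstrate that the *mechanisms* behave and
interact as specified, not that any particular real screen's noise floor is
matched.

# Numerical and testing choices

* Normalisation is counts-per-fixed-total (per million by default) — the
  simplest scheme consistent with "normalized read counts"; log2 fold change
  uses pseudocount 1 on normalised counts to guard zeros without compressing
  the mock screen's dynamic range.
* GC bins: exact strata when the ladder is discrete (≤ 8 unique values),
  else 2.5-percentage-point equal-width bins.
* The two-arm rate comparison defaults to an exact binomial test of the
  second arm's count at the first arm's observed rate (two-sided), which for
  17/65 vs 3/55 gives p ≈ 1.5×10⁻⁴; the construction is ambiguous in
  general, so Fisher's exact test is exposed as an alternative and no
  result is pinned to the exact p-value. No multiple-testing correction is
  applied anywhere — single correlations and one rate comparison are
  reported; users running many tests should correct downstream.
* Stochastic binomial duplication switches to a normal approximation above
  10⁷ molecules, where the relative error is negligible.
* Simulation sizes used in the test suite: mock screens at representation
  200 (matching the mock-screen protocol) with 1000 elements; recombination
  assays at 10⁵ sampled proviruses × 20 seeds; null-scenario calibration at
  50 seeds. These give Monte-Carlo standard errors comfortably below the
  tolerances asserted.
* One global seed is expanded into fixed per-stage substreams
  (`substream_seed()`), so a stage rerun in isolation reproduces its
  in-pipeline draws and full runs are byte-identical per seed.

# Known limitations

* The homozygosity correction and the generative inverse differ at second
  order in $h$ (above); both conventions are intentional.
* Efficiency-vs-GC and reaction capacity are unmeasured; all GC-bias claims
  are directional.
* The Benzonase dose–response is a step (untreated vs treated) rather than a
  titration.
* Titer-to-plasmid apportionment assumes carryover proportional to
  supernatant volume with a single proportionality constant.
* `fixed_per_design` switch rates interpolate nothing: a new design needs
  either a measured rate or one of the per-base extrapolation forms.
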