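---
title: "Methods: 3C-qPCR interaction profiling and loop calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3C-qPCR interaction profiling and loop calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threeCquant)
```

## Scope and model

`threeCquant` analyses single-locus chromosome conformation capture (3C)
experiments read out by TaqMan qPCR. The measurement model is multiplicative
throughout: one PCR cycle corresponds to one doubling of template at perfect
efficiency, so all quantities are differences of Cq values mapped through
`2^x`, and all statistics are computed on the log scale where such ratios
are approximately normal.

The 3C stage rests on three assumptions:

1. **Control-locus normalisation removes library effects.** Each junction's
   quantity is expressed relative to a ligation junction inside a
   ubiquitously expressed, conformationally invariant locus (an *ERCC3*
   junction in the motivating application). Any factor that multiplies every
   junction of a library — template amount, ligation efficiency, plate
   offset — cancels. This is asserted as an exact invariance test: a global
   Cq shift of a plate leaves every relative frequency unchanged to 1e-12.
2. **Background contacts decay as a power law.** Random (non-looping)
   contact frequency falls with genomic distance `d` as `a·|d|^(−b)`, the
   standard polymer contact-decay shape. Upstream and downstream are pooled
   on `|d|`: with a seven-anchor panel there are too few points per side for
   a two-sided fit (a two-sided mode exists but is off by default).
3. **Loops are multiplicative excursions above the decay.** A looping
   fragment's frequency is the background times a loop fold, which makes
   "X-fold over background" both the generator's ground-truth parameter and
   the caller's decision statistic.

## Distance-decay fit and peak exclusion

`fit_background()` fits `log(rel) = log_a − b·log|d|` by least squares.
Loop points would inflate the background, so candidate peaks are excluded
iteratively (up to 3 rounds): after each fit, points whose residual exceeds
2 robust scale units are dropped, where the scale is the median absolute
deviation (MAD) of the kept residuals **floored at 0.25 natural-log units**.

Both halves of that scale matter, and the floor is the result of a design
decision worth recording. A classical RMS-based standardised residual
suffers masking with as few as seven points: two genuine peaks inflate the
RMS so much that neither exceeds twice it (the statistic is bounded by the
square root of the residual degrees of freedom), and the iteration never
starts. A raw MAD has the opposite failure: on a quiet no-loop profile it
shrinks to replicate noise and ordinary scatter gets excluded. The floor —
requiring a point to sit at least ~1.65-fold above the curve before it can
be excluded — separates the two regimes cleanly. In the package's Monte
Carlo checks (200 seeds each), loop profiles exclude exactly the planted
peaks and no-loop profiles exclude nothing.

If the fitted exponent is not positive (a profile with no usable decay),
the model falls back to a flat background at the robust mean of the kept
log frequencies, with a warning; predictions remain positive everywhere.

## Loop calling

`fold_enrichments()` reports, per fragment, the observed frequency over the
fitted background and over a promoter-proximal reference; `call_loops()`
flags fragments exceeding both thresholds.

* **Thresholds** default to 3.0× background and 1.5× proximal. Loop
  profiles in the motivating data sit at 6–9× background and 2–3×
  proximal, no-loop profiles near 1×, so the defaults bisect the two
  populations with a wide margin; both are exposed in the run
  configuration.
* **Proximal reference**: the assayed point with the smallest `|d|` inside
  a window (4 kb by default, matching the "close to the promoter"
  comparison the assay design implies). When no assayed fragment falls in
  the window — the bundled anchor panel's closest point is at −6.8 kb —
  the nearest fragment is used and a warning is emitted; the pipeline
  configuration therefore sets the window to 8 kb, a statement about this
  panel's geometry rather than a change to the function default.
* The proximal reference itself is never called a peak.

## Why the generator's decay exponent is 0.5

The generator's defaults are the study conditions, so their internal
consistency matters. The motivating profiles put the upstream loop at ~9×
the background **and** ~3× the proximal fragment, with anchors at −63.2 kb
and −6.8 kb. Those two folds jointly determine the decay exponent:
`9·(6.8/63.2)^b = 3` gives `b ≈ 0.49`. A steeper exponent (for example
`b = 1`) would make the same 9× background excursion fall *below* the
proximal fragment (fold ≈ 0.97) and no threshold pair could call it while
rejecting nulls. The default is therefore `b = 0.5`, with the amplitude
`a = 6.8^b` pinning the proximal fragment at rel ≈ 1. Under these
conditions the planted 9× and 6× loops yield proximal folds of ~3.0 and
~2.25, reproducing the qualitative structure of the motivating data.

## Synthetic-data generator

`scenario()` fixes every parameter; four presets (`pc3m`, `pc3`,
`fibroblast`, `null`) encode the cell-line effect sizes the pipeline is
tested against (loops 9×/6× or one 9× loop or none; expression folds
4.5/3.0, 2.0/2.0 or 1; ChIP folds 30×/60×, 5×/3× or 1×; ddPCR ratios 2.5,
1.4 or 1).

* **Locus**: a 201-kb sequence with HindIII sites planted so each of seven
  anchors (−79.7 … +119.3 kb) receives a 1.2-kb fragment centred exactly on
  it, a bait fragment containing the TSS, and filler sites between anchors;
  spurious motif occurrences are edited out, so digestion recovers the
  planted map exactly. The 25-site map is deterministic given the geometry;
  only the filler sequence consumes randomness.
* **3C plates**: junction Cq = normaliser Cq − log2(true rel) + Gaussian
  noise per replicate; digestion-QC wells encode a true per-site efficiency
  of 0.92.
* **Expression plates**: per-sample loading offsets (which must cancel in
  ΔΔCt) plus per-assay folds arranged so the ΔΔCt fold against *each*
  reference gene equals the stated truth — when the two reference genes
  imply different folds (4.5 vs 3.0), the reference genes themselves shift
  between lines, which is the only way both printed values can be true
  simultaneously.
* **ChIP wells**: a shared IgG percent-input baseline (0.05%) per region,
  antibody signal at `fold ×` baseline, two independent experiments, 1%
  input fraction.
* **ddPCR wells**: duplicate wells of 15,000 droplets; positives drawn
  binomially from `p = 1 − e^(−λ)`, with per-sample loading factors that
  cancel in the normalised ratio. A deterministic `"expected"` mode rounds
  the expected count to the nearest droplet — exactness claims for this
  generator are therefore at 1e-3, not machine precision, because counts
  are integers.

Cq noise defaults (sd 0.15 for 3C and ChIP, 0.12 for expression, 3
replicates) are realistic plate-to-plate dispersions for TaqMan/SYBR assays
and keep the presets' significance patterns stable; no dispersion was
published for the motivating study, so these are generator choices, flagged
as such.

What the generator does **not** emulate: GC/mappability-dependent primer
efficiencies, partial digestion, rain in ddPCR droplet classification,
inter-library ligation-efficiency drift beyond a global factor, and any
sequence realism beyond motif placement. Passing tests therefore
demonstrate estimator correctness under the stated noise model, not
robustness to every bench artefact.

## Companion quantifications

* **ΔΔCt** (`delta_delta_ct()`): replicate-wise ΔCq, Welch t-test
  (a robust default at n = 3; the motivating work names no test), CI by
  t-interval on ΔΔCq back-transformed. Amplification efficiency `E ∈ (0,1]`
  defaults to 1 (no standard curves to estimate it from); the
  efficiency-corrected ratio `(1+E_t)^{ΔCq_t}/(1+E_r)^{ΔCq_r}` is used when
  efficiencies are supplied. Dual reference genes are reported separately
  by default (as expression figures usually show); a geometric-mean mode is
  available. Noiseless plates are handled explicitly: constant groups give
  p = 1 (equal means) or p = 0, rather than a t-test error.
* **Digestion QC** (`digestion_efficiency()`, `qc_digestion()`): the
  ratio-of-ratios percent with a strict `> 85%` per-site pass rule;
  negative efficiencies are reported as anomalies, not clipped.
* **ChIP** (`percent_input()`, `fold_over_igg()`): both normalisations are
  reported side by side; experiments combine as geometric means with the
  test on log2 percent input. The three-tier star scheme is the default,
  with a two-tier variant available via `star_thresholds`.
* **ddPCR** (`poisson_concentration()`): delta-method CI by default, exact
  Clopper–Pearson for low counts; wells with < 10 positive or < 10 negative
  droplets are flagged. Droplet volume defaults to 0.85 nl and cancels in
  every ratio the package reports.
* **Star thresholds**: 0.05/0.01/0.001. A figure legend in the motivating
  study prints "p < 0.5" for one tier; this is treated as a typo for 0.05,
  consistent with the body text.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally and in BED; 1-based only in
  human-readable output. Cut position defaults to the motif start
  (sub-motif offsets configurable; fragment identity is all that matters
  downstream). `N` never matches the motif.
* TSS distances use fragment midpoints — single per-fragment distances
  require a convention and the midpoint is the least biased one.
* Ties/degenerates: saturated ddPCR wells are errors, not infinities; zero
  proximal signal is an error; profiles need ≥ 4 distinct distances to fit;
  plates with duplicate well keys resolve last-wins with a warning.
* Libraries combine by averaging per-fragment log relative frequencies
  after per-library normalisation.

## Problem sizes

The bundled checks run at the scale a desk validation needs: 20-seed means
for effect-size recovery (3C folds, ΔΔCt, ddPCR, ChIP), 100 seeds for the
digestion-QC pass rate, 200 seeds each for loop-caller specificity and
sensitivity, and 1000 simulated wells for ddPCR CI coverage. These sizes
give Monte-Carlo standard errors a factor of a few below the tolerances
being asserted.

## Known limitations

* The power-law background is a modelling choice; the motivating data only
  establish monotone decay. With seven anchors the exponent is estimated
  with ~5% relative error at the default noise, which is adequate for fold
  calls but not for comparing exponents between conditions.
* The loop caller is a thresholding rule, not a hypothesis test; it
  reports fold ratios, and its error rates are calibrated by simulation
  under the stated noise model only.
* Per-assay 3C calibration factors (random-ligation/BAC controls) default
  to 1 — a hook is provided, but no such control is modelled.
* The ERCC3-style normaliser is treated as an opaque reference junction;
  its own interaction level is not modelled.
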