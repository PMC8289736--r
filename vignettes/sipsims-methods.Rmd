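---
title: "Methods: heavy-fraction SIP detection and NanoSIMS single-cell quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heavy-fraction SIP detection and NanoSIMS single-cell quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipsims)
```

# Scope

`sipsims` implements two quantitative procedures used in DNA
stable-isotope-probing (SIP) studies of microbial communities, together
with synthetic-data generators that provide ground truth for testing:

1. detection of ¹³C-labelled ASVs from CsCl density-gradient amplicon
   profiles (and of substrate responders from microcosm time series), and
2. single-cell ¹³C atom-fraction quantification from NanoSIMS multilayer
   ion-count images with an enrichment call against a natural-abundance
   control.

Everything upstream (ASV inference, taxonomy, qPCR) and downstream
(phylogenetics, metagenomics) is out of scope.

# Gradient SIP detection

## Model and assumptions

DNA that incorporates ¹³C during replication becomes denser and
equilibrates deeper in a CsCl gradient. The readout is compositional:
per-fraction ASV relative abundances. The procedure therefore makes a
*categorical* labelling call — it does not estimate atom-fraction excess
from band shifts. For each timepoint, in-window fractions of the ¹³C
treatment and of the ¹²C control are treated as two independent groups of
observations per ASV; fractions come from different gradients, so the
unpaired rank-sum (Mann–Whitney) test is the default rather than a paired
signed-rank test (a paired variant is available via
`compare_groups_wilcoxon(paired = TRUE)` for sensitivity analysis).

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| windows | 1.725–1.741, 1.735–1.746 | g/ml | heavy-fraction membership (bounds inclusive, overlap allowed) |
| fractions per window | 3–5 | — | surplus trimmed toward the window midpoint, ties toward higher density |
| `abundance_cutoff` | 0.001 (gradient), 0.05 (microcosm) | fraction of 1 | per-sample abundance a taxon must exceed |
| `prevalence_cutoff` | 0.1 | fraction of pooled samples | `ceiling(0.1 * n)` samples must exceed the abundance cutoff |
| `max_median_cutoff` | 0.001 | fraction of 1 | median must exceed this in at least one group |
| `replace_zero` | FALSE | — | zeros stay zeros; TRUE substitutes half the smallest nonzero value |
| `alpha` | 0.05 | — | raw two-sided level; significance additionally requires direction *up* |
| `min_timepoints` | 3 (gradient), 2 (microcosm) | — | timepoints required for a labelled/responder call |
| `window_rule` | `"any"` | — | a timepoint counts if at least one window is significant (`"all"` available) |

Filter semantics for serial group comparisons are under-specified in common
usage: cutoffs here are fractions of 1 applied to relative abundances,
prevalence is computed over the union of the two groups with a ceiling
rule, and the median rule passes if *either* group's median exceeds the
cutoff. All three interpretations are configurable.

## Numerical choices

* **Exact versus approximate p-values.** The exact rank-sum null
  distribution is used when the combined sample size is at most 20 and the
  data are tie-free; otherwise the normal approximation with tie correction
  (and continuity correction) applies. With triplicate microcosms, however,
  the exact two-sided distribution cannot go below p = 0.1, so the
  microcosm responder mode defaults to the plain normal approximation
  *without* continuity correction — the convention of the Rhea-style serial
  group comparisons this reproduces, under which a 3-vs-3 comparison with
  complete separation yields p = 0.0495 and can clear α = 0.05. Both
  switches (`exact`, `continuity`) are explicit arguments.
* **One-sidedness.** Two-sided p-values are reported, but a significant
  call also requires the ¹³C (or substrate) group mean to be higher. This
  matches the biology (labelling can only add density) and suppresses the
  compositional false positives that arise when labelled taxa invade heavy
  fractions and push everything else down.
* **Multiplicity.** Raw p-values at α = 0.05 are the default, matching how
  such screens are usually reported; Benjamini–Hochberg per
  timepoint × window is available (`p_adjust = "BH"`).
* **Degenerate inputs.** Two identical constant groups give p = 1 and
  direction `none`; a timepoint missing one treatment is skipped with a
  warning and excluded from the `timepoints_tested` denominator rather than
  counted as non-significant.

# NanoSIMS single-cell quantification

## Order of operations

Raw integer counts are (1) dead-time corrected per pixel, plane and
species; (2) drift-aligned by integer-pixel cross-correlation of each plane
against plane 1 on the ¹²C¹⁴N⁻ channel (the cellular biomass indicator);
(3) accumulated over planes on pixels valid in every plane; (4) summarized
per ROI as ratios of summed counts. Dead time is a per-dwell physical
effect, so it must precede any mixing of pixels; integer shifts preserve
counts exactly, which is why subpixel interpolation is deliberately not
offered. Out-of-frame pixels after a shift are marked invalid and excluded
from accumulation, never wrapped or zero-filled into the data.

## The isotope ratio

With ¹²C₂⁻ and ¹³C¹²C⁻ detected (¹³C₂⁻ not in the detector set), the atom
fraction estimator is the ratio of summed counts

\[
\widehat{x} = \frac{{}^{13}C^{12}C}{2\cdot{}^{12}C_2 + {}^{13}C^{12}C}.
\]

Under random pairing of carbon atoms into C₂⁻ ions the species rates are
proportional to \((1-x)^2\), \(2x(1-x)\) and \(x^2\); the ratio above
equals \(x\) *exactly* for every \(x\), because the ¹²C atom of each mixed
pair that the denominator omits compensates the undetected ¹³C₂⁻ pairs.
Internally `atomic_counts_from_c2()` therefore defines
`n13C = C13C12` and `n12C = 2·C2`, so `n13C/(n12C + n13C)` reproduces this
ratio, and the same totals feed the Poisson error
\(\sigma = \sqrt{n_{12}^2 n_{13} + n_{13}^2 n_{12}}/(n_{12}+n_{13})^2\).
ROI values are ratios of ROI-summed counts (not means of per-pixel
ratios): the error formula operates on total counts per object, and the
ratio-of-sums is the minimum-variance way to use them.

## Enrichment call

A cell is significantly enriched iff

1. its at% ¹³C exceeds the upper bound of the two-sided 99.9 % confidence
   interval of the control cells, and
2. `3 × sigma_Pois < atpct − mean(control)`.

"Confidence interval of the values" is ambiguous between a CI of the
control *mean* and a tolerance band on single-cell *values*; the default is
the t-based CI of the mean (`mode = "mean_ci"`), with
`mode = "population"` (mean + z·sd) available. With the default, criterion
1 alone would flag a fair share of honest control cells (the bound shrinks
with √n); criterion 2 is what keeps the control false-call rate at the
3σ level.

Unit conventions: at% throughout (σ multiplied by 100); δ¹³C conversions
use the VPDB reference ratio 0.0111802 (configurable).

# Synthetic data: what it emulates and what it does not

## Gradient generator

Each taxon's DNA band is a Gaussian (sd `band_sigma` = 0.004 g/ml) centred
at a linear buoyant-density model,
`rho = 1.660 + 0.098·GC + 0.036·(x − 0.0107)/(1 − 0.0107)` g/ml — standard
literature constants, exposed in `density_model()` and never treated as
measured values. Twenty fractions span 1.690–1.760 g/ml (densities below
~1.71 g/ml, where unlabelled low-GC DNA bands, are typically not recovered
in practice, which the truncated grid reflects); per fraction, read counts
are multinomial at depth 20 000. In the ¹²C control every taxon is forced
to natural abundance. The default detection scenario
(`sip_scenario_taxa()`) plants 12 low-GC (30–33 %), strongly labelled
(atom fraction 0.90–1.0) ASVs across 4 groups among 200 unlabelled
background ASVs (GC 30–70 %, log-normal abundances): the labelled bands
then sit inside the heavy windows only in the ¹³C treatment, reaching
single-fraction relative abundances from a few percent up to ~25 % against
essentially zero in the control — the magnitude of contrast seen for
strong natural responders. The microcosm generator multiplies responder
base abundances by a per-timepoint profile in the substrate treatment
only, with optional Dirichlet overdispersion (default 0 so null
calibration stays exactly multinomial).

Not emulated: sedimentation-equilibrium physics, per-fraction volume or
recovery variation, PCR/primer bias, chimeras, sequencing error, or
compositional correlations beyond the multinomial constraint. Passing the
recovery tests therefore shows the *procedure* is correct and calibrated
under its stated sampling model, not that real gradients are free of those
artefacts.

## NanoSIMS generator

Per pixel and plane, the C₂-family ion count is Poisson at the local
carbon rate; each ion is a random atom pairing at the local atom fraction,
split into ¹²C₂⁻ / ¹³C¹²C⁻ / ¹³C₂⁻, with the ¹³C₂⁻ ions generated and
then discarded so the estimator's unbiasedness under the discard is itself
testable. Cells are ~100-px ellipses; CN⁻ and ³¹P⁻ channels mark biomass;
planes can drift by an integer step per cycle; optional dead-time
distortion applies the inverse non-paralyzable map, rounded to integers
(raw data are integer counts — at realistic count rates the distortion is
well below the Poisson noise, so the rounding is immaterial). The two
canonical scenarios use 51 cells at 7.5 at% and 25 cells at 1.08 at%, 10
planes, and 200 C₂-family counts per pixel per plane — a count level
typical of C₂⁻ secondary-ion imaging at ~10 ms dwell — giving per-cell
counting errors of ~0.04–0.02 at%, so the 1 %-relative recovery checks are
driven by estimator correctness rather than luck.

Not emulated: quasi-simultaneous arrival effects, EM yield drift,
topography, sample charging, or subpixel drift.

# Test and verification sizes

The test suite freezes closed-form spot values (dead-time correction of
1000 counts at τ = 44 ns/T = 10 ms; at% and σ for C₂ = 490, ¹³C¹²C = 11;
δ = 0 ↔ 1.10566 at%), checks exact rank-sum p-values against brute-force
enumeration of all rank assignments up to combined n = 12 at 10⁻¹²,
validates σ_Pois against the Monte-Carlo sd of 10⁵ Poisson draws (5 %),
and runs the recovery scenarios at the sizes above: 10 seeds of the
12-planted-ASV gradient experiment (expected: exactly 12 labelled, 4
groups, zero false positives) and single-seed 51-cell / 25-cell NanoSIMS
recoveries within 1 % relative. Null calibration uses label-free gradient
simulations and a one-sided Kolmogorov–Smirnov check that the p-value ECDF
does not exceed the uniform CDF — rank-sum p-values at n = 3–5 per group
are heavily discrete, so a two-sided uniformity test would reject by
construction; super-uniformity (conservatism) is the property that
matters for error control.

# Known limitations

* The gradient call is categorical; it does not quantify atom-fraction
  excess or model band shifts, and weakly labelled taxa whose bands stay
  below 1.725 g/ml are invisible to the heavy-window screen.
* With triplicates, the responder mode's p = 0.0495 floor means single
  comparisons carry essentially no multiplicity headroom; the ≥ 2
  timepoints rule is the real error-control device.
* Drift correction is integer-pixel; acquisitions with large subpixel
  drift per cycle will retain up to half a pixel of blur.
* The dual-criterion enrichment call assumes the control cells share the
  measurement session's instrumental state; no inter-session drift model
  is provided.
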