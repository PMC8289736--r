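# sipsims

Stable isotope probing (SIP) with ¹³C-labelled substrates identifies which
members of a microbial community assimilate a compound of interest: organisms
that incorporate the heavy isotope while replicating produce denser DNA,
which migrates further in a CsCl buoyant-density gradient, and cells that
grow on the labelled carbon acquire a ¹³C atom fraction far above the ~1.1 %
natural abundance, measurable ion-by-ion with NanoSIMS. `sipsims` implements
both readouts as a tested R pipeline for people running DNA-SIP amplicon
experiments and single-cell NanoSIMS follow-ups:

* **Gradient SIP detection** — find amplicon sequence variants (ASVs) whose
  relative abundance in *heavy* density windows (e.g. 1.725–1.741 and
  1.735–1.746 g/ml) is significantly higher in ¹³C-substrate gradients than
  in parallel ¹²C-control gradients, repeatedly across incubation
  timepoints.
* **Microcosm responder detection** — the same machinery applied to
  replicated microcosm time series (substrate vs no-substrate controls).
* **NanoSIMS single-cell quantification** — per-cell ¹³C atom percent from
  multilayer ion-count images with dead-time correction, drift alignment,
  Poisson counting errors, and a dual-criterion enrichment call.
* **Synthetic-data generators** — gradient, microcosm and ion-image
  simulators with known ground truth, so every stage is testable without
  instrument data.

## The statistics at the core

**Gradient screening.** For each timepoint and each heavy window, the
relative abundances of an ASV across the 3–5 in-window fractions of the ¹³C
treatment are compared against the corresponding ¹²C-control fractions with
a two-sided Wilcoxon rank-sum test (exact null distribution when the
combined n ≤ 20 and there are no ties; normal approximation with tie
correction otherwise). ASVs first pass abundance/prevalence/median cutoffs
(defaults `abundance_cutoff` 0.001, `prevalence_cutoff` 0.1,
`max_median_cutoff` 0.001, zeros kept as zeros). A call is *enrichment-only*:
significance requires p ≤ α **and** a higher mean in the ¹³C treatment. An
ASV is labelled when significant at ≥ 3 timepoints (≥ 2 for microcosm
responders, which default to the plain normal approximation used by serial
group comparison pipelines — with triplicates, complete separation gives
p = 0.0495).

**NanoSIMS quantification.** With detected species ¹²C₂⁻ and ¹³C¹²C⁻, the
¹³C atom fraction is the per-object ratio of summed counts

```
at% 13C = 100 · 13C12C / (2·12C2 + 13C12C)
```

which is exactly unbiased for the true atom fraction under random isotope
pairing, despite ¹³C₂⁻ not being detected. Counts are first corrected per
pixel for detector dead time τ (non-paralyzable model, `m / (1 − m·τ/T)`
with dwell time T), planes are aligned by integer-pixel cross-correlation on
the ¹²C¹⁴N⁻ channel, and ROI statistics are ratios of summed counts. The
counting error is

```
sigma_Pois = sqrt(n12C²·n13C + n13C²·n12C) / (n12C + n13C)²   (× 100, at%)
```

and a cell is called enriched iff its at% exceeds the upper bound of the
99.9 % confidence interval of the natural-abundance control **and**
3·σ_Pois is smaller than its distance to the control mean.

## Worked example

```r
library(sipsims)

# 1. simulate a gradient experiment planting 12 labelled ASVs among 200
taxa <- sip_scenario_taxa(n_labelled = 12, n_groups = 4,
                          n_background = 200, seed = 42)
sim  <- simulate_gradient_experiment(synth_gradient_config(taxa, seed = 42))
res  <- detect_labelled_asvs(sim$table)        # default windows + cutoffs
head(res$summary, 4)
#>     asv_id timepoints_significant timepoints_tested labelled
#> 1 ASV_L001                      4                 4     TRUE
#> 2 ASV_L002                      4                 4     TRUE
#> 3 ASV_L003                      4                 4     TRUE
#> 4 ASV_L004                      4                 4     TRUE
aggregate_group_calls(res$summary, sim$truth$groups)
#>   group_id n_labelled                    asv_ids
#> 1  group_1          3 ASV_L001,ASV_L005,ASV_L009
#> 2  group_2          3 ASV_L002,ASV_L006,ASV_L010
#> 3  group_3          3 ASV_L003,ASV_L007,ASV_L011
#> 4  group_4          3 ASV_L004,ASV_L008,ASV_L012

# 2. single-cell NanoSIMS quantification against a control culture
ctrl <- simulate_nanosims_stack(nanosims_scenario("control",  seed = 42))
lab  <- simulate_nanosims_stack(nanosims_scenario("labelled", seed = 42))
ctrl_cells <- nanosims_quantify(ctrl$stack, ctrl$rois)$cells
ref   <- build_control_reference(ctrl_cells$atpct, ci_level = 0.999)
cells <- nanosims_quantify(lab$stack, lab$rois, control = ref)$cells
round(c(mean_control = mean(ctrl_cells$atpct),
        mean_labelled = mean(cells$atpct),
        upper_bound = ref$upper_bound, enriched = sum(cells$enriched)), 4)
#>  mean_control mean_labelled   upper_bound      enriched
#>        1.0833        7.4905        1.0933       51.0000
```

The 12 planted labelled ASVs are recovered exactly and fall into their 4
taxon groups; the 51 simulated labelled cells (true composition 7.5 at%
¹³C) average 7.49 at%, every one called enriched against the 25-cell
natural-abundance control (1.08 at%), none of the controls mis-called.

A command-line layer over the same functions lives in
`inst/cli/sipsims.R` (`simulate-gradient`, `simulate-nanosims`,
`detect-labelled`, `detect-responders`, `nanosims-quantify`, `report`); every
run writes a JSON manifest of its parameters and input digests.

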