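# arcoephys

Zebra finch song is driven by projection neurons of the robust nucleus of
the arcopallium (RAPNs), upper motor neurons that fire ultranarrow action
potentials (half-width ~0.2 ms at body temperature) at high rates — a
phenotype they share with primate Betz cells and owe largely to
high-threshold, fast-gating Kv3.1 potassium channels. Their neighbours in
the dorsal intermediate arcopallium (AId), which serve non-vocal somatic
motor control, fire spikes roughly twice as broad. `arcoephys` is an R
package plus analysis workflow for quantifying that contrast end to end:

- a single-compartment conductance-based neuron (`make_preset()`,
  `simulate_current_clamp()`, `simulate_voltage_clamp()`) with Na⁺, a
  low-threshold delayed rectifier, a Kv3-type high-threshold conductance
  (V½ = −10 mV, sub-millisecond activation), an inactivating A-type
  current, temperature Q10 scaling, and a drug panel (TEA, 4-AP, AUT5);
- spike waveform metrics (`detect_spikes()`, `extract_ap_features()`):
  dV/dt-criterion threshold (10 V/s), interpolated half-width, phase-plane
  maximum depolarization/repolarization rates, AHP, F-I curves
  (`fi_analysis()`);
- passive properties (`fit_tau()`, `input_resistance()`,
  `capacitance_and_area()`): τ_m from AICc-selected single/double
  exponential fits, R_in from the V-I slope, C_m = τ_m/R_in, and the
  capacitance-derived surface area at 1 µF/cm² (1 pF ↔ 100 µm²);
- voltage-clamp decomposition (`subtract_currents()`, `vclamp_metrics()`):
  drug-sensitive currents by sweep subtraction, A-type peak and time to
  peak, sustained current 200 ms after onset, degree of inactivation;
- SWC morphometry (`sholl()`, `spine_density()`, `spine_geometry()`,
  `dendrite_geometry()`, `soma_geometry()`, `summarize_morphometry()`):
  Sholl profiles, 30 µm-segment and rolling-window spine densities,
  frustum surface areas, voxelized union volumes, soma contour
  triangulation, shrinkage-adjusted totals and surface-to-volume ratios;
- ISH densitometry (`window_od()`, `expression_ratio()`,
  `count_labeled_cells()`): background-subtracted optical density in
  200×200 µm windows and labeled-cell counts at a 2.5× background
  threshold;
- the study's statistics (`compare_groups()`, `anova_two_way()`,
  `rm_anova_two_way()`): Student's t vs Mann-Whitney U selected by
  normality/variance diagnostics, factorial ANOVA with Tukey post hoc,
  and repeated-measures ANOVA with Greenhouse-Geisser correction;
- synthetic-data generators for all of it (`generate_swc()`,
  `generate_spiny_cable()`, `generate_soma_stack()`,
  `generate_ish_image()`), each with analytic ground truth.

The model neuron's central knob is the Kv3 conductance (3400 nS in the
RAPN-like preset vs 400 nS in the AId-like preset); every pipeline contrast
— spike width, repolarization rate, F-I gain, TEA/4-AP sensitivity, AUT5
modulation, the high-threshold sustained current — follows from it.

## Worked example

```r
library(arcoephys)

rapn <- make_preset("RAPN-like")
aid  <- make_preset("AId-like")

hw <- function(p, temp) {
  ft <- trace_ap_features(simulate_spontaneous(p, 2000, temp),
                          discard_ms = 300)
  mean(ft$half_width)
}
round(c(rapn_24 = hw(rapn, 24), aid_24 = hw(aid, 24),
        rapn_40 = hw(rapn, 40), aid_40 = hw(aid, 40)), 3)
#> rapn_24  aid_24 rapn_40  aid_40
#>   0.463   0.927   0.112   0.231
```

The RAPN-like spike is half as wide as the AId-like spike at both
temperatures, and both narrow steeply from 24 °C to 40 °C — the
Q10-driven speedup of gating. Blocking Kv3 preferentially broadens the
narrow spike:

```r
tea <- drug_preset("TEA")   # 500 uM: blocks 80% of Kv3, 50% of A-type
round(c(rapn_fold = hw(apply_drug(rapn, tea), 24) / hw(rapn, 24),
        aid_fold  = hw(apply_drug(aid, tea), 24) / hw(aid, 24)), 2)
#> rapn_fold  aid_fold
#>      2.40      1.99
```

and the TEA-sensitive current isolated by sweep subtraction is an order of
magnitude larger in the RAPN-like cell at 0 mV (71.4 vs 8.4 nA sustained)
while staying marginal in both at −30 mV — the high-threshold signature.

The full synthetic study (spontaneous spikes, F-I curves, drug panel,
passive properties, clamp decomposition, morphometry, ISH, statistics) runs
from the numbered drivers:

```sh
Rscript analysis/01_spontaneous_spikes.R   # ... through 08_group_statistics.R
```

each of which prints its findings and writes a table under `results/`.
`run_pipeline(default_config(seed = 1))` does the same in one call and is
byte-reproducible for a fixed config.

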