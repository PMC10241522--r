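#!/usr/bin/env Rscript
# Pharmacology of the spike waveform: Kv3 blockers (TEA, 4-AP) broaden
# spikes and slow repolarization in both classes but disproportionately in
# the Kv3-rich preset; the positive modulator AUT5 does the reverse and only
# meaningfully in the Kv3-rich preset.
library(arcoephys)

dir.create("results", showWarnings = FALSE)
cfg <- default_config(seed = 1)
ph <- run_pipeline(cfg, stages = "pharm")$pharm
write.csv(ph, "results/03_pharmacology.csv", row.names = FALSE)

for (d in unique(ph$drug)) {
  sub <- ph[ph$drug == d, ]
  cat(sprintf("%-4s half-width fold: RAPN %.2f vs AId %.2f | repol fold: %.2f vs %.2f\n",
              d,
              sub$half_width_fold[sub$preset == "RAPN-like"],
              sub$half_width_fold[sub$preset == "AId-like"],
              sub$repol_fold[sub$preset == "RAPN-like"],
              sub$repol_fold[sub$preset == "AId-like"]))
}
cat(sprintf("AUT5 steady-state evoked rate change (RAPN): %+.1f%%\n",
            ph$steady_state_change_pct[ph$drug == "AUT5" &
                                         ph$preset == "RAPN-like"]))
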