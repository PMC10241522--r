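#!/usr/bin/env Rscript
# Voltage-clamp K+ current decomposition: 200 ms steps to -30 and 0 mV from
# -80 mV with Na+ silenced; the TEA-sensitive component is isolated by
# subtracting post-TEA from pre-TEA sweeps. The Kv3-rich preset carries a
# far larger high-threshold (0 mV) TEA-sensitive current, while the -30 mV
# currents stay small in both classes.
library(arcoephys)

dir.create("results", showWarnings = FALSE)
cfg <- default_config(seed = 1)
vc <- run_pipeline(cfg, stages = "vclamp")$vclamp
write.csv(vc, "results/05_vclamp_decomposition.csv", row.names = FALSE)

print(vc[, c("preset", "test_mv", "i200_pre", "i200_tea_sensitive",
             "a_peak_tea_sensitive", "time_to_peak_tea_sensitive")],
      row.names = FALSE)
r0 <- vc$i200_tea_sensitive[vc$preset == "RAPN-like" & vc$test_mv == 0]
a0 <- vc$i200_tea_sensitive[vc$preset == "AId-like" & vc$test_mv == 0]
cat(sprintf("TEA-sensitive sustained current at 0 mV: %.1f vs %.1f nA (%.1fx)\n",
            r0, a0, r0 / a0))
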