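#!/usr/bin/env Rscript
# Group comparison of per-cell spike half-widths between the two classes,
# using the diagnostic-driven selection rule (Student's t when both samples
# are normal with equal variances, Mann-Whitney U otherwise).
library(arcoephys)

dir.create("results", showWarnings = FALSE)
cfg <- default_config(seed = 1)
st <- run_pipeline(cfg, stages = "stats")$stats
write.csv(st, "results/08_group_statistics.csv", row.names = FALSE)

cat(sprintf("%s: %s, statistic %.2f, p = %.2g (means %.3f vs %.3f ms)\n",
            st$comparison, st$test_name, st$statistic, st$p_value,
            st$mean_a, st$mean_b))
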