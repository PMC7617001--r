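#!/usr/bin/env Rscript
# Step 3 -- Surrogate activation thresholds.
# Runs the calibrated 30-neuron bank (6 layers x 5 clones) against the
# matched conventional and PWM coil currents, then summarises the
# per-layer median threshold reduction and the cross-pulse regression.

library(pwmtms)
dir.create("results", showWarnings = FALSE)

pair <- default_waveform_pair()
bank <- default_neuron_bank()
cmp <- population_thresholds(bank, pair$magstim$current, pair$ptms$current)

print(cmp)
cat(sprintf("overall: PWM thresholds %.1f%% lower on average; slope %.3f (r^2 %.4f)\n",
            mean(cmp$per_neuron$percent_reduction), cmp$slope, cmp$r_squared))

write.csv(cmp$per_neuron, "results/thresholds_per_neuron.csv", row.names = FALSE)
write.csv(cmp$layer_medians, "results/thresholds_layer_medians.csv",
          row.names = FALSE)
write_neuron_bank_toml(bank, "results/neuron_bank.toml")
cat("wrote results/thresholds_per_neuron.csv, results/thresholds_layer_medians.csv, results/neuron_bank.toml\n")
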