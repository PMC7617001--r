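#!/usr/bin/env Rscript
# Step 1 -- Device waveforms.
# Synthesizes the conventional monophasic coil pulse (underdamped RLC
# discharge + freewheel tail) at full output, scales it to the PWM
# device's 1600 V positive peak, and builds the five-level PWM
# approximation with its coil current. Writes the four waveforms as
# CSV under results/.

library(pwmtms)
dir.create("results", showWarnings = FALSE)

pair <- default_waveform_pair()
full <- synth_magstim_monophasic()

cat(sprintf("conventional pulse at 100%% MSO: peak voltage %.0f V, peak current %.2f kA\n",
            max(full$voltage$samples), max(full$current$samples) / 1000))
cat(sprintf("intensity calibration (1600 V PWM peak / 2800 V peak): %.4f\n",
            pair$ratio))
t_pk <- waveform_time(full$current)[which.max(full$current$samples)]
cat(sprintf("coil current peaks %.1f us after pulse onset\n", t_pk - 50))
cat(sprintf("PWM plan: %d switching periods of %.2f us, %d saturated\n",
            nrow(pair$ptms$plan), pair$ptms$plan$t_end[1] - pair$ptms$plan$t_start[1],
            pair$ptms$saturated_periods))

write_waveform_csv(pair$magstim$voltage, "results/magstim_voltage.csv")
write_waveform_csv(pair$magstim$current, "results/magstim_current.csv")
write_waveform_csv(pair$ptms$voltage, "results/ptms_voltage.csv")
write_waveform_csv(pair$ptms$current, "results/ptms_current.csv")
cat("wrote results/{magstim,ptms}_{voltage,current}.csv\n")
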