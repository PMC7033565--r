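#!/usr/bin/env Rscript
# Simulate the three data sets the analysis runs on: a multi-date GAI
# calibration trial, a whole-season overflight series with final biomass,
# and a SPAD senescence trial. Raw tables are large and reproducible, so
# they go to scratch/; downstream scripts regenerate or reread them from
# there. The effective configuration is written next to the outputs.

library(gaiseason)

cfg <- run_config()
dir.create("scratch/data", showWarnings = FALSE, recursive = TRUE)

fm <- forward_model_config(seed = cfg$seed)
cal <- generate_calibration_set(fm)
write_table_csv(cal, "scratch/data/calibration_reflectance.csv")
message(sprintf("calibration set: %d records, %d plots x %d dates, GAI %.2f-%.2f",
                nrow(cal), fm$n_plots, fm$n_dates, min(cal$gai_true),
                max(cal$gai_true)))

seas <- generate_season(fm, biomass_noise_sd = 0.05)
write_table_csv(seas$reflectance, "scratch/data/season_reflectance.csv")
write_table_csv(seas$biomass, "scratch/data/final_biomass.csv")
message(sprintf("season series: %d flights, biomass %.0f-%.0f g m-2",
                length(unique(seas$reflectance$date)),
                min(seas$biomass$biomass), max(seas$biomass$biomass)))

sc <- senescence_sim_config(seed = cfg$seed)
spad <- generate_spad_trial(sc)
write_table_csv(spad, "scratch/data/spad_trial.csv")
message(sprintf("SPAD trial: %d plots x %d layers x %d dates", sc$n_plots,
                sc$n_layers, length(sc$thermal_time_grid)))

write_run_config(cfg, "results/effective_config.json")
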