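#!/usr/bin/env Rscript
# Generate the two study datasets the rest of the workflow analyzes: a
# hybridization-array signal table (Langmuir saturation, additive
# background, log-normal noise) and an RNA-Seq signal table (Poisson
# counts, RPKM floor). Both carry the canonical anomaly set: the
# ERCC-00113 subpool preparation error (labeled E, truly C), one dropout,
# and one +2 log2 mixing-error offset inside the linear region.

library(spikeqc)
library(jsonlite)

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

design <- load_design()
anomalies <- anomaly_spec(
  misassigned = c("ERCC-00113" = "C"),
  dropouts = "ERCC-00051",                  # mid-ladder dropout
  offset_controls = c("ERCC-00086" = 2)     # mixing error, +2 log2
)

acfg <- array_sim_config(seed = 20160624)
array_tab <- simulate_microarray(design, acfg, anomalies)
write_signals(array_tab, "results/data/array_signals.tsv")

rcfg <- rnaseq_sim_config(seed = 20160624)
rnaseq_tab <- simulate_rnaseq(design, rcfg, anomalies)
write_signals(rnaseq_tab, "results/data/rnaseq_signals.tsv")

truth <- list(
  array = list(k_d = acfg$k_d, i_max = acfg$i_max, bg = acfg$bg,
               noise_sd = acfg$noise_sd, seed = acfg$seed),
  rnaseq = list(depth = rcfg$depth, floor = rcfg$floor, seed = rcfg$seed),
  anomalies = list(misassigned = as.list(anomalies$misassigned),
                   dropouts = anomalies$dropouts,
                   offset_controls = as.list(anomalies$offset_controls))
)
write_json(truth, "results/data/simulation_truth.json",
           auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("array table:  %d rows (%d controls)\n", nrow(array_tab),
            length(unique(array_tab$control_id))))
cat(sprintf("rnaseq table: %d rows (%d controls)\n", nrow(rnaseq_tab),
            length(unique(rnaseq_tab$control_id))))
cat("injected anomalies: ERCC-00113 mislabeled (truth C),",
    "ERCC-00051 dropout, ERCC-00086 +2 log2 offset\n")
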