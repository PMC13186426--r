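#!/usr/bin/env Rscript
# Stage 1 -- simulate the tract-level inputs.
#
# Generates an ACS-like raw indicator table at the study's dimensions
# (1,478 tracts, 14 indicators) from a known five-profile truth, so every
# later stage can be checked against the generating parameters. Writes the
# raw table, the truth, and the true allocations under results/synthetic/.

library(nsdohmix)

out_dir <- "results/synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

truth <- study_truth(seed = 20150)
sim <- simulate_acs_like_raw(1478, 14, truth)

write.csv(sim$raw, file.path(out_dir, "raw_tracts.csv"), row.names = FALSE)
write.csv(data.frame(tract_id = sim$raw$tract_id, z_true = sim$z),
          file.path(out_dir, "true_allocations.csv"), row.names = FALSE)
jsonlite::write_json(
  list(K_true = truth$K_true, pi_true = truth$pi_true,
       theta_true = truth$theta_true, seed = truth$seed),
  file.path(out_dir, "truth.json"), digits = NA, pretty = TRUE)

cat(sprintf("Simulated %d tracts x %d indicators from %d profiles\n",
            nrow(sim$raw), ncol(sim$raw) - 1, truth$K_true))
cat(sprintf("True profile weights: %s\n",
            paste(sprintf("%.2f", truth$pi_true), collapse = ", ")))
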