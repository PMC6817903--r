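#!/usr/bin/env Rscript
# Inverse optimization: samples candidate proportions in the published box
# (A 0.5-4, B 0.5-3, C 5-10, D 1.5-6.5, E 0.5-3.5, F 0.5-3.5), screens them
# through the fitted surrogate against the response criteria
# (absorbance < 0.539, swelling < 19.198 %), and forms the median consensus
# with its ten-point conversion and confirmation.

suppressPackageStartupMessages(library(saiopt))
dir.create("results", showWarnings = FALSE)
seed <- 2024

model <- if (file.exists("results/surrogate.json")) {
  load_surrogate("results/surrogate.json")
} else {
  stop("run analysis/03_surrogate.R first (results/surrogate.json missing)")
}

cs <- screen_candidates(model, component_ranges(), acceptance_criteria(),
                        target_size = 50, seed = seed + 2)
print(cs)

cons <- consensus_proportion(cs, "median")
conf <- confirm_proportion(model, cons, acceptance_criteria(),
                           ranges = component_ranges())
print(conf)

orig <- mean_proportion(relative_areas(sai_peak_table(), digits = 2),
                        paste0("S", 1:5), LETTERS[1:6])
cat("\nOriginal commercial ten-point proportion for comparison:\n")
print(round_proportion(orig))

utils::write.csv(data.frame(cs$proportions, cs$responses,
                            check.names = FALSE),
                 "results/accepted_candidates.csv", row.names = FALSE)
utils::write.csv(data.frame(component = names(cons),
                            consensus = cons,
                            ten_point = round_proportion(conf$ten_point),
                            original = round_proportion(orig)),
                 "results/consensus_proportion.csv", row.names = FALSE)
cat("\nwrote results/accepted_candidates.csv, results/consensus_proportion.csv\n")
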