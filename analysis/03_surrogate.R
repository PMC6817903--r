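#!/usr/bin/env Rscript
# Fits the four-layer backpropagation surrogate (10-20-2-2, tanh hidden
# layers) on nine samples' dosages and responses, holding out S5 for
# validation, and reports the training trajectory and holdout errors.

suppressPackageStartupMessages(library(saiopt))
dir.create("results", showWarnings = FALSE)
seed <- 2024

dm <- peak_doses(sai_peak_table(), sai_doses())
resp <- simulate_bioassay(dm, ground_truth(), seed = seed)
targets <- cbind(absorbance = resp$absorbance,
                 swelling = resp$swelling_ratio)
rownames(targets) <- resp$sample

spec <- network_spec(input_width = ncol(dm), max_epochs = 8000,
                     error_goal = 1e-6, momentum = 0.9, seed = seed + 1)
val <- holdout_validate(dm, targets, "S5", spec)

print(val)
print(val$model)
cat("\nNote: with nine training rows the near-zero training error is\n")
cat("interpolation, not generalization; the holdout row probes plausibility\n")
cat("only. Recovery against known ground truth is assessed in the tests.\n")

save_surrogate(val$model, "results/surrogate.json")
utils::write.csv(data.frame(epoch = seq_along(val$model$history),
                            mse = val$model$history),
                 "results/training_history.csv", row.names = FALSE)
cat("\nwrote results/surrogate.json, results/training_history.csv\n")
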