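#!/usr/bin/env Rscript
# Collapse the six per-interval optima into a practical three-stage
# protocol: exhaustive search over weekly boundaries (t1, t2), scoring
# each candidate by the average overall desirability when every interval
# is run at its stage's mean optimal concentrations.

suppressPackageStartupMessages(library(cytokinedoe))
dir.create("results", showWarnings = FALSE)

factors <- default_factors()
model_files <- list.files("results/models", full.names = TRUE)
models <- lapply(model_files, read_rsm_model)
optima <- readRDS("results/optima.rds")

best <- select_best_partition(optima, models)
write_protocol(best, "results/protocol.json")
utils::write.csv(best$all_partitions, "results/partition_scores.csv",
                 row.names = FALSE)

cat(sprintf("Best stage boundaries: t1 = %d, t2 = %d days\n",
            best$t1, best$t2))
cat(sprintf("Average overall desirability: %.4f\n", best$average_D))
unconstrained <- mean(vapply(optima, function(o) o$best$D, 0))
cat(sprintf("Ratio to unconstrained per-interval optima: %.4f\n",
            best$average_D / unconstrained))
cat("Stage concentrations (ng/ml):\n")
print(round(best$stage_concentrations, 1))
cat("All partition scores:\n")
print(best$all_partitions, row.names = FALSE)
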