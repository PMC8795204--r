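#!/usr/bin/env Rscript
# Desirability optimization: for each 7-day interval, maximize the overall
# desirability of the populations present (geometric mean of per-population
# desirabilities) by basin-hopping over the coded concentration box.

suppressPackageStartupMessages(library(cytokinedoe))
dir.create("results", showWarnings = FALSE)
seed <- 20240117

factors <- default_factors()
model_files <- list.files("results/models", full.names = TRUE)
models <- lapply(model_files, read_rsm_model)
names(models) <- sub("\\.json$", "", basename(model_files))

schedule <- default_schedule()
write_schedule(schedule, "results/schedule.yaml")

optima <- optimize_all_intervals(models, schedule, lower = -2, upper = 2,
                                 n_iter = 50, seed = seed)

rows <- do.call(rbind, lapply(optima, function(o)
  data.frame(day_start = o$interval[1], D = o$best$D,
             as.list(round(o$best$natural, 2)))))
utils::write.csv(rows, "results/interval_optima.csv", row.names = FALSE)
utils::write.csv(optima_summary(optima), "results/optima_top5_summary.csv",
                 row.names = FALSE)
saveRDS(optima, "results/optima.rds")  # consumed by 05_stage.R

cat("Per-interval optima (ng/ml):\n")
print(rows, row.names = FALSE)
spread <- vapply(optima, function(o) max(o$top_k$D) - min(o$top_k$D), 0)
cat(sprintf("Top-5 desirability spread per interval: max %.2e\n",
            max(spread)))
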