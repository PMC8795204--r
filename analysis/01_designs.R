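#!/usr/bin/env Rscript
# Build the two experimental designs of the campaign: a 15-factor
# definitive screening design (the cytokine screen) and the 6-cytokine
# orthogonal central composite design used for the response-surface
# experiments. Writes both as CSV under results/.

suppressPackageStartupMessages(library(cytokinedoe))
dir.create("results", showWarnings = FALSE)

# 15 candidate molecules, three levels each; concentration grids are
# placeholders on a common 10-30 ng/ml band
screen_factors <- lapply(paste0("C", 1:15), doe_factor, low = 10,
                         high = 30)
dsd <- generate_dsd(screen_factors)
write_design(dsd, "results/design_dsd_screen.csv")
cat(sprintf("DSD screen: %d runs x %d factors (order-16 conference matrix)\n",
            nrow(dsd$coded), ncol(dsd$coded)))

factors <- default_factors()
ccd <- generate_ccd(factors, n_center = 8, alpha_mode = "orthogonal")
write_design(ccd, "results/design_ccd.csv")
cat(sprintf("CCD: %d runs, alpha = %.4f, 5 levels per cytokine\n",
            nrow(ccd$coded), ccd$alpha))
cat("Natural-unit ranges (ng/ml):\n")
for (f in factors)
  cat(sprintf("  %-7s %g / %g / %g\n", f$name, f$low, f$center, f$high))
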