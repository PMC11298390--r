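#!/usr/bin/env Rscript
# Regenerates the response-surface views from the tuned models saved by
# 03_tune_models.R: 3-D surface, contour map, and per-level trend slices.

suppressPackageStartupMessages(library(scfsol))

for (fam in c("PPR", "KRR", "TDR")) {
  path <- sprintf("results/model_%s.json", fam)
  if (!file.exists(path)) {
    stop("missing ", path, "; run analysis/03_tune_models.R first")
  }
  bundle <- load_model_json(path)
  pb <- surface_plots(bundle, label = fam, out_dir = "results/figures")
  top <- pb$data$grid[which.max(pb$data$grid$predicted), ]
  cat(sprintf("%s: predicted maximum %.3g at T = %.2f K, P = %.0f bar\n",
              fam, top$predicted, top$temperature_K, top$pressure_bar))
}
cat("Surface, contour and trend-slice figures written under results/figures/\n")
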