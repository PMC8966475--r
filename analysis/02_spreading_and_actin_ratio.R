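#!/usr/bin/env Rscript
# Spreading kinetics from the IRM movies and the center/annulus actin MFI
# ratio on painted fixed-cell frames. Writes results/spreading.csv and
# results/actin_ratio.csv.

suppressPackageStartupMessages(library(synapseflow))
scenes <- "results/scenes"
stopifnot(dir.exists(scenes))   # run 01_simulate_scenes.R first

rows <- lapply(c("2SI", "3SI"), function(cond) {
  st <- read_stack(file.path(scenes, paste0("irm_", cond, ".tif")),
                   pixel_size = 0.2, frame_interval = 5)
  fit <- fit_spreading(measure_spreading(st))
  data.frame(condition = cond, A0_um2 = fit$A0,
             alpha_per_s = fit$alpha_spread, r_squared = fit$goodness)
})
spread <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(spread, "results/spreading.csv", row.names = FALSE)
cat("Spreading fits:\n"); print(spread, digits = 4)
cat("-> spreading rates are comparable across conditions;",
    "the plateau areas differ, matching the generating truth.\n\n")

# actin depletion: per-cell MFI ratios for two synthetic populations, one
# center-depleted (ratio < 1) and one flat, compared by Wilcoxon rank-sum
set.seed(20260917)
make_cell_ratio <- function(depletion) {
  n <- 140
  ii <- seq_len(n) - 1; cen <- (n - 1) / 2
  rd <- sqrt(outer(ii - cen, rep(1, n))^2 + outer(rep(1, n), ii - cen)^2)
  r_cell <- runif(1, 45, 60)
  cm <- cell_mask(rd <= r_cell, 0.2)
  frame <- matrix(0, n, n)
  frame[cm$mask] <- 1 - depletion * pmax(1 - rd[cm$mask] / r_cell, 0) +
    rnorm(sum(cm$mask), 0, 0.05)
  intensity_ratio(pmax(frame, 0), partition_center_annulus(cm, 0.3))$ratio
}
ratios_dep <- replicate(25, make_cell_ratio(0.6))
ratios_flat <- replicate(25, make_cell_ratio(0))
w <- wilcoxon_rank_sum(ratios_dep, ratios_flat)
tab <- data.frame(population = c("depleted", "uniform"),
                  median_ratio = c(median(ratios_dep), median(ratios_flat)))
write.csv(tab, "results/actin_ratio.csv", row.names = FALSE)
print(tab, digits = 3)
cat(sprintf("Wilcoxon rank-sum on MFI ratios: W = %g, p = %.2e\n",
            w$statistic, w$p_value))
cat("-> central actin depletion shows up as MFI ratio < 1 and the rank-sum",
    "test separates the populations.\n")
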