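#!/usr/bin/env Rscript
# Stage 2: per-site Weir & Cockerham Fst and the windowed Z(Fst) scan.
#
# Reads the stage-1 bundle, applies the >= 50 % per-population call-rate
# filter, computes per-site theta-hat, averages it in non-overlapping
# 500 kb windows, Z-transforms the window means genome-wide and flags
# windows at least 5 SD above the mean as putative sweeps.

suppressPackageStartupMessages(library(canidscan))

pm <- read_population_map("results/bundle/popmap.tsv")
sites <- read_sites("results/bundle/variants.vcf", pm)
sites <- filter_by_call_rate(sites, 0.5)
fst <- fst_sites(sites)
windows <- window_scan(fst)

dir.create("results/scan", showWarnings = FALSE, recursive = TRUE)
write.table(fst, "results/scan/fst_sites.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_windows_bed(windows, "results/scan/windows.tsv")

cat(sprintf("%d sites after call-rate filter; mean per-site Fst = %.3f\n",
            nrow(fst), mean(fst$fst, na.rm = TRUE)))
cat(sprintf("%d/%d windows defined; genome-wide mean window Fst = %.3f\n",
            sum(!is.na(windows$mean_fst)), nrow(windows),
            mean(windows$mean_fst, na.rm = TRUE)))
out <- windows[windows$outlier, ]
cat(sprintf("%d outlier window(s) at Z >= 5:\n", nrow(out)))
print(out[, c("chrom", "start", "end", "n_sites", "mean_fst", "z_fst")],
      row.names = FALSE)
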