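#!/usr/bin/env Rscript
# Stage 5: Fst-bin functional-category spectra and the flanking-Fst
# contrast across consequence categories (one-way ANOVA + Tukey HSD).

suppressPackageStartupMessages(library(canidscan))

pm <- read_population_map("results/bundle/popmap.tsv")
sites <- filter_by_call_rate(read_sites("results/bundle/variants.vcf", pm))
fst <- fst_sites(sites)
models <- load_gene_models("results/bundle/genes.gff3",
                           "results/bundle/genome.fa")
de <- join_effects(select_divergent_sites(fst, sites),
                   classify_variants(sites, models))

sp <- bin_spectrum(de)
dir.create("results/categories", showWarnings = FALSE, recursive = TRUE)
spt <- as.data.frame.table(sp$counts, responseName = "count")
names(spt)[1:2] <- c("bin", "category")
spt$percent <- as.data.frame.table(sp$percent)$Freq
write.table(spt, "results/categories/bin_spectrum.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("sites per Fst bin:", paste(sp$totals, collapse = ", "), "\n")

ct <- tryCatch(category_contrast(fst, de), error = function(e) NULL)
if (is.null(ct)) {
  cat("too few category groups for the flanking contrast on this bundle\n")
} else {
  write.table(ct$tukey, "results/categories/tukey.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("ANOVA: F[%d, %d] = %.2f, p = %.3g\n", ct$anova$df[1],
              ct$anova$df[2], ct$anova$F, ct$anova$p))
  print(ct$tukey, row.names = FALSE, digits = 3)
}
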