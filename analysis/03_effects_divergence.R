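#!/usr/bin/env Rscript
# Stage 3: variant-effect classification and divergent-site tables.
#
# Classifies every retained SNP against the toy gene models, selects
# fixed (Fst = 1) and highly differentiated (Fst >= 0.75) sites, joins
# effects, labels each divergent site with its scan-window context, and
# maps genes to their putatively functional divergent sites.

suppressPackageStartupMessages(library(canidscan))

pm <- read_population_map("results/bundle/popmap.tsv")
sites <- filter_by_call_rate(read_sites("results/bundle/variants.vcf", pm))
fst <- fst_sites(sites)
windows <- window_scan(fst)
models <- load_gene_models("results/bundle/genes.gff3",
                           "results/bundle/genome.fa")
effects <- classify_variants(sites, models)
divergent <- select_divergent_sites(fst, sites)
de <- annotate_window_context(join_effects(divergent, effects), windows)
genes <- genes_with_functional_divergence(de)

dir.create("results/divergence", showWarnings = FALSE, recursive = TRUE)
write.table(de, "results/divergence/divergent_sites.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
fixed_func <- de[de$category == "fixed" &
                   is_putatively_functional(de$consequence), ]
write.table(fixed_func[, c("gene_id", "chrom", "pos", "ref", "alt",
                           "consequence", "aa_ref", "aa_alt")],
            "results/divergence/fixed_functional.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("divergent sites (Fst >= 0.75): %d, of which fixed: %d\n",
            length(unique(paste(de$chrom, de$pos))),
            length(unique(paste(de$chrom, de$pos)[de$category == "fixed"]))))
cat(sprintf("genes with putatively functional divergent sites: %d\n",
            length(genes)))
cat(sprintf("fixed functional sites inside/near outlier windows: %d/%d\n",
            sum(fixed_func$near_outlier_window), nrow(fixed_func)))
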