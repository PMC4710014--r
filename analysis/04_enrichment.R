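#!/usr/bin/env Rscript
# Stage 4: pathway over-representation of the divergent-functional genes
# against the background gene list, binomial tail with Bonferroni
# correction (hypergeometric mode available via run_scan's test_mode).

suppressPackageStartupMessages(library(canidscan))

pm <- read_population_map("results/bundle/popmap.tsv")
sites <- filter_by_call_rate(read_sites("results/bundle/variants.vcf", pm))
fst <- fst_sites(sites)
models <- load_gene_models("results/bundle/genes.gff3",
                           "results/bundle/genome.fa")
de <- join_effects(select_divergent_sites(fst, sites),
                   classify_variants(sites, models))
genes <- names(genes_with_functional_divergence(de))

pathways <- read_pathway_table("results/bundle/pathways.tsv")
background <- readLines("results/bundle/background_genes.txt")
en <- pathway_enrichment(pathways, genes, background)

dir.create("results/enrichment", showWarnings = FALSE, recursive = TRUE)
write.table(en, "results/enrichment/pathways.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("foreground: %d genes of %d background\n", length(genes),
            length(background)))
cat("top pathways (ref count, sample count, expected, p, Bonferroni p):\n")
print(head(en, 5), row.names = FALSE, digits = 3)
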