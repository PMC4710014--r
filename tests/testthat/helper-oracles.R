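# Independent oracle for the Weir & Cockerham (1984) estimator: a nested
# analysis-of-variance on expanded allele indicators (sums of squares
# between populations / between individuals / within individuals, turned
# into variance components via the mean-square relations). Shares no code
# with the package's direct variance-component implementation.
wc_oracle <- function(g1, g2) {
  r <- 2; n1 <- length(g1); n2 <- length(g2); N <- n1 + n2
  nbar <- N / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  x1 <- g1 / 2; x2 <- g2 / 2            # per-individual allele frequency
  p1 <- mean(x1); p2 <- mean(x2)
  pbar <- (n1 * p1 + n2 * p2) / N
  SSW <- sum(g1 == 1) * 0.5 + sum(g2 == 1) * 0.5  # het: alleles 0,1 -> SS 0.5
  SSI <- 2 * (sum((x1 - p1)^2) + sum((x2 - p2)^2))
  SSP <- 2 * (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2)
  MSW <- SSW / N; MSI <- SSI / (N - r); MSP <- SSP / (r - 1)
  a <- (MSP - MSI) / (2 * nc); b <- (MSI - MSW) / 2; cc <- MSW
  list(a = a, b = b, c = cc, fst = a / (a + b + cc))
}

dose_to_counts <- function(g) c(sum(g == 0), sum(g == 1), sum(g == 2))

# Build a site_table directly from per-population genotype-count rows.
make_sites <- function(df, populations = c("dog", "wolf"),
                       pop_sizes = NULL) {
  if (is.null(pop_sizes))
    pop_sizes <- c(df$hom_ref_1[1] + df$het_1[1] + df$hom_alt_1[1] +
                     df$miss_1[1],
                   df$hom_ref_2[1] + df$het_2[1] + df$hom_alt_2[1] +
                     df$miss_2[1])
  canidscan:::new_site_table(df, populations, pop_sizes)
}

site_row <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                     c1 = c(0, 0, 0), m1 = 0L, c2 = c(0, 0, 0), m2 = 0L) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             hom_ref_1 = c1[1], het_1 = c1[2], hom_alt_1 = c1[3],
             miss_1 = m1,
             hom_ref_2 = c2[1], het_2 = c2[2], hom_alt_2 = c2[3],
             miss_2 = m2, stringsAsFactors = FALSE)
}

# ---- hand-built two-gene annotation fixture ---------------------------
# Chromosome "t1", 3400 bp. Gene GP (+ strand) and its mirror GM (-):
#   GP: exon1 1001-1102 (UTR5 1001-1030, CDS 1031-1102),
#       intron 1103-1202,
#       exon2 1203-1304 (CDS 1203-1274, UTR3 1275-1304).
#   CDS (144 bp, 48 codons) = ATG + 46 x GGA + TAA.
#   GM: same intervals shifted +1000, minus strand; its CDS reads the same
#       ATG + GGA... + TAA in transcript orientation, so genomic bases are
#       the reverse complement.
toy_cds_seq <- function() paste(c("ATG", rep("GGA", 46), "TAA"),
                                collapse = "")

toy_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(unname(comp[strsplit(x, "")[[1]]])), collapse = "")
}

toy_annotation <- function(dir, explicit_utrs = TRUE) {
  seq <- paste(rep("A", 3400), collapse = "")
  cds <- toy_cds_seq()
  substr(seq, 1031, 1102) <- substr(cds, 1, 72)
  substr(seq, 1203, 1274) <- substr(cds, 73, 144)
  rc <- toy_revcomp(cds)
  substr(seq, 2031, 2102) <- substr(rc, 1, 72)
  substr(seq, 2203, 2274) <- substr(rc, 73, 144)
  fasta <- file.path(dir, "toy.fa")
  writeLines(c(">t1", seq), fasta)

  ln <- function(type, s, e, strand, attrs, phase = ".")
    sprintf("t1\ttest\t%s\t%d\t%d\t.\t%s\t%s\t%s", type, s, e, strand,
            phase, attrs)
  gp <- c(ln("gene", 1001, 1304, "+", "ID=GP"),
          ln("mRNA", 1001, 1304, "+", "ID=GP.t1;Parent=GP"),
          ln("exon", 1001, 1102, "+", "ID=GP.e1;Parent=GP.t1"),
          ln("exon", 1203, 1304, "+", "ID=GP.e2;Parent=GP.t1"),
          ln("CDS", 1031, 1102, "+", "ID=GP.c1;Parent=GP.t1", "0"),
          ln("CDS", 1203, 1274, "+", "ID=GP.c2;Parent=GP.t1", "0"))
  gm <- c(ln("gene", 2001, 2304, "-", "ID=GM"),
          ln("mRNA", 2001, 2304, "-", "ID=GM.t1;Parent=GM"),
          ln("exon", 2001, 2102, "-", "ID=GM.e1;Parent=GM.t1"),
          ln("exon", 2203, 2304, "-", "ID=GM.e2;Parent=GM.t1"),
          ln("CDS", 2031, 2102, "-", "ID=GM.c1;Parent=GM.t1", "0"),
          ln("CDS", 2203, 2274, "-", "ID=GM.c2;Parent=GM.t1", "0"))
  if (explicit_utrs) {
    gp <- c(gp, ln("five_prime_UTR", 1001, 1030, "+",
                   "ID=GP.u5;Parent=GP.t1"),
            ln("three_prime_UTR", 1275, 1304, "+",
               "ID=GP.u3;Parent=GP.t1"))
    gm <- c(gm, ln("five_prime_UTR", 2275, 2304, "-",
                   "ID=GM.u5;Parent=GM.t1"),
            ln("three_prime_UTR", 2001, 2030, "-",
               "ID=GM.u3;Parent=GM.t1"))
  }
  gff3 <- file.path(dir, if (explicit_utrs) "toy.gff3" else "toy_noutr.gff3")
  writeLines(c("##gff-version 3", "##sequence-region t1 1 3400", gp, gm),
             gff3)
  list(gff3 = gff3, fasta = fasta)
}

snp <- function(pos, ref, alt)
  data.frame(chrom = "t1", pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)

# small synthetic config for fast tests
small_config <- function(...) {
  synthetic_config(chrom_lengths = c(chrA = 2000000L, chrB = 2000000L),
                   background = "iid", iid_sites_per_window = 60L,
                   sweep_windows = NULL,
                   pathway_background_size = 500L, ...)
}
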