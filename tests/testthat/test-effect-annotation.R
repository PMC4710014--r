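test_that("gene models load with explicit UTRs or derive them by subtraction", {
  dir <- tempfile(); dir.create(dir)
  tx <- toy_annotation(dir, explicit_utrs = TRUE)
  tx2 <- toy_annotation(dir, explicit_utrs = FALSE)
  with_utr <- load_gene_models(tx$gff3, tx$fasta)
  without <- load_gene_models(tx2$gff3, tx2$fasta)
  expect_equal(length(with_utr), 2L)
  gp1 <- with_utr[[1]]; gp2 <- without[[1]]
  expect_equal(gp1$utr5, gp2$utr5)
  expect_equal(gp1$utr3, gp2$utr3)
  expect_equal(unname(gp1$utr5), cbind(start = 1001, end = 1030),
               ignore_attr = TRUE)
  # minus-strand transcript: 5'-UTR at higher genomic coordinates than CDS
  gm <- without[[2]]
  expect_equal(gm$strand, "-")
  expect_gt(min(gm$utr5[, 1]), max(gm$cds[, 2]))
})

test_that("a CDS length not divisible by 3 skips the transcript with warning", {
  dir <- tempfile(); dir.create(dir)
  tx <- toy_annotation(dir)
  bad <- readLines(tx$gff3)
  # shorten GP's second CDS by one base: 144 -> 143
  bad <- sub("CDS\t1203\t1274", "CDS\t1203\t1273", bad)
  badfile <- file.path(dir, "bad.gff3")
  writeLines(bad, badfile)
  expect_warning(models <- load_gene_models(badfile, tx$fasta),
                 "not divisible by 3")
  expect_equal(length(models), 1L)   # only GM survives
})

test_that("coding consequences follow the standard genetic code", {
  dir <- tempfile(); dir.create(dir)
  tx <- toy_annotation(dir)
  models <- load_gene_models(tx$gff3, tx$fasta)
  # ATG -> GTG at the first codon position: missense M/V
  e <- classify_variants(snp(1031, "A", "G"), models)
  expect_equal(e$consequence, "missense")
  expect_equal(e$aa_ref, "M"); expect_equal(e$aa_alt, "V")
  # GGA -> GGG at a third position: synonymous G/G
  e <- classify_variants(snp(1036, "A", "G"), models)
  expect_equal(e$consequence, "synonymous")
  # GGA -> TGA: stop gained
  e <- classify_variants(snp(1037, "G", "T"), models)
  expect_equal(e$consequence, "stop_gained")
  expect_equal(e$aa_alt, "*")
  # terminal TAA -> TCA: stop lost
  e <- classify_variants(snp(1273, "A", "C"), models)
  expect_equal(e$consequence, "stop_lost")
  expect_equal(e$aa_ref, "*")
})

test_that("UTR, splice-region and intergenic locations classify correctly", {
  dir <- tempfile(); dir.create(dir)
  tx <- toy_annotation(dir)
  models <- load_gene_models(tx$gff3, tx$fasta)
  expect_equal(classify_variants(snp(1010, "A", "C"), models)$consequence,
               "five_prime_utr")
  expect_equal(classify_variants(snp(1280, "A", "C"), models)$consequence,
               "three_prime_utr")
  # 5 bp into the intron from the donor junction
  expect_equal(classify_variants(snp(1107, "A", "C"), models)$consequence,
               "splice_region")
  # 1 bp into the intron (canonical donor) also reported splice_region
  expect_equal(classify_variants(snp(1103, "A", "C"), models)$consequence,
               "splice_region")
  # deep intron -> non_functional
  expect_equal(classify_variants(snp(1150, "A", "C"), models)$consequence,
               "non_functional")
  # intergenic -> non_functional with no gene id
  e <- classify_variants(snp(50, "A", "C"), models)
  expect_equal(e$consequence, "non_functional")
  expect_true(is.na(e$gene_id))
  # exonic base within 3 bp of the junction: coding row + splice row
  e <- classify_variants(snp(1102, "A", "C"), models)
  expect_setequal(e$consequence, c("synonymous", "splice_region"))
})

test_that("minus-strand classification equals the reverse-complement case", {
  dir <- tempfile(); dir.create(dir)
  tx <- toy_annotation(dir)
  models <- load_gene_models(tx$gff3, tx$fasta)
  # GM transcript position 1 is genomic 2274 (base T = complement of A).
  # Genomic T -> C is transcript A -> G: same ATG -> GTG missense as GP.
  plus <- classify_variants(snp(1031, "A", "G"), models)
  minus <- classify_variants(snp(2274, "T", "C"), models)
  expect_equal(minus$consequence, plus$consequence)
  expect_equal(minus$aa_ref, plus$aa_ref)
  expect_equal(minus$aa_alt, plus$aa_alt)
  # genomic C -> T inside GM's CDS is transcript G -> A
  e <- classify_variants(snp(2273, "A", "G"), models)   # transcript pos 2
  expect_equal(e$gene_id, "GM")
  expect_equal(e$aa_ref, "M")
})

test_that("every CDS SNP gets exactly one coding consequence per transcript", {
  dir <- tempfile(); dir.create(dir)
  tx <- toy_annotation(dir)
  models <- load_gene_models(tx$gff3, tx$fasta)
  cds_pos <- c(1031:1102, 1203:1274)
  set.seed(2)
  take <- sample(cds_pos, 40)
  for (p in take) {
    ref <- substr(readLines(tx$fasta)[2], p, p)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    e <- classify_variants(snp(p, ref, alt), models)
    coding <- e$consequence %in% c("missense", "synonymous", "stop_gained",
                                   "stop_lost")
    expect_equal(sum(coding), 1L)
  }
})

test_that("putative functionality covers protein and proximal regulatory sites", {
  expect_true(all(is_putatively_functional(
    c("missense", "stop_gained", "stop_lost", "frameshift",
      "five_prime_utr", "three_prime_utr", "splice_region"))))
  expect_false(any(is_putatively_functional(c("synonymous",
                                              "non_functional"))))
})

test_that("the classifier recovers every planted consequence label", {
  dir <- tempfile()
  cfg <- small_config(seed = 5L)
  bundle <- generate_dataset(cfg, dir)
  models <- load_gene_models(bundle$gff3, bundle$fasta)
  planted <- bundle$truth[bundle$truth$type == "fixed_variant", ]
  eff <- classify_variants(
    data.frame(chrom = planted$chrom, pos = planted$start,
               ref = planted$ref, alt = planted$alt,
               stringsAsFactors = FALSE), models)
  for (i in seq_len(nrow(planted))) {
    want <- if (planted$consequence[i] == "intronic") "non_functional"
            else planted$consequence[i]
    got <- eff$consequence[eff$chrom == planted$chrom[i] &
                             eff$pos == planted$start[i]]
    expect_true(want %in% got,
                label = sprintf("%s recovered at %s:%d (got: %s)",
                                want, planted$chrom[i], planted$start[i],
                                paste(got, collapse = ",")))
  }
})

test_that("most_severe_effects keeps one row per site by severity", {
  eff <- data.frame(chrom = "c", pos = c(1, 1, 2), ref = "A", alt = "T",
                    gene_id = c("g1", "g2", "g1"), tx_id = "t",
                    consequence = c("synonymous", "missense",
                                    "three_prime_utr"),
                    aa_ref = NA, aa_alt = NA, stringsAsFactors = FALSE)
  top <- most_severe_effects(eff)
  expect_equal(nrow(top), 2L)
  expect_equal(top$consequence[top$pos == 1], "missense")
})
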