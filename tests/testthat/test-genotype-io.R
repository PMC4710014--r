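write_test_vcf <- function(lines, samples) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"),
               lines), path)
  path
}

test_that("VCF reading counts genotypes per population and skips non-SNPs", {
  samples <- c("d1", "d2", "w1", "w2")
  pm <- population_map(samples, c("dog", "dog", "wolf", "wolf"))
  rec <- function(pos, ref, alt, gts)
    paste(c("chr1", pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  vcf <- write_test_vcf(c(
    rec(100, "A", "T", c("0/0", "0|1", "1/1", "./.")),
    rec(200, "A", "C,T", c("0/0", "0/0", "0/0", "0/0")),   # multi-allelic
    rec(300, "AT", "A", c("0/0", "0/0", "0/0", "0/0")),    # indel
    rec(400, "G", "C", c("1/1", "1/1", "0/0", "0/0"))
  ), samples)
  sites <- suppressMessages(read_sites(vcf, pm))
  expect_equal(nrow(sites), 2L)
  expect_equal(attr(sites, "n_skipped"), 2L)
  # missing wolf counted as missing, not in a genotype class
  expect_equal(sites$miss_2[1], 1L)
  expect_equal(sites$hom_alt_2[1], 1L)
  expect_equal(sites$hom_ref_1[1], 1L)
  expect_equal(sites$het_1[1], 1L)
  expect_equal(sites$call_2, c(0.5, 1))
})

test_that("a VCF sample absent from the population map is fatal", {
  samples <- c("d1", "mystery")
  pm <- population_map(c("d1", "w1"), c("dog", "wolf"))
  vcf <- write_test_vcf(
    paste(c("chr1", 100, ".", "A", "T", ".", "PASS", ".", "GT",
            "0/0", "0/1"), collapse = "\t"), samples)
  expect_error(read_sites(vcf, pm), "mystery")
})

test_that("population map requires exactly two non-empty labels", {
  expect_error(population_map(c("a", "b"), c("x", "y")), NA)
  expect_error(population_map(c("a", "b", "c"), c("x", "y", "z")),
               "exactly two")
  expect_error(population_map(c("a", "a"), c("x", "y")), "duplicate")
})

test_that("call-rate filter keeps sites called in >= threshold of BOTH pops", {
  rows <- rbind(
    site_row(pos = 1L, c1 = c(67, 0, 0), c2 = c(3, 0, 0), m2 = 4L),  # 3/7
    site_row(pos = 2L, c1 = c(67, 0, 0), c2 = c(7, 0, 0)),           # full
    site_row(pos = 3L, c1 = c(30, 2, 2), m1 = 33L,                   # 50/50
             c2 = c(2, 1, 1), m2 = 3L))
  # population sizes: 67 and 7; site 3 has exactly 50% called in pop2
  # (4/8 would be needed) -> use sizes 68 and 8 for an exact boundary
  rows2 <- rbind(
    site_row(pos = 1L, c1 = c(68, 0, 0), c2 = c(3, 0, 0), m2 = 5L),
    site_row(pos = 2L, c1 = c(68, 0, 0), c2 = c(8, 0, 0)),
    site_row(pos = 3L, c1 = c(34, 0, 0), m1 = 34L, c2 = c(4, 0, 0),
             m2 = 4L))
  sites <- make_sites(rows2, pop_sizes = c(68L, 8L))
  kept <- filter_by_call_rate(sites, 0.5)
  expect_equal(kept$pos, c(2L, 3L))   # 3/8 = 0.375 removed; 50% retained

  sites74 <- make_sites(rows, pop_sizes = c(67L, 7L))
  kept74 <- filter_by_call_rate(sites74, 0.5)
  expect_false(1L %in% kept74$pos)    # 3 of 7 wolves (0.4286) -> removed
})

test_that("call-rate filtering is idempotent and monotone in the threshold", {
  set.seed(11)
  n <- 50L
  m1 <- rbinom(n, 10L, 0.4); m2 <- rbinom(n, 6L, 0.4)
  rows <- do.call(rbind, lapply(seq_len(n), function(i)
    site_row(pos = i, c1 = c(10L - m1[i], 0, 0), m1 = m1[i],
             c2 = c(6L - m2[i], 0, 0), m2 = m2[i])))
  sites <- make_sites(rows, pop_sizes = c(10L, 6L))
  f5 <- filter_by_call_rate(sites, 0.5)
  expect_equal(nrow(filter_by_call_rate(f5, 0.5)), nrow(f5))
  for (th in c(0.2, 0.5, 0.8)) {
    lo <- filter_by_call_rate(sites, th)
    hi <- filter_by_call_rate(sites, min(th + 0.3, 1))
    expect_true(all(hi$pos %in% lo$pos))
  }
})

test_that("alt-allele frequency counts alleles over called genotypes", {
  s <- make_sites(site_row(c1 = c(0, 2, 2), c2 = c(4, 0, 0)),
                  pop_sizes = c(4L, 4L))
  expect_equal(allele_frequency(s, 1), 0.75)   # (2*2 + 2) / 8
  expect_equal(allele_frequency(s, 2), 0)
  s2 <- make_sites(site_row(c1 = c(0, 0, 4), c2 = c(0, 0, 0), m2 = 4L),
                   pop_sizes = c(4L, 4L))
  expect_equal(allele_frequency(s2, 1), 1)
  expect_true(is.na(allele_frequency(s2, 2)))  # zero called -> sentinel
  expect_error(allele_frequency(s2, "coyote"), "unknown population")
})

test_that("VCF round trip preserves genotype counts exactly", {
  set.seed(7)
  n <- 30L
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    c1 <- as.vector(rmultinom(1, 10L, c(0.5, 0.3, 0.15, 0.05)))
    c2 <- as.vector(rmultinom(1, 4L, c(0.6, 0.2, 0.1, 0.1)))
    site_row(pos = i * 10L, ref = "G", alt = "A",
             c1 = c1[1:3], m1 = c1[4], c2 = c2[1:3], m2 = c2[4])
  }))
  sites <- make_sites(rows, pop_sizes = c(10L, 4L))
  path <- tempfile(fileext = ".vcf")
  write_sites_vcf(sites, path)
  pm <- population_map(c(paste0("dog", 1:10), paste0("wolf", 1:4)),
                       rep(c("dog", "wolf"), c(10, 4)))
  back <- read_sites(path, pm)
  cols <- c("chrom", "pos", "ref", "alt", "hom_ref_1", "het_1",
            "hom_alt_1", "miss_1", "hom_ref_2", "het_2", "hom_alt_2",
            "miss_2")
  expect_equal(as.data.frame(back)[, cols], as.data.frame(sites)[, cols])
})
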