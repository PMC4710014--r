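#' Read a two-population sample map
#'
#' A population map assigns every sample to exactly one of two population
#' labels (e.g. "dog" and "wolf"). The file is a two-column tab-separated
#' table: sample_id, population. No header is expected.
#'
#' @param path Path to the two-column TSV.
#' @return A `population_map` object: a data.frame with columns `sample`
#'   and `population`, with both labels guaranteed non-empty.
#' @export
read_population_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("sample", "population"))
  population_map(tab$sample, tab$population)
}

#' Construct a population map from vectors
#'
#' @param samples Character vector of sample ids.
#' @param populations Character vector of population labels, parallel to
#'   `samples`. Exactly two distinct labels must be present.
#' @return A `population_map` data.frame.
#' @export
population_map <- function(samples, populations) {
  stopifnot(length(samples) == length(populations))
  if (anyDuplicated(samples))
    stop("duplicate sample ids in population map: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  labs <- unique(populations)
  if (length(labs) != 2L)
    stop("population map must contain exactly two population labels, got: ",
         paste(labs, collapse = ", "))
  if (any(table(populations) == 0L)) stop("both populations must be non-empty")
  out <- data.frame(sample = as.character(samples),
                    population = as.character(populations),
                    stringsAsFactors = FALSE)
  class(out) <- c("population_map", "data.frame")
  out
}

#' @export
print.population_map <- function(x, ...) {
  tab <- table(x$population)
  cat("population map:", nrow(x), "samples (",
      paste(sprintf("%s = %d", names(tab), as.integer(tab)), collapse = ", "),
      ")\n")
  invisible(x)
}

pop_labels <- function(popmap) unique(popmap$population)

# Internal constructor for the per-site genotype-count table shared by the
# VCF reader, the synthetic generator and the coalescent path. One row per
# biallelic SNP; counts are per population (suffix 1/2 in popmap label order).
new_site_table <- function(df, populations, pop_sizes, n_skipped = 0L) {
  needed <- c("chrom", "pos", "ref", "alt",
              "hom_ref_1", "het_1", "hom_alt_1", "miss_1",
              "hom_ref_2", "het_2", "hom_alt_2", "miss_2")
  stopifnot(all(needed %in% names(df)))
  df$call_1 <- (pop_sizes[1] - df$miss_1) / pop_sizes[1]
  df$call_2 <- (pop_sizes[2] - df$miss_2) / pop_sizes[2]
  attr(df, "populations") <- populations
  attr(df, "pop_sizes") <- pop_sizes
  attr(df, "n_skipped") <- n_skipped
  class(df) <- c("site_table", "data.frame")
  df
}

#' @export
print.site_table <- function(x, ...) {
  cat("site table:", nrow(x), "biallelic SNPs;",
      attr(x, "n_skipped"), "records skipped; populations:",
      paste(sprintf("%s (n=%d)", attr(x, "populations"),
                    attr(x, "pop_sizes")), collapse = ", "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

# Classify a matrix of GT strings into per-sample alt-allele dosage.
# Phase is ignored; haploid calls are counted as homozygous allele pairs
# (Fst only needs allele counts). NA / any '.' allele -> missing.
gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  d[clean %in% c("0/0", "0")] <- 0L
  d[clean %in% c("0/1", "1/0")] <- 1L
  d[clean %in% c("1/1", "1")] <- 2L
  d
}

#' Read biallelic SNPs from a VCF into per-population genotype counts
#'
#' Parses a multi-sample VCF (plain or bgzipped) and tallies, for each
#' biallelic SNP, the number of hom-ref, het, hom-alt and missing genotypes
#' in each of the two populations of `popmap`. Indels, multi-allelic records
#' and symbolic alleles are skipped and counted. Positions are VCF-native
#' 1-based. Phase is ignored; haploid genotypes count as allele pairs.
#'
#' @param vcf_path Path to the VCF file.
#' @param popmap A `population_map` covering every sample in the VCF.
#' @return A `site_table` data.frame: one row per retained SNP with
#'   per-population genotype counts and called fractions (`call_1`,
#'   `call_2`); the number of skipped records in `attr(, "n_skipped")`.
#' @export
read_sites <- function(vcf_path, popmap) {
  if (!file.exists(vcf_path)) stop("cannot read VCF: ", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- v@fix   # always a matrix, even for a single record
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", vcf_path)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, names(gt)))
  missing_samples <- setdiff(colnames(gt), popmap$sample)
  if (length(missing_samples) > 0)
    stop("sample(s) in VCF absent from population map: ",
         paste(missing_samples, collapse = ", "))

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  is_snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snp)
  if (n_skipped > 0)
    message("read_sites: skipped ", n_skipped,
            " non-SNP / multi-allelic record(s)")

  fix <- fix[is_snp, , drop = FALSE]
  gt <- gt[is_snp, , drop = FALSE]
  dose <- gt_to_dosage(gt)

  pops <- pop_labels(popmap)
  count_pop <- function(label) {
    keep <- popmap$sample[popmap$population == label]
    sub <- dose[, colnames(dose) %in% keep, drop = FALSE]
    list(n = length(keep),
         hom_ref = rowSums(sub == 0L, na.rm = TRUE),
         het     = rowSums(sub == 1L, na.rm = TRUE),
         hom_alt = rowSums(sub == 2L, na.rm = TRUE),
         miss    = rowSums(is.na(sub)) + (length(keep) - ncol(sub)))
  }
  c1 <- count_pop(pops[1]); c2 <- count_pop(pops[2])
  df <- data.frame(chrom = fix[, "CHROM"],
                   pos = as.integer(fix[, "POS"]),
                   ref = fix[, "REF"], alt = fix[, "ALT"],
                   hom_ref_1 = c1$hom_ref, het_1 = c1$het,
                   hom_alt_1 = c1$hom_alt, miss_1 = c1$miss,
                   hom_ref_2 = c2$hom_ref, het_2 = c2$het,
                   hom_alt_2 = c2$hom_alt, miss_2 = c2$miss,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  new_site_table(df, pops, c(c1$n, c2$n), n_skipped = n_skipped)
}

#' Filter sites by per-population call rate
#'
#' Retains a site only if the fraction of called genotypes is at least
#' `min_fraction` in *both* populations (inclusive boundary), the standard
#' low-power guard for between-population allele-frequency contrasts.
#'
#' @param sites A `site_table`.
#' @param min_fraction Minimum called fraction, default 0.5.
#' @return The filtered `site_table`.
#' @export
filter_by_call_rate <- function(sites, min_fraction = 0.5) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  keep <- sites$call_1 >= min_fraction & sites$call_2 >= min_fraction
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "populations") <- attr(sites, "populations")
  attr(out, "pop_sizes") <- attr(sites, "pop_sizes")
  attr(out, "n_skipped") <- attr(sites, "n_skipped")
  class(out) <- class(sites)
  out
}

#' Alternative-allele frequency per population
#'
#' @param sites A `site_table`.
#' @param population Population label or index (1 or 2).
#' @return Numeric vector of alt-allele frequencies,
#'   `(2 hom_alt + het) / (2 called)`; `NA` where no genotype was called.
#' @export
allele_frequency <- function(sites, population) {
  i <- pop_index(sites, population)
  ha <- sites[[paste0("hom_alt_", i)]]
  he <- sites[[paste0("het_", i)]]
  hr <- sites[[paste0("hom_ref_", i)]]
  called <- hr + he + ha
  ifelse(called > 0, (2 * ha + he) / (2 * called), NA_real_)
}

pop_index <- function(sites, population) {
  pops <- attr(sites, "populations")
  if (is.numeric(population)) {
    stopifnot(population %in% c(1, 2))
    return(as.integer(population))
  }
  i <- match(population, pops)
  if (is.na(i)) stop("unknown population: ", population)
  i
}

#' Write a site table back to a minimal VCF
#'
#' Emits per-sample GT columns consistent with the stored genotype counts
#' (samples within each population filled in hom-ref, het, hom-alt, missing
#' order). Used for round-trip testing and for exporting synthetic data.
#'
#' @param sites A `site_table`.
#' @param path Output path.
#' @param sample_names Optional character vector of sample names
#'   (population 1 samples first); defaults to `<pop><i>`.
#' @return `path`, invisibly.
#' @export
write_sites_vcf <- function(sites, path, sample_names = NULL) {
  pops <- attr(sites, "populations")
  ns <- attr(sites, "pop_sizes")
  if (is.null(sample_names))
    sample_names <- c(paste0(pops[1], seq_len(ns[1])),
                      paste0(pops[2], seq_len(ns[2])))
  stopifnot(length(sample_names) == sum(ns))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", unique(sites$chrom), ">"),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sample_names), collapse = "\t")), con)
  gt_block <- function(i) {
    hr <- sites[[paste0("hom_ref_", i)]]; he <- sites[[paste0("het_", i)]]
    ha <- sites[[paste0("hom_alt_", i)]]; mi <- sites[[paste0("miss_", i)]]
    mapply(function(a, b, c, d)
      paste(rep(c("0/0", "0/1", "1/1", "./."), c(a, b, c, d)),
            collapse = "\t"), hr, he, ha, mi, USE.NAMES = FALSE)
  }
  lines <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                 "PASS", ".", "GT", gt_block(1), gt_block(2), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
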