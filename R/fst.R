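#' Per-site Weir & Cockerham Fst for two populations
#'
#' Evaluates the Weir & Cockerham (1984) theta-hat estimator for a single
#' biallelic site observed in two populations of diploids, returning the
#' three variance components: `a` (among populations), `b` (among
#' individuals within populations), `c` (within individuals, i.e. the
#' heterozygote term), and `fst = a / (a + b + c)`.
#'
#' Sample sizes enter through the usual n-bar and n_c corrections, so the
#' estimate is unbiased under unequal sample sizes and may be negative.
#' A site monomorphic across both populations (zero denominator), or with
#' zero called genotypes in either population, yields `NA` components
#' (the undefined sentinel; such sites are excluded downstream).
#'
#' @param counts_pop1,counts_pop2 Integer vectors `c(hom_ref, het, hom_alt)`
#'   of called genotype counts in each population.
#' @return A named list with `a`, `b`, `c` and `fst`.
#' @examples
#' wc_fst_site(c(0, 0, 67), c(7, 0, 0))$fst   # fixed difference -> 1
#' @export
wc_fst_site <- function(counts_pop1, counts_pop2) {
  stopifnot(length(counts_pop1) == 3, length(counts_pop2) == 3,
            all(counts_pop1 >= 0), all(counts_pop2 >= 0))
  n1 <- sum(counts_pop1); n2 <- sum(counts_pop2)
  if (n1 == 0 || n2 == 0)
    return(list(a = NA_real_, b = NA_real_, c = NA_real_, fst = NA_real_))
  p1 <- (2 * counts_pop1[3] + counts_pop1[2]) / (2 * n1)
  p2 <- (2 * counts_pop2[3] + counts_pop2[2]) / (2 * n2)
  h1 <- counts_pop1[2] / n1
  h2 <- counts_pop2[2] / n2
  comp <- wc_components(n1, p1, h1, n2, p2, h2)
  list(a = unname(comp[1, "a"]), b = unname(comp[1, "b"]),
       c = unname(comp[1, "c"]), fst = unname(comp[1, "fst"]))
}

# Vectorised W&C (1984) variance components for r = 2 populations.
# n: diploid sample sizes, p: alt-allele frequencies, h: observed
# heterozygote frequencies. Requires n1, n2 >= 1 (and nbar > 1 for the
# finite-sample corrections; nbar == 1 yields NA).
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  fst <- ifelse(is.finite(denom) & denom != 0, a / denom, NA_real_)
  cbind(a = a, b = b, c = cc, fst = fst)
}

#' Per-site Fst across a site table
#'
#' Applies the Weir & Cockerham estimator to every row of a `site_table`,
#' returning chromosome, position, the variance components and theta-hat.
#' Sites with no called genotypes in a population, or monomorphic across
#' both populations, carry `NA`.
#'
#' @param sites A `site_table` (see [read_sites()]).
#' @return A data.frame with columns `chrom`, `pos`, `a`, `b`, `c`, `fst`.
#' @export
fst_sites <- function(sites) {
  n1 <- sites$hom_ref_1 + sites$het_1 + sites$hom_alt_1
  n2 <- sites$hom_ref_2 + sites$het_2 + sites$hom_alt_2
  p1 <- (2 * sites$hom_alt_1 + sites$het_1) / (2 * n1)
  p2 <- (2 * sites$hom_alt_2 + sites$het_2) / (2 * n2)
  h1 <- sites$het_1 / n1
  h2 <- sites$het_2 / n2
  comp <- wc_components(n1, p1, h1, n2, p2, h2)
  comp[n1 == 0 | n2 == 0, ] <- NA_real_
  out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    a = comp[, "a"], b = comp[, "b"], c = comp[, "c"],
                    fst = comp[, "fst"], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
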