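#' Select fixed and highly differentiated sites
#'
#' Retains sites with per-site theta-hat at or above `threshold`
#' (inclusive) and classifies each as `"fixed"` or `"high"`. A site counts
#' as fixed only when theta-hat equals 1 within floating-point tolerance
#' *and* the two populations are monomorphic for opposite alleles among
#' called genotypes — the biological definition, which guards against
#' rounding artefacts.
#'
#' @param fst Data.frame from [fst_sites()].
#' @param sites The matching `site_table` (same row order), used for the
#'   monomorphism check.
#' @param threshold Minimum Fst (default 0.75, inclusive).
#' @return Data.frame of divergent sites: `chrom`, `pos`, `ref`, `alt`,
#'   `fst`, `category`.
#' @export
select_divergent_sites <- function(fst, sites, threshold = 0.75) {
  stopifnot(nrow(fst) == nrow(sites))
  keep <- !is.na(fst$fst) & fst$fst >= threshold
  p1 <- allele_frequency(sites, 1)
  p2 <- allele_frequency(sites, 2)
  mono_opposite <- (p1 == 0 & p2 == 1) | (p1 == 1 & p2 == 0)
  fixed <- keep & abs(fst$fst - 1) <= 1e-12 & !is.na(mono_opposite) &
    mono_opposite
  out <- data.frame(chrom = sites$chrom[keep], pos = sites$pos[keep],
                    ref = sites$ref[keep], alt = sites$alt[keep],
                    fst = fst$fst[keep],
                    category = ifelse(fixed[keep], "fixed", "high"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Attach effect annotations to divergent sites
#'
#' Many-to-many join on (chrom, pos): a site shared by overlapping
#' transcripts keeps one row per effect.
#'
#' @param divergent Data.frame from [select_divergent_sites()].
#' @param effects Data.frame from [classify_variants()].
#' @return Data.frame of divergent sites with `gene_id`, `tx_id`,
#'   `consequence`, `aa_ref`, `aa_alt` columns.
#' @export
join_effects <- function(divergent, effects) {
  out <- merge(divergent,
               effects[, c("chrom", "pos", "gene_id", "tx_id", "consequence",
                           "aa_ref", "aa_alt")],
               by = c("chrom", "pos"), all.x = TRUE, sort = FALSE)
  out$consequence[is.na(out$consequence)] <- "non_functional"
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Genes carrying putatively functional divergent sites
#'
#' Maps each gene to its putatively functional divergent sites. Genes
#' whose divergent sites are all synonymous or non-functional are absent.
#' A site inside two overlapping genes contributes to both.
#'
#' @param divergent_effects Data.frame from [join_effects()].
#' @return Named list: gene id -> data.frame of its functional divergent
#'   sites.
#' @export
genes_with_functional_divergence <- function(divergent_effects) {
  f <- divergent_effects[is_putatively_functional(divergent_effects$consequence) &
                           !is.na(divergent_effects$gene_id), , drop = FALSE]
  if (nrow(f) == 0L) return(list())
  split(f, f$gene_id)
}

#' Label divergent sites with their scan-window context
#'
#' Adds the containing fixed-width window (1-based inclusive bounds) and
#' flags whether that window, or an immediately neighbouring window on the
#' same chromosome, is a scan outlier.
#'
#' @param divergent Data.frame of divergent sites (needs `chrom`, `pos`).
#' @param windows Data.frame from [window_scan()] with `outlier` flags.
#' @return `divergent` with `window_start`, `window_end`,
#'   `in_outlier_window`, `near_outlier_window` columns.
#' @export
annotate_window_context <- function(divergent, windows) {
  wsize <- unique(windows$end - windows$start + 1L)
  stopifnot(length(wsize) == 1L)
  idx <- (divergent$pos - 1L) %/% wsize          # 0-based window index
  divergent$window_start <- idx * wsize + 1L
  divergent$window_end <- (idx + 1L) * wsize
  wkey <- paste(windows$chrom, (windows$start - 1L) %/% wsize)
  outl <- windows$outlier[match(paste(divergent$chrom, idx), wkey)]
  left <- windows$outlier[match(paste(divergent$chrom, idx - 1L), wkey)]
  right <- windows$outlier[match(paste(divergent$chrom, idx + 1L), wkey)]
  divergent$in_outlier_window <- !is.na(outl) & outl
  divergent$near_outlier_window <- divergent$in_outlier_window |
    (!is.na(left) & left) | (!is.na(right) & right)
  divergent
}
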