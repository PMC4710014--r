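#' Read a pathway-membership table
#'
#' Two-column TSV (pathway, gene), one row per membership.
#'
#' @param path Path to the TSV (no header).
#' @return Named list: pathway -> character vector of gene ids.
#' @export
read_pathway_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("pathway", "gene"))
  lapply(split(tab$gene, tab$pathway), unique)
}

#' Expected pathway hits in a gene sample
#'
#' Under random sampling of `sample_size` genes from a background of
#' `background_size`, the expected number falling in a pathway of
#' `pathway_size` members is `sample_size * pathway_size / background_size`
#' (reported to 2 decimals in tables).
#'
#' @param background_size Background (reference) gene-list size.
#' @param pathway_size Number of background genes in the pathway.
#' @param sample_size Number of genes in the test sample.
#' @return Expected count (numeric).
#' @export
expected_count <- function(background_size, pathway_size, sample_size) {
  if (background_size == 0) stop("background_size must be positive")
  stopifnot(pathway_size <= background_size, sample_size <= background_size)
  sample_size * pathway_size / background_size
}

#' One-sided pathway over-representation test
#'
#' Primary statistic is the binomial upper tail
#' `P(X >= observed)` with `n = sample_size` and
#' `p = pathway_size / background_size` (the classic over-representation
#' test); a hypergeometric tail (one-sided Fisher exact) is available as
#' an alternative mode.
#'
#' @inheritParams expected_count
#' @param observed Observed pathway genes in the sample.
#' @param mode `"binomial"` (default) or `"hypergeometric"`.
#' @return One-sided p-value in (0, 1].
#' @export
overrepresentation_test <- function(background_size, pathway_size,
                                    sample_size, observed,
                                    mode = c("binomial", "hypergeometric")) {
  mode <- match.arg(mode)
  if (observed > pathway_size)
    stop("observed (", observed, ") exceeds pathway size (", pathway_size, ")")
  stopifnot(observed <= sample_size)
  if (observed == 0) return(1)
  if (mode == "binomial") {
    stats::pbinom(observed - 1, size = sample_size,
                  prob = pathway_size / background_size, lower.tail = FALSE)
  } else {
    stats::phyper(observed - 1, m = pathway_size,
                  n = background_size - pathway_size, k = sample_size,
                  lower.tail = FALSE)
  }
}

#' Bonferroni correction
#'
#' @param pvalues Numeric vector of raw p-values.
#' @return `min(1, p * m)` with `m = length(pvalues)`.
#' @export
bonferroni <- function(pvalues) {
  pmin(1, pvalues * length(pvalues))
}

#' Pathway over-representation table
#'
#' Tests each pathway for over-representation of `foreground` genes
#' against the `background` list, with Bonferroni correction across
#' pathways. A pathway named `"Unclassified"` is listed (counts and
#' expectation only) but excluded from testing and from the correction
#' denominator. Output mirrors the classic enrichment-table layout:
#' reference count, sample count, expected, fold enrichment, direction,
#' p, adjusted p; rows ordered by p.
#'
#' @param pathways Named list: pathway -> gene ids (see
#'   [read_pathway_table()]). Every pathway gene must be in `background`.
#' @param foreground Character vector of sample gene ids.
#' @param background Character vector of background gene ids.
#' @param mode Test mode passed to [overrepresentation_test()].
#' @return Data.frame with one row per pathway.
#' @export
pathway_enrichment <- function(pathways, foreground, background,
                               mode = "binomial") {
  foreground <- unique(foreground)
  background <- unique(background)
  stray <- setdiff(foreground, background)
  if (length(stray))
    stop("foreground gene(s) not in background: ",
         paste(utils::head(stray, 5), collapse = ", "))
  M <- length(background)
  n <- length(foreground)
  rows <- lapply(names(pathways), function(pw) {
    genes <- intersect(pathways[[pw]], background)
    K <- length(genes)
    k <- length(intersect(genes, foreground))
    exp_k <- expected_count(M, K, n)
    data.frame(pathway = pw, ref_count = K, sample_count = k,
               expected = exp_k,
               fold_enrichment = if (exp_k > 0) k / exp_k else NA_real_,
               direction = ifelse(k >= exp_k, "+", "-"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  testable <- out$pathway != "Unclassified"
  out$p <- NA_real_
  out$p[testable] <- mapply(function(K, k)
    overrepresentation_test(M, K, n, k, mode = mode),
    out$ref_count[testable], out$sample_count[testable])
  out$p_adj <- NA_real_
  out$p_adj[testable] <- bonferroni(out$p[testable])
  out <- out[order(is.na(out$p), out$p), ]
  rownames(out) <- NULL
  out
}
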