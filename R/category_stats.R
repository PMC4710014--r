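#' Functional-category spectrum across Fst bins
#'
#' Cross-tabulates divergent sites by Fst bin and consequence category and
#' expresses counts as a percentage of the total sites in each bin. In the
#' default multi-label mode a site with several consequence labels (e.g.
#' from overlapping transcripts) contributes once to each category; the
#' exclusive mode first reduces each site to its single most severe
#' consequence (see [CONSEQUENCE_SEVERITY]).
#'
#' @param divergent_effects Data.frame from [join_effects()] (needs
#'   `chrom`, `pos`, `fst`, `consequence`).
#' @param edges Bin edges passed to [assign_fst_bin()].
#' @param mode `"multi"` (default) or `"exclusive"`.
#' @return List with `counts` (bin x category matrix), `percent`
#'   (same shape, percentages of bin totals) and `totals` (distinct sites
#'   per bin).
#' @export
bin_spectrum <- function(divergent_effects, edges = c(0.85, 0.9, 0.95, 1),
                         mode = c("multi", "exclusive")) {
  mode <- match.arg(mode)
  de <- divergent_effects
  if (mode == "exclusive") de <- most_severe_effects(de)
  de <- de[!duplicated(paste(de$chrom, de$pos, de$consequence)), ]
  bin <- assign_fst_bin(de$fst, edges)
  keep <- !is.na(bin)
  counts <- table(bin[keep], factor(de$consequence[keep]))
  # totals count distinct sites, not labels, so multi-label percentages
  # can sum above 100 but each is a fraction of sites in the bin
  site_bin <- bin[keep][!duplicated(paste(de$chrom, de$pos)[keep])]
  totals <- table(site_bin)
  percent <- sweep(unclass(counts), 1, as.numeric(totals), "/") * 100
  percent[as.numeric(totals) == 0, ] <- NA_real_
  list(counts = unclass(counts), percent = percent,
       totals = as.numeric(totals))
}

#' One-way analysis of variance over category groups
#'
#' Classic equal-variance one-way ANOVA (via [stats::aov()]):
#' `F = MS_between / MS_within` with df `(k - 1, N - k)`.
#'
#' @param groups Named list: category -> numeric vector of values
#'   (each group needs >= 2 values).
#' @return List with `F`, `df` (length-2), `p`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 1L) >= 2))
  values <- unlist(groups, use.names = FALSE)
  if (stats::var(values) == 0) stop("all values identical: ANOVA undefined")
  g <- factor(rep(names(groups), vapply(groups, length, 1L)))
  fit <- stats::aov(values ~ g)
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1],
       df = c(s[["Df"]][1], s[["Df"]][2]),
       p = s[["Pr(>F)"]][1])
}

#' Tukey's range test over category groups
#'
#' All-pairs comparison of group means after a one-way ANOVA, using the
#' studentized range distribution with `(k, N - k)` df (via
#' [stats::TukeyHSD()]). Reports, per pair, the mean difference, the
#' studentized-range statistic q, and the family-wise adjusted p.
#'
#' @inheritParams one_way_anova
#' @return Data.frame with `pair`, `diff`, `q`, `p_adj`.
#' @export
tukey_hsd <- function(groups) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 1L) >= 2))
  values <- unlist(groups, use.names = FALSE)
  if (stats::var(values) == 0) stop("all values identical: test undefined")
  g <- factor(rep(names(groups), vapply(groups, length, 1L)))
  fit <- stats::aov(values ~ g)
  t_ <- stats::TukeyHSD(fit)$g
  ns <- vapply(groups, length, 1L)
  ms_within <- sum((unlist(lapply(groups, function(v) (v - mean(v))^2)))) /
    (length(values) - length(groups))
  pairs <- strsplit(rownames(t_), "-", fixed = TRUE)
  q <- vapply(seq_along(pairs), function(i) {
    na <- ns[pairs[[i]][1]]; nb <- ns[pairs[[i]][2]]
    abs(t_[i, "diff"]) / sqrt(ms_within / 2 * (1 / na + 1 / nb))
  }, numeric(1))
  out <- data.frame(pair = rownames(t_), diff = t_[, "diff"], q = q,
                    p_adj = t_[, "p adj"], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Flanking-Fst contrast across functional categories
#'
#' For every putatively functional divergent site, computes the mean Fst
#' in a window centred on the site ([flanking_mean_fst()]), groups those
#' values by consequence category, and contrasts the groups with a one-way
#' ANOVA followed by Tukey's range test. Synonymous sites are retained as
#' the neutral reference category. Categories with fewer than 2 values
#' are dropped.
#'
#' @param fst Data.frame from [fst_sites()] (all sites, for the flanks).
#' @param divergent_effects Data.frame from [join_effects()].
#' @param span Flanking window width in bp (default 50 kb).
#' @param categories Consequence labels to contrast. Defaults to the six
#'   scan categories (missense reported as "non-synonymous").
#' @return List with `groups` (category -> flanking means), `anova`,
#'   `tukey`.
#' @export
category_contrast <- function(fst, divergent_effects, span = 50000L,
                              categories = c("five_prime_utr",
                                             "three_prime_utr", "missense",
                                             "splice_region", "stop_gained",
                                             "synonymous")) {
  de <- divergent_effects[divergent_effects$consequence %in% categories, ,
                          drop = FALSE]
  de <- de[!duplicated(paste(de$chrom, de$pos, de$consequence)), ]
  if (nrow(de) == 0L) stop("no sites in the requested categories")
  de$flank <- vapply(seq_len(nrow(de)), function(i)
    flanking_mean_fst(fst, de$chrom[i], de$pos[i], span = span), numeric(1))
  de <- de[!is.na(de$flank), ]
  groups <- split(de$flank, de$consequence)
  groups <- groups[vapply(groups, length, 1L) >= 2]
  list(groups = groups,
       anova = one_way_anova(groups),
       tukey = tukey_hsd(groups))
}
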