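#' Mean Fst in non-overlapping genomic windows
#'
#' Tiles every chromosome with fixed-width windows
#' `[(k-1) * window_size + 1, k * window_size]` (1-based inclusive) and
#' computes, per window, the number of sites with a defined per-site
#' theta-hat, the unweighted arithmetic mean of those values, and the
#' ratio-of-sums ("weighted") estimator `sum(a) / sum(a + b + c)`.
#' Negative per-site estimates are retained (clamping would bias window
#' means upward). Windows with fewer than `min_sites` defined sites carry
#' `NA` means and are excluded from the Z-transform downstream.
#'
#' @param fst A data.frame from [fst_sites()], sorted by (chrom, pos).
#' @param window_size Window width in bp (default 500 kb).
#' @param min_sites Minimum defined sites for a window mean (default 10).
#' @return A data.frame with `chrom`, `start`, `end`, `n_sites`,
#'   `mean_fst`, `wmean_fst`.
#' @export
window_mean_fst <- function(fst, window_size = 500000L, min_sites = 10L) {
  stopifnot(window_size >= 1)
  win <- (fst$pos - 1L) %/% window_size   # 0-based window index
  key <- paste(fst$chrom, win, sep = "\r")
  ok <- !is.na(fst$fst)
  n_sites <- tapply(ok, key, sum)
  mean_fst <- tapply(ifelse(ok, fst$fst, NA), key, mean, na.rm = TRUE)
  sum_a <- tapply(ifelse(ok, fst$a, NA), key, sum, na.rm = TRUE)
  sum_abc <- tapply(ifelse(ok, fst$a + fst$b + fst$c, NA), key, sum,
                    na.rm = TRUE)
  ks <- strsplit(names(n_sites), "\r", fixed = TRUE)
  chrom <- vapply(ks, `[`, "", 1L)
  idx <- as.integer(vapply(ks, `[`, "", 2L))
  out <- data.frame(chrom = chrom,
                    start = idx * window_size + 1L,
                    end = (idx + 1L) * window_size,
                    n_sites = as.integer(n_sites),
                    mean_fst = as.numeric(mean_fst),
                    wmean_fst = as.numeric(sum_a) / as.numeric(sum_abc),
                    stringsAsFactors = FALSE)
  out$mean_fst[out$n_sites < min_sites] <- NA_real_
  out$wmean_fst[out$n_sites < min_sites] <- NA_real_
  out$mean_fst[out$n_sites == 0] <- NA_real_
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Z-transform a vector of window statistics
#'
#' Standardises to genome-wide mean 0 and sample standard deviation 1
#' (n - 1 denominator). All windows, autosomes and X alike, enter a single
#' transform so that one genome-wide threshold applies.
#'
#' @param values Numeric vector (NAs pass through as NA).
#' @return Numeric vector of Z-scores.
#' @export
z_transform <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("z_transform needs at least 2 non-missing values")
  s <- stats::sd(values[ok])
  if (s == 0) stop("z_transform undefined for constant input")
  (values - mean(values[ok])) / s
}

#' Flag outlier windows on the Z(Fst) scale
#'
#' Adds (or refreshes) a `z_fst` column from the chosen window estimator
#' and flags windows whose Z-score is at least `threshold` standard
#' deviations above the genome-wide mean (inclusive; upper tail only —
#' the scan targets elevated divergence).
#'
#' @param windows Data.frame from [window_mean_fst()].
#' @param threshold Z threshold in standard deviations (default 5).
#' @param estimator `"unweighted"` (mean of per-site theta-hat; default)
#'   or `"weighted"` (ratio of sums).
#' @return `windows` with `z_fst` and logical `outlier` columns.
#' @export
flag_outlier_windows <- function(windows, threshold = 5,
                                 estimator = c("unweighted", "weighted")) {
  estimator <- match.arg(estimator)
  vals <- if (estimator == "unweighted") windows$mean_fst else windows$wmean_fst
  windows$z_fst <- z_transform(vals)
  windows$outlier <- !is.na(windows$z_fst) & windows$z_fst >= threshold
  windows
}

#' Mean Fst in a window flanking a focal site
#'
#' Computes the unweighted mean per-site theta-hat over all sites on the
#' focal chromosome within `span / 2` bp of the focal position (inclusive
#' bounds; the focal site itself included). Windows extending past a
#' chromosome edge are truncated, not discarded.
#'
#' @param fst Data.frame from [fst_sites()].
#' @param chrom Focal chromosome.
#' @param pos Focal position (1-based bp).
#' @param span Total window width in bp (default 50 kb).
#' @return Mean Fst (scalar); `NA` if no defined sites fall in the window.
#' @export
flanking_mean_fst <- function(fst, chrom, pos, span = 50000L) {
  half <- span / 2
  sel <- fst$chrom == chrom & fst$pos >= pos - half & fst$pos <= pos + half &
    !is.na(fst$fst)
  if (!any(sel)) return(NA_real_)
  mean(fst$fst[sel])
}

#' Assign Fst values to the scan's frequency bins
#'
#' Half-open, left-inclusive bins `[0.85, 0.9)`, `[0.9, 0.95)`,
#' `[0.95, 1)`, with exactly-1 (fixed differences) as its own category.
#' Values below the lowest edge return `NA` (no bin).
#'
#' @param fst Numeric vector of per-site Fst.
#' @param edges Increasing numeric vector of interior bin edges ending at 1
#'   (default `c(0.85, 0.9, 0.95, 1)`).
#' @return Factor of bin labels such as `"0.85-0.9"`, `"0.95-1"`, `"1"`.
#' @export
assign_fst_bin <- function(fst, edges = c(0.85, 0.9, 0.95, 1)) {
  stopifnot(!is.unsorted(edges), edges[length(edges)] == 1)
  labs <- paste(edges[-length(edges)], edges[-1], sep = "-")
  out <- rep(NA_character_, length(fst))
  for (i in seq_len(length(edges) - 1L)) {
    out[!is.na(fst) & fst >= edges[i] & fst < edges[i + 1]] <- labs[i]
  }
  out[!is.na(fst) & fst == 1] <- "1"
  factor(out, levels = c(labs, "1"))
}

#' Windowed selection scan in one call
#'
#' Convenience wrapper: windows, Z-transform and outlier flags.
#'
#' @inheritParams window_mean_fst
#' @inheritParams flag_outlier_windows
#' @return Data.frame of windows with `z_fst` and `outlier`.
#' @export
window_scan <- function(fst, window_size = 500000L, min_sites = 10L,
                        threshold = 5, estimator = "unweighted") {
  w <- window_mean_fst(fst, window_size = window_size, min_sites = min_sites)
  flag_outlier_windows(w, threshold = threshold, estimator = estimator)
}

#' Write windows as a BED-compatible TSV
#'
#' Emits both coordinate conventions, clearly labelled: BED's 0-based
#' half-open `bed_start`/`bed_end` and the 1-based inclusive
#' `start`/`end` used in reports.
#'
#' @param windows Data.frame from [window_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path) {
  out <- data.frame(chrom = windows$chrom,
                    bed_start = windows$start - 1L,
                    bed_end = windows$end,
                    start = windows$start, end = windows$end,
                    windows[, setdiff(names(windows),
                                      c("chrom", "start", "end")),
                            drop = FALSE])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
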