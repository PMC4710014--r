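test_that("bin spectrum counts and percentages recompute exactly", {
  de <- data.frame(
    chrom = "c", pos = 1:5, ref = "A", alt = "T",
    fst = c(0.87, 0.87, 0.87, 0.87, 0.87),
    category = "high", gene_id = "g", tx_id = "t",
    consequence = c("synonymous", "synonymous", "synonymous", "synonymous",
                    "missense"),
    aa_ref = NA, aa_alt = NA, stringsAsFactors = FALSE)
  sp <- bin_spectrum(de)
  expect_equal(sp$totals[1], 5)
  expect_equal(sp$percent["0.85-0.9", "synonymous"], 80)
  expect_equal(sp$percent["0.85-0.9", "missense"], 20)
  # percentages recompute from counts
  expect_equal(sp$percent["0.85-0.9", ],
               sp$counts["0.85-0.9", ] / sp$totals[1] * 100)
  expect_equal(sum(sp$totals), 5)
})

test_that("multi-label sites count once per category; exclusive mode dedups", {
  de <- data.frame(
    chrom = "c", pos = c(1, 1, 2), ref = "A", alt = "T",
    fst = c(0.96, 0.96, 0.96), category = "high",
    gene_id = "g", tx_id = c("t1", "t2", "t1"),
    consequence = c("missense", "splice_region", "synonymous"),
    aa_ref = NA, aa_alt = NA, stringsAsFactors = FALSE)
  multi <- bin_spectrum(de, mode = "multi")
  expect_equal(multi$totals[3], 2)   # two distinct sites in 0.95-1
  expect_equal(multi$counts["0.95-1", "missense"], 1)
  expect_equal(multi$counts["0.95-1", "splice_region"], 1)
  excl <- bin_spectrum(de, mode = "exclusive")
  expect_equal(sum(excl$counts["0.95-1", ]), 2)   # one label per site
  expect_equal(unname(excl$counts["0.95-1", "missense"]), 1)
})

test_that("ANOVA df arithmetic: 6 groups of 2824 values give (5, 2818)", {
  set.seed(30)
  sizes <- c(500, 600, 700, 500, 500, 24)
  groups <- lapply(sizes, function(n) rnorm(n))
  names(groups) <- paste0("g", 1:6)
  a <- one_way_anova(groups)
  expect_equal(a$df, c(5, 2818))
})

test_that("ANOVA reproduces hand-computed sums of squares", {
  # small worked example, computed from the one-way decomposition by hand:
  # groups A = (2, 4, 6), B = (5, 7, 9), C = (9, 11, 13)
  # means 4, 7, 11; grand mean 22/3; SSB = 3*((4-22/3)^2+(7-22/3)^2+
  # (11-22/3)^2) = 74/...; compute explicitly below
  g <- list(A = c(2, 4, 6), B = c(5, 7, 9), C = c(9, 11, 13))
  means <- vapply(g, mean, 1); gm <- mean(unlist(g))
  ssb <- sum(3 * (means - gm)^2)
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 1))
  f_hand <- (ssb / 2) / (ssw / 6)
  p_hand <- pf(f_hand, 2, 6, lower.tail = FALSE)
  a <- one_way_anova(g)
  expect_equal(a$F, f_hand, tolerance = 1e-10)
  expect_equal(a$p, p_hand, tolerance = 1e-10)
  expect_equal(round(a$F, 4), round(f_hand, 4))
})

test_that("groups with equal means give F = 0", {
  g <- list(a = c(1, 2, 3), b = c(0, 2, 4), c = c(2, 2, 2))
  expect_equal(one_way_anova(g)$F, 0, tolerance = 1e-12)
  expect_error(one_way_anova(list(a = c(1, 1), b = c(1, 1))), "identical")
})

test_that("with two groups, F equals the squared pooled-variance t statistic", {
  x <- c(1.2, 2.3, 3.1); y <- c(4.0, 5.2, 6.8)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  a <- one_way_anova(list(x = x, y = y))
  expect_equal(a$F, t_hand^2, tolerance = 1e-10)
})

test_that("Tukey HSD: zero differences, order invariance, q = sqrt(2)|t|", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3.0001))
  tk <- tukey_hsd(g)
  ab <- tk[tk$pair %in% c("b-a", "a-b"), ]
  expect_equal(ab$diff, 0, tolerance = 1e-12)
  expect_gt(min(tk$p_adj), 0.9)
  # order invariance
  set.seed(14)
  g2 <- list(u = rnorm(8), v = rnorm(8, 1), w = rnorm(8, 2))
  t1 <- tukey_hsd(g2)
  t2 <- tukey_hsd(g2[c(3, 1, 2)])
  key <- function(tt) {
    s <- strsplit(tt$pair, "-")
    k <- vapply(s, function(p) paste(sort(p), collapse = "-"), "")
    ord <- order(k)
    data.frame(pair = k[ord], absdiff = abs(tt$diff)[ord],
               q = tt$q[ord], p = tt$p_adj[ord])
  }
  expect_equal(key(t1), key(t2), tolerance = 1e-10)
  # two groups: adjusted p equals the plain two-sample comparison, q = √2|t|
  x <- c(1.2, 2.3, 3.1, 2.0); y <- c(4.0, 5.2, 6.8, 5.5)
  tk2 <- tukey_hsd(list(x = x, y = y))
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / 6
  t_hand <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(tk2$q, sqrt(2) * abs(t_hand), tolerance = 1e-10)
  p_t <- 2 * pt(abs(t_hand), df = 6, lower.tail = FALSE)
  # ptukey's quantile integration is accurate to ~1e-4 relative
  expect_equal(tk2$p_adj, p_t, tolerance = 1e-4)
})

test_that("a category with shifted flanking Fst is the one Tukey flags", {
  set.seed(77)
  cats <- c("synonymous", "missense", "three_prime_utr", "five_prime_utr")
  groups <- lapply(cats, function(cc)
    rnorm(40, mean = if (cc == "missense") 0.45 else 0.2, sd = 0.05))
  names(groups) <- cats
  a <- one_way_anova(groups)
  expect_lt(a$p, 1e-6)
  tk <- tukey_hsd(groups)
  hit <- grepl("missense", tk$pair)
  expect_true(all(tk$p_adj[hit] < 0.05))
  expect_true(all(tk$p_adj[!hit] >= 0.05))
})

test_that("category_contrast wires flanking means into the ANOVA", {
  set.seed(6)
  pos <- sort(sample.int(2000000L, 600))
  f <- data.frame(chrom = "chr1", pos = pos, a = 1, b = 1, c = 0,
                  fst = runif(600, 0.1, 0.3))
  # plant elevated flanks around missense sites at known spots
  focal <- data.frame(
    chrom = "chr1", pos = seq(100000L, 1900000L, by = 100000L),
    ref = "A", alt = "T", fst = 0.9, category = "high",
    gene_id = "g", tx_id = "t",
    consequence = rep(c("missense", "synonymous"), length.out = 19),
    aa_ref = NA, aa_alt = NA, stringsAsFactors = FALSE)
  for (p in focal$pos[focal$consequence == "missense"])
    f$fst[abs(f$pos - p) <= 25000] <- f$fst[abs(f$pos - p) <= 25000] + 0.5
  ct <- category_contrast(f, focal, span = 50000L)
  expect_setequal(names(ct$groups), c("missense", "synonymous"))
  expect_lt(ct$anova$p, 0.001)
  expect_gt(mean(ct$groups$missense), mean(ct$groups$synonymous))
})
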