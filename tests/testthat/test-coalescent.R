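one_deme <- function(N = 1000, mu = 1e-8, L = 10000L, blocks = 1L)
  demographic_model(data.frame(name = "p", size = N), mu = mu,
                    window_length = L, blocks = blocks)

island2 <- function(N = 1000, m = 2.5e-4, mu = 1e-7, L = 20000L,
                    blocks = 5L)
  suppressWarnings(demographic_model(
    data.frame(name = c("a", "b"), size = c(N, N)),
    migration = data.frame(from = c("a", "b"), to = c("b", "a"),
                           rate = c(m, m)),
    mu = mu, window_length = L, blocks = blocks))

test_that("pairwise TMRCA and coalescence waiting times match theory", {
  m <- one_deme(N = 500)
  set.seed(101)
  tm <- replicate(4000, canidscan:::sim_genealogy(m, c("p", "p"))$tmrca)
  # E[T2] = 2N, Var = (2N)^2: 3 MC standard errors
  se <- 1000 / sqrt(4000)
  expect_lt(abs(mean(tm) - 1000), 3 * se)
  # exponential shape: sd ~= mean for an exponential
  expect_equal(sd(tm) / mean(tm), 1, tolerance = 0.1)
  # first waiting time with k = 5 lineages: rate k(k-1)/(4N) = 0.01
  set.seed(102)
  w5 <- replicate(4000, {
    g <- canidscan:::sim_genealogy(m, rep("p", 5))
    min(g$time[g$time > 0])
  })
  expect_lt(abs(mean(w5) - 100), 3 * 100 / sqrt(4000))
})

test_that("single-deme pairwise diversity matches 4*N*mu per site", {
  N <- 2000; mu <- 1e-6; L <- 20000L
  m <- one_deme(N = N, mu = mu, L = L, blocks = 4L)
  set.seed(103)
  reps <- 400
  diffs <- replicate(reps, {
    w <- simulate_window(m, c(p = 2))
    ncol(w$haplotypes)    # pairwise differences for n = 2
  })
  exp_diff <- 4 * N * mu * L
  se <- sd(diffs) / sqrt(reps)
  expect_lt(abs(mean(diffs) - exp_diff), 3 * se)
})

test_that("site-frequency spectrum in one deme follows the 1/i expectation", {
  m <- one_deme(N = 1000, mu = 1e-6, L = 5000L, blocks = 2L)
  set.seed(104)
  n <- 8L
  counts <- integer(n - 1)
  for (r in 1:300) {
    w <- simulate_window(m, c(p = n))
    if (length(w$positions) == 0) next
    dac <- colSums(w$haplotypes)
    tab <- tabulate(dac, nbins = n - 1)
    counts <- counts + tab
  }
  props <- counts / sum(counts)
  expected <- (1 / (1:(n - 1))) / sum(1 / (1:(n - 1)))
  expect_lt(max(abs(props - expected)), 0.03)
})

test_that("two-deme island model: mean Fst near 1/(1 + 16 N m)", {
  N <- 1000; m_rate <- 2.5e-4
  mdl <- island2(N = N, m = m_rate)
  nd <- null_distribution(mdl, c(a = 8, b = 8), n_reps = 250, seed = 105)
  theory <- 1 / (1 + 16 * N * m_rate)     # = 0.2 for these parameters
  se <- sd(nd, na.rm = TRUE) / sqrt(sum(!is.na(nd)))
  expect_lt(abs(mean(nd, na.rm = TRUE) - theory), max(4 * se, 0.04))
})

test_that("mean null Fst decreases monotonically with migration rate", {
  N <- 1000
  means <- vapply(c(1e-4, 5e-4, 2.5e-3), function(mr) {
    nd <- null_distribution(island2(N = N, m = mr), c(a = 8, b = 8),
                            n_reps = 150, seed = 106)
    mean(nd, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("deep split with no migration pushes Fst towards 1", {
  mdl <- demographic_model(
    data.frame(name = c("a", "b"), size = c(200, 200)),
    splits = data.frame(time = 40000, derived = "a", ancestral = "b"),
    mu = 1e-6, window_length = 20000L, blocks = 4L)
  nd <- null_distribution(mdl, c(a = 8, b = 8), n_reps = 40, seed = 107)
  expect_gt(mean(nd, na.rm = TRUE), 0.9)
})

test_that("a panmictic pair of labels shows no differentiation on average", {
  mdl <- suppressWarnings(demographic_model(
    data.frame(name = c("a", "b"), size = c(1000, 1000)),
    migration = data.frame(from = c("a", "b"), to = c("b", "a"),
                           rate = c(0.5, 0.5)),   # effectively one deme
    mu = 1e-6, window_length = 20000L, blocks = 4L))
  nd <- suppressWarnings(
    null_distribution(mdl, c(a = 10, b = 10), n_reps = 150, seed = 108))
  se <- sd(nd, na.rm = TRUE) / sqrt(sum(!is.na(nd)))
  expect_lt(abs(mean(nd, na.rm = TRUE)), 4 * se + 0.01)
})

test_that("isolated demes with no events are a fatal model error", {
  mdl <- suppressWarnings(demographic_model(
    data.frame(name = c("a", "b"), size = c(100, 100)),
    mu = 1e-8, window_length = 1000L, blocks = 1L))
  set.seed(109)
  expect_error(simulate_window(mdl, c(a = 2, b = 2)), "stranded")
})

test_that("simulation is deterministic given the seed", {
  mdl <- island2()
  w1 <- simulate_window(mdl, c(a = 4, b = 4), seed = 42)
  w2 <- simulate_window(mdl, c(a = 4, b = 4), seed = 42)
  expect_identical(w1, w2)
  n1 <- null_distribution(mdl, c(a = 4, b = 4), n_reps = 20, seed = 9)
  n2 <- null_distribution(mdl, c(a = 4, b = 4), n_reps = 20, seed = 9)
  expect_identical(n1, n2)
  expect_length(n1, 20L)
})

test_that("haplotype pooling yields correct diploid counts and contracts", {
  mdl <- island2(mu = 1e-6)
  w <- simulate_window(mdl, c(a = 134, b = 14), seed = 21)
  g <- haplotypes_to_genotypes(w)
  expect_equal(attr(g, "pop_sizes"), c(67L, 7L))
  expect_equal(attr(g, "populations"), c("a", "b"))
  # infinite sites: every column segregating, never all-derived
  dac <- colSums(w$haplotypes)
  expect_true(all(dac >= 1 & dac < nrow(w$haplotypes)))
  # counts consistent with haplotypes at every site
  expect_equal(2 * g$hom_alt_1 + g$het_1,
               unname(colSums(w$haplotypes[w$pop == "a", , drop = FALSE])))
  expect_error(haplotypes_to_genotypes(
    simulate_window(mdl, c(a = 3, b = 4), seed = 2)), "odd")
  # a (0,1) haplotype pair at a site is one het
  w2 <- simulate_window(mdl, c(a = 2, b = 2), seed = 33)
  if (length(w2$positions) > 0) {
    g2 <- haplotypes_to_genotypes(w2)
    ha <- w2$haplotypes[w2$pop == "a", , drop = FALSE]
    expect_equal(g2$het_1, as.integer(colSums(ha) == 1))
  }
})

test_that("simulated windows agree with an independent coalescent simulator", {
  # msprime run with matched parameters as the external oracle
  skip_if(Sys.which("python") == "", "python not on PATH")
  N <- 1000; m_rate <- 2.5e-4; mu <- 1e-7; L <- 20000
  py <- sprintf(
    "import msprime, random\nimport statistics\nvals=[]\nfor rep in range(150):\n    dem = msprime.Demography()\n    dem.add_population(name='a', initial_size=%d)\n    dem.add_population(name='b', initial_size=%d)\n    dem.set_migration_rate('a','b',%g)\n    dem.set_migration_rate('b','a',%g)\n    ts = msprime.sim_ancestry(samples={'a':4,'b':4}, demography=dem, sequence_length=%d, ploidy=2, random_seed=rep+1)\n    mts = msprime.sim_mutations(ts, rate=%g, random_seed=rep+1000, discrete_genome=False)\n    import numpy as np\n    G = mts.genotype_matrix()\n    vals.append(G.shape[0])\nprint(statistics.mean(vals))\n",
    N, N, m_rate, m_rate, L, mu)
  f <- tempfile(fileext = ".py")
  writeLines(py, f)
  out <- suppressWarnings(system2("python", f, stdout = TRUE, stderr = TRUE))
  skip_if(length(out) == 0 || is.na(suppressWarnings(
    as.numeric(out[length(out)]))), "msprime unavailable")
  ms_sites <- as.numeric(out[length(out)])
  mdl <- island2(N = N, m = m_rate, mu = mu, L = L, blocks = 5L)
  set.seed(110)
  my_sites <- mean(replicate(150, length(simulate_window(
    mdl, c(a = 8, b = 8))$positions)))
  # segregating-site counts from the two engines within 10 %
  expect_lt(abs(my_sites - ms_sites) / ms_sites, 0.10)
})

test_that("empirical exceedance uses the +1 correction and reports the gap", {
  w <- data.frame(chrom = "c", start = c(1, 501), end = c(500, 1000),
                  n_sites = 10, mean_fst = c(0.05, 0.5),
                  wmean_fst = c(0.05, 0.5), z_fst = c(-1, 6),
                  outlier = c(FALSE, TRUE))
  null <- seq(0.1, 0.31, length.out = 100)
  ex <- empirical_exceedance(w, null)
  expect_equal(ex$per_window$p_empirical[1], 1, tolerance = 0.01)
  expect_equal(ex$per_window$p_empirical[2], 1 / 101)
  expect_equal(ex$max_null, 0.31)
  expect_equal(ex$min_outlier, 0.5)
  expect_gt(ex$gap, 0)
})

test_that("the YAML demography config round-trips into a model", {
  path <- system.file("extdata/demography_dog_wolf.yaml",
                      package = "canidscan")
  mdl <- read_demographic_model(path)
  expect_s3_class(mdl, "demographic_model")
  expect_setequal(mdl$populations$name, c("dog", "wolf"))
  # dog bottleneck size within the documented 700-3,200 range
  expect_gte(mdl$populations$size[mdl$populations$name == "dog"], 700)
  expect_lte(mdl$populations$size[mdl$populations$name == "dog"], 3200)
  expect_equal(mdl$blocks, 50L)
})
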