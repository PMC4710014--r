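#' Build a two-or-more-deme demographic model
#'
#' Defines the demography driving the structured-coalescent engine: demes
#' with diploid sizes, split events (a derived deme merging into its
#' parent, backwards in time), stepwise size changes, and per-pair
#' migration rates. Time is in generations before present; migration is
#' defined backwards in time (the rate at which a lineage currently in
#' `from` traces its ancestry to `to`), the standard coalescent
#' convention. Mutations occur at `mu` per bp per generation under the
#' infinite-sites model. A window of `window_length` bp is simulated as
#' `blocks` independent non-recombining segments, a cheap stand-in for
#' intra-window recombination that preserves its variance-reduction
#' effect on window-mean Fst.
#'
#' @param populations Data.frame with columns `name`, `size` (diploid N).
#' @param splits Optional data.frame `time`, `derived`, `ancestral`.
#' @param size_changes Optional data.frame `time`, `population`, `size`.
#' @param migration Optional data.frame `from`, `to`, `rate`.
#' @param migration_changes Optional data.frame `time`, `from`, `to`,
#'   `rate` (rate replacing the previous value from `time` backwards).
#' @param mu Mutation rate per bp per generation.
#' @param window_length Window length in bp.
#' @param blocks Number of independent non-recombining blocks per window.
#' @return A `demographic_model` object.
#' @export
demographic_model <- function(populations, splits = NULL,
                              size_changes = NULL, migration = NULL,
                              migration_changes = NULL, mu = 1e-8,
                              window_length = 500000L, blocks = 50L) {
  stopifnot(is.data.frame(populations),
            all(c("name", "size") %in% names(populations)),
            all(populations$size > 0), mu >= 0, window_length >= 1,
            blocks >= 1)
  pops <- populations$name
  chk_pop <- function(x) if (!all(x %in% pops))
    stop("unknown population(s): ", paste(setdiff(x, pops), collapse = ", "))
  if (!is.null(splits)) {
    stopifnot(all(c("time", "derived", "ancestral") %in% names(splits)))
    chk_pop(c(splits$derived, splits$ancestral))
    if (any(splits$time <= 0)) stop("split times must be positive")
    if (anyDuplicated(splits$time)) stop("split times must be strictly ordered")
    splits <- splits[order(splits$time), ]
  }
  if (!is.null(size_changes)) {
    stopifnot(all(c("time", "population", "size") %in% names(size_changes)))
    chk_pop(size_changes$population)
    stopifnot(all(size_changes$size > 0), all(size_changes$time >= 0))
  }
  if (!is.null(migration)) {
    stopifnot(all(c("from", "to", "rate") %in% names(migration)))
    chk_pop(c(migration$from, migration$to))
    stopifnot(all(migration$rate >= 0))
  }
  if (!is.null(migration_changes)) {
    stopifnot(all(c("time", "from", "to", "rate") %in%
                    names(migration_changes)))
    chk_pop(c(migration_changes$from, migration_changes$to))
    stopifnot(all(migration_changes$rate >= 0),
              all(migration_changes$time >= 0))
  }
  if (length(pops) > 1) {
    # all demes must eventually merge into one ancestral deme
    if (is.null(splits) || nrow(splits) != length(pops) - 1)
      warning("with ", length(pops), " demes, ", length(pops) - 1,
              " split events are expected for a single root; lineages may ",
              "strand if demes never merge and migration is absent")
  }
  structure(list(populations = populations, splits = splits,
                 size_changes = size_changes, migration = migration,
                 migration_changes = migration_changes, mu = mu,
                 window_length = as.integer(window_length),
                 blocks = as.integer(blocks)),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("demographic model:", nrow(x$populations), "deme(s) [",
      paste(sprintf("%s N=%d", x$populations$name, x$populations$size),
            collapse = ", "), "]",
      if (!is.null(x$splits)) sprintf("; %d split(s)", nrow(x$splits)) else "",
      sprintf("; mu=%g, window=%d bp, blocks=%d", x$mu, x$window_length,
              x$blocks), "\n", sep = "")
  invisible(x)
}

#' Read a demographic model from a YAML config
#'
#' Schema: top-level keys `populations` (list of `{name, size}`),
#' optional `splits` (list of `{time, derived, ancestral}`),
#' `size_changes` (list of `{time, population, size}`), `migration`
#' (list of `{from, to, rate}`), `migration_changes`, and scalars `mu`,
#' `window_length`, `blocks`. See
#' `system.file("extdata/demography_dog_wolf.yaml", package = "canidscan")`
#' for an annotated example.
#'
#' @param path Path to the YAML file.
#' @return A `demographic_model`.
#' @export
read_demographic_model <- function(path) {
  y <- yaml::read_yaml(path)
  df <- function(x) if (is.null(x)) NULL else
    do.call(rbind, lapply(x, function(e) as.data.frame(e)))
  demographic_model(populations = df(y$populations), splits = df(y$splits),
                    size_changes = df(y$size_changes),
                    migration = df(y$migration),
                    migration_changes = df(y$migration_changes),
                    mu = if (is.null(y$mu)) 1e-8 else y$mu,
                    window_length = if (is.null(y$window_length)) 500000L
                                    else y$window_length,
                    blocks = if (is.null(y$blocks)) 50L else y$blocks)
}

# ---- engine -----------------------------------------------------------

# Assemble the backwards-time event schedule from a model.
event_schedule <- function(model) {
  ev <- list()
  add <- function(time, kind, payload)
    ev[[length(ev) + 1L]] <<- list(time = time, kind = kind,
                                   payload = payload)
  if (!is.null(model$splits))
    for (i in seq_len(nrow(model$splits)))
      add(model$splits$time[i], "split", model$splits[i, ])
  if (!is.null(model$size_changes))
    for (i in seq_len(nrow(model$size_changes)))
      add(model$size_changes$time[i], "size", model$size_changes[i, ])
  if (!is.null(model$migration_changes))
    for (i in seq_len(nrow(model$migration_changes)))
      add(model$migration_changes$time[i], "migration",
          model$migration_changes[i, ])
  ev[order(vapply(ev, `[[`, 0, "time"))]
}

# Simulate one genealogy of the lineages in `deme0` (character labels)
# under the structured coalescent. Returns parent pointers and node times
# (nodes 1..n are leaves; 2n-1 is created last and is the root when all
# lineages coalesce).
sim_genealogy <- function(model, deme0) {
  n <- length(deme0)
  pops <- model$populations$name
  N <- stats::setNames(model$populations$size, pops)
  mig <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  if (!is.null(model$migration))
    for (i in seq_len(nrow(model$migration)))
      mig[model$migration$from[i], model$migration$to[i]] <-
        model$migration$rate[i]
  events <- event_schedule(model)
  ei <- 1L

  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  node_time <- numeric(n_nodes)
  active <- seq_len(n)            # node ids of live lineages
  deme <- deme0                   # parallel to active
  nxt <- n + 1L
  t <- 0

  repeat {
    if (length(active) == 1L) break
    k <- as.numeric(table(factor(deme, levels = pops)))
    coal_rate <- ifelse(k > 1, k * (k - 1) / (4 * N[pops]), 0)
    mig_rate <- k * mig                      # row i: lineages in deme i
    total <- sum(coal_rate) + sum(mig_rate)
    t_next_ev <- if (ei <= length(events)) events[[ei]]$time else Inf
    if (total <= 0) {
      if (!is.finite(t_next_ev))
        stop("lineages stranded in isolated demes with no further ",
             "demographic events: model misspecified")
      t <- t_next_ev
    } else {
      dt <- stats::rexp(1, total)
      t_prop <- t + dt
      if (t_prop >= t_next_ev) {
        t <- t_next_ev
      } else {
        t <- t_prop
        # choose event type
        u <- stats::runif(1, 0, total)
        cum <- cumsum(c(coal_rate, as.numeric(mig_rate)))
        pick <- which(u <= cum)[1]
        if (is.na(pick)) pick <- length(cum)
        if (pick <= length(pops)) {        # coalescence in deme `pick`
          d <- pops[pick]
          here <- which(deme == d)
          pair <- sample(here, 2L)
          node_time[nxt] <- t
          parent[active[pair]] <- nxt
          active <- c(active[-pair], nxt)
          deme <- c(deme[-pair], d)
          nxt <- nxt + 1L
        } else {                           # migration from deme i to j
          idx <- pick - length(pops) - 1L
          i_from <- idx %% length(pops) + 1L
          i_to <- idx %/% length(pops) + 1L
          here <- which(deme == pops[i_from])
          mv <- if (length(here) == 1L) here else sample(here, 1L)
          deme[mv] <- pops[i_to]
        }
        next
      }
    }
    # arrived exactly at a demographic event
    e <- events[[ei]]; ei <- ei + 1L
    if (e$kind == "split") {
      deme[deme == e$payload$derived] <- e$payload$ancestral
      mig[e$payload$derived, ] <- 0
      mig[, e$payload$derived] <- 0
      N[e$payload$derived] <- NA            # deme retired
    } else if (e$kind == "size") {
      N[e$payload$population] <- e$payload$size
    } else {
      mig[e$payload$from, e$payload$to] <- e$payload$rate
    }
  }
  list(parent = parent, time = node_time, n = n, tmrca = t)
}

# Leaf descendants of every node, children-before-parents.
leaf_sets <- function(parent, n) {
  n_nodes <- length(parent)
  desc <- vector("list", n_nodes)
  for (i in seq_len(n)) desc[[i]] <- i
  for (i in seq_len(n_nodes)) {           # internal node ids increase with time
    p <- parent[i]
    if (p > 0) desc[[p]] <- c(desc[[p]], desc[[i]])
  }
  desc
}

# Drop infinite-sites mutations on a genealogy: returns 0/1 haplotype
# columns and positions within [1, block_len].
drop_mutations <- function(gen, mu, block_len) {
  live <- which(gen$parent > 0)
  blen <- gen$time[gen$parent[live]] - gen$time[live]
  tl <- sum(blen)
  nmut <- stats::rpois(1, mu * block_len * tl)
  if (nmut == 0)
    return(list(haps = matrix(0L, gen$n, 0), pos = integer(0)))
  nmut <- min(nmut, block_len)            # infinite-sites within the block
  branch <- sample(live, nmut, replace = TRUE, prob = blen)
  pos <- sort(sample.int(block_len, nmut))
  desc <- leaf_sets(gen$parent, gen$n)
  haps <- matrix(0L, gen$n, nmut)
  for (j in seq_len(nmut)) haps[desc[[branch[j]]], j] <- 1L
  list(haps = haps, pos = pos)
}

#' Simulate one genomic window under the structured coalescent
#'
#' Simulates `blocks` independent genealogies for the sampled haplotypes,
#' drops Poisson infinite-sites mutations on each (rate
#' `mu * window_length / blocks` per generation of branch length), and
#' concatenates the blocks into one window. Deterministic given `seed`.
#'
#' @param model A `demographic_model`.
#' @param samples Named integer vector: haplotypes sampled per extant
#'   deme, e.g. `c(dog = 134, wolf = 14)`.
#' @param seed Optional integer seed (`NULL` leaves the RNG stream alone).
#' @return A `sim_window`: list with `haplotypes` (haplotype x site 0/1
#'   matrix), `positions` (1-based bp in the window), `pop` (deme label
#'   per haplotype) and `tmrca` (per-block TMRCAs, generations).
#' @export
simulate_window <- function(model, samples, seed = NULL) {
  stopifnot(all(samples >= 1),
            all(names(samples) %in% model$populations$name))
  if (!is.null(seed)) set.seed(seed)
  deme0 <- rep(names(samples), samples)
  n <- length(deme0)
  block_len <- model$window_length / model$blocks
  haps <- vector("list", model$blocks)
  pos <- vector("list", model$blocks)
  tmrca <- numeric(model$blocks)
  for (b in seq_len(model$blocks)) {
    gen <- sim_genealogy(model, deme0)
    m <- drop_mutations(gen, model$mu, floor(block_len))
    haps[[b]] <- m$haps
    pos[[b]] <- m$pos + as.integer((b - 1) * block_len)
    tmrca[b] <- gen$tmrca
  }
  structure(list(haplotypes = do.call(cbind, haps),
                 positions = unlist(pos), pop = deme0, samples = samples,
                 window_length = model$window_length, tmrca = tmrca),
            class = "sim_window")
}

#' Pool simulated haplotypes into diploid genotype counts
#'
#' Pairs consecutive haplotypes within each population into diploids and
#' tallies genotype counts per site, yielding the same `site_table`
#' contract as the empirical VCF path so that simulated windows flow
#' through the identical Fst machinery.
#'
#' @param window A `sim_window` from [simulate_window()].
#' @param chrom Chromosome label for the output rows.
#' @return A `site_table`.
#' @export
haplotypes_to_genotypes <- function(window, chrom = "sim") {
  if (any(window$samples %% 2 != 0))
    stop("odd haplotype count: cannot pair into diploids")
  pops <- names(window$samples)
  stopifnot(length(pops) == 2L)
  S <- length(window$positions)
  counts <- function(label) {
    rows <- which(window$pop == label)
    h <- window$haplotypes[rows, , drop = FALSE]
    odd <- seq(1, nrow(h), by = 2)
    dose <- h[odd, , drop = FALSE] + h[odd + 1, , drop = FALSE]
    list(hom_ref = colSums(dose == 0L), het = colSums(dose == 1L),
         hom_alt = colSums(dose == 2L))
  }
  c1 <- counts(pops[1]); c2 <- counts(pops[2])
  df <- data.frame(chrom = rep(chrom, S), pos = as.integer(window$positions),
                   ref = rep("A", S), alt = rep("T", S),
                   hom_ref_1 = c1$hom_ref, het_1 = c1$het,
                   hom_alt_1 = c1$hom_alt, miss_1 = 0L,
                   hom_ref_2 = c2$hom_ref, het_2 = c2$het,
                   hom_alt_2 = c2$hom_alt, miss_2 = 0L,
                   stringsAsFactors = FALSE)
  new_site_table(df, pops, as.integer(window$samples / 2))
}

#' Neutral null distribution of window-mean Fst
#'
#' Simulates `n_reps` windows under the model and computes each realized
#' window's mean per-site theta-hat through the same estimator path as
#' the empirical data ([fst_sites()] on pooled diploids). Reproducible
#' given `seed`.
#'
#' @inheritParams simulate_window
#' @param n_reps Number of replicate windows.
#' @param seed Integer seed.
#' @return Numeric vector of `n_reps` window-mean Fst values (`NA` for
#'   the rare window with no segregating sites).
#' @export
null_distribution <- function(model, samples, n_reps, seed = 1L) {
  stopifnot(n_reps >= 1)
  set.seed(seed)
  vapply(seq_len(n_reps), function(r) {
    w <- simulate_window(model, samples, seed = NULL)
    if (length(w$positions) == 0L) return(NA_real_)
    f <- fst_sites(haplotypes_to_genotypes(w))
    mean(f$fst, na.rm = TRUE)
  }, numeric(1))
}

#' Compare observed windows against a neutral null
#'
#' Per-window empirical p-value `(1 + #{null >= observed}) / (n + 1)`,
#' plus the headline comparison of the null maximum against the lowest
#' observed outlier-window mean.
#'
#' @param windows Data.frame from [window_scan()] (needs `mean_fst`,
#'   `outlier`).
#' @param null Numeric vector of null window-mean Fst values.
#' @return List with `per_window` (windows + `p_empirical`), `max_null`,
#'   `min_outlier` (NA if no outliers) and `gap`
#'   (`min_outlier - max_null`).
#' @export
empirical_exceedance <- function(windows, null) {
  null <- null[!is.na(null)]
  stopifnot(length(null) > 0)
  p <- vapply(windows$mean_fst, function(x) {
    if (is.na(x)) return(NA_real_)
    (1 + sum(null >= x)) / (length(null) + 1)
  }, numeric(1))
  windows$p_empirical <- p
  min_outlier <- if (any(windows$outlier, na.rm = TRUE))
    min(windows$mean_fst[windows$outlier], na.rm = TRUE) else NA_real_
  list(per_window = windows, max_null = max(null),
       min_outlier = min_outlier, gap = min_outlier - max(null))
}
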