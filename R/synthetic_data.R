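#' Default illustrative dog/wolf demography
#'
#' Two demes: a domesticated deme with a strong post-split bottleneck
#' (N in the low thousands, matching published estimates for the ancestral
#' dog population) and a larger wild deme, splitting from a common
#' ancestral population with weak symmetric migration. Labelled
#' illustrative: the published model's exact parameters are not
#' reproduced, only its structure (split + bottleneck + migration).
#'
#' @param window_length Window length in bp.
#' @param blocks Non-recombining blocks per window.
#' @return A `demographic_model`.
#' @export
default_dog_wolf_model <- function(window_length = 500000L, blocks = 50L) {
  demographic_model(
    populations = data.frame(name = c("dog", "wolf"),
                             size = c(2500L, 10000L)),
    splits = data.frame(time = 3000, derived = "dog", ancestral = "wolf"),
    size_changes = data.frame(time = 3000, population = "wolf",
                              size = 15000L),
    migration = data.frame(from = c("dog", "wolf"), to = c("wolf", "dog"),
                           rate = c(1e-4, 1e-4)),
    mu = 1e-8, window_length = window_length, blocks = blocks)
}

#' Configuration for a ground-truthed synthetic dataset
#'
#' Defines the study conditions the generator emulates: a toy diploid
#' genome with annotated genes, two populations sampled at the study's
#' sizes (67 + 7 diploids), background polymorphism from the coalescent
#' engine (or a fast i.i.d. Balding-Nichols mode for unit tests), injected
#' high-divergence sweep windows, planted fixed functional variants placed
#' at CDS/UTR/splice positions, per-site missing genotypes, and a pathway
#' table with one enriched pathway.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#'   Default 2 x 20 Mb: 80 windows of 500 kb, enough windows that a
#'   genuine sweep can exceed the Z >= 5 rule (the maximum attainable Z
#'   with K windows is about sqrt(K)).
#' @param n_pop1,n_pop2 Diploid sample sizes (default 67 dogs, 7 wolves).
#' @param populations The two population labels.
#' @param window_size Scan window width in bp.
#' @param background `"coalescent"` (realistic frequency spectra) or
#'   `"iid"` (fast Balding-Nichols draws).
#' @param model Demographic model for the coalescent background
#'   (default [default_dog_wolf_model()]).
#' @param iid_sites_per_window,iid_fst Site count and differentiation
#'   level for the i.i.d. mode.
#' @param sweep_windows Data.frame `chrom`, `start` (1-based window
#'   starts) of injected sweeps; `NULL` for none.
#' @param sweep_beta Shape of the minor-frequency Beta(1, sweep_beta)
#'   draw inside sweeps; larger = stronger divergence.
#' @param planted_variants Character vector of consequence labels to
#'   plant as fixed differences, one gene each (default covers every
#'   reachable category plus synonymous and intronic controls).
#' @param missing_rate Per-genotype missing probability at background
#'   sites (planted sites stay fully called).
#' @param pathway_background_size Total background gene-list size
#'   (toy genes plus filler ids).
#' @param n_pathways,pathway_size Decoy pathway count and size.
#' @param enriched_size Size of the planted enriched pathway.
#' @param seed Integer seed; the bundle is byte-identical given the seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(chrom_lengths = c(chr1 = 20000000L,
                                               chr2 = 20000000L),
                             n_pop1 = 67L, n_pop2 = 7L,
                             populations = c("dog", "wolf"),
                             window_size = 500000L,
                             background = c("coalescent", "iid"),
                             model = NULL,
                             iid_sites_per_window = 250L, iid_fst = 0.14,
                             sweep_windows = data.frame(
                               chrom = c("chr1", "chr2"),
                               start = c(2500001L, 10000001L)),
                             sweep_beta = 19,
                             planted_variants = c("missense", "missense",
                                                  "stop_gained", "stop_lost",
                                                  "five_prime_utr",
                                                  "three_prime_utr",
                                                  "three_prime_utr",
                                                  "splice_region",
                                                  "synonymous", "intronic"),
                             missing_rate = 0.05,
                             pathway_background_size = 2000L,
                             n_pathways = 8L, pathway_size = 25L,
                             enriched_size = 10L, seed = 1L) {
  background <- match.arg(background)
  if (is.null(model))
    model <- default_dog_wolf_model(window_length = window_size)
  if (!is.null(sweep_windows)) {
    stopifnot(all(sweep_windows$chrom %in% names(chrom_lengths)),
              all((sweep_windows$start - 1L) %% window_size == 0),
              all(sweep_windows$start <=
                    chrom_lengths[sweep_windows$chrom]))
  }
  stopifnot(missing_rate >= 0, missing_rate <= 1)
  structure(list(chrom_lengths = chrom_lengths, n_pop1 = n_pop1,
                 n_pop2 = n_pop2, populations = populations,
                 window_size = as.integer(window_size),
                 background = background, model = model,
                 iid_sites_per_window = iid_sites_per_window,
                 iid_fst = iid_fst, sweep_windows = sweep_windows,
                 sweep_beta = sweep_beta,
                 planted_variants = planted_variants,
                 missing_rate = missing_rate,
                 pathway_background_size = pathway_background_size,
                 n_pathways = n_pathways, pathway_size = pathway_size,
                 enriched_size = enriched_size, seed = as.integer(seed)),
            class = "synthetic_config")
}

# --- toy gene layout ---------------------------------------------------
# Each gene: 3 exons; CDS of 300 bp split 100/100/100 across exons;
# 100 bp 5'-UTR and 150 bp 3'-UTR; 500 bp introns. Alternating strand.
# Offsets are relative to the gene start (span 1550 bp).
TOY_GENE <- list(
  span = 1550L,
  exons = rbind(c(0L, 199L), c(700L, 799L), c(1300L, 1549L)),
  cds = rbind(c(100L, 199L), c(700L, 799L), c(1300L, 1399L)),
  utr_lo = rbind(c(0L, 99L)),       # low-coordinate UTR (5' on +, 3' on -)
  utr_hi = rbind(c(1400L, 1549L)))  # high-coordinate UTR

place_genes <- function(chrom_lengths, n_genes) {
  per <- ceiling(n_genes / length(chrom_lengths))
  out <- list()
  i <- 0L
  for (chrom in names(chrom_lengths)) {
    len <- chrom_lengths[[chrom]]
    # evenly spaced gene starts, clear of chromosome edges
    starts <- as.integer(round(seq(len * 0.05, len * 0.95 - TOY_GENE$span,
                                   length.out = per)))
    for (s in starts) {
      i <- i + 1L
      if (i > n_genes) break
      out[[i]] <- list(gene_id = sprintf("GENE%03d", i),
                       tx_id = sprintf("TX%03d", i), chrom = chrom,
                       start = s, strand = if (i %% 2 == 1) "+" else "-")
    }
  }
  out
}

NON_STOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                           c("TAA", "TAG", "TGA"))

# Long pseudo-random DNA assembled from 1 kb chunks (exact base-level
# randomness is irrelevant here: gene bodies are overwritten with real
# codons and only planted/queried bases are ever read back).
random_dna <- function(len) {
  pool <- vapply(seq_len(64L), function(i)
    paste(sample(c("A", "C", "G", "T"), 1000L, replace = TRUE),
          collapse = ""), character(1))
  n_chunks <- ceiling(len / 1000L)
  s <- paste(sample(pool, n_chunks, replace = TRUE), collapse = "")
  substr(s, 1L, len)
}

revcomp <- function(x) {
  paste(rev(unname(COMPLEMENT[strsplit(x, "")[[1]]])), collapse = "")
}

# Write the coding sequence of a toy gene into the chromosome string,
# returning the modified sequence. CDS reads ATG ... TAA in transcript
# orientation; middle codons avoid stops so stop_lost is only reachable
# at the terminal codon.
imprint_gene <- function(seqchar, gene) {
  n_codons <- 100L
  codons <- c("ATG", sample(NON_STOP_CODONS, n_codons - 2L, replace = TRUE),
              "TAA")
  cds_seq <- paste(codons, collapse = "")
  if (gene$strand == "-") cds_seq <- revcomp(cds_seq)
  offs <- TOY_GENE$cds
  at <- 1L
  for (k in seq_len(nrow(offs))) {
    lo <- gene$start + offs[k, 1]; hi <- gene$start + offs[k, 2]
    w <- hi - lo + 1L
    substr(seqchar, lo, hi) <- substr(cds_seq, at, at + w - 1L)
    at <- at + w
  }
  seqchar
}

gene_intervals <- function(gene) {
  shift <- function(m) cbind(start = gene$start + m[, 1],
                             end = gene$start + m[, 2])
  utr5 <- if (gene$strand == "+") TOY_GENE$utr_lo else TOY_GENE$utr_hi
  utr3 <- if (gene$strand == "+") TOY_GENE$utr_hi else TOY_GENE$utr_lo
  list(exons = shift(TOY_GENE$exons), cds = shift(TOY_GENE$cds),
       utr5 = shift(utr5), utr3 = shift(utr3))
}

# genomic CDS positions in transcript order for a toy gene
toy_cds_positions <- function(gene) {
  iv <- gene_intervals(gene)$cds
  pos <- unlist(lapply(seq_len(nrow(iv)), function(k) iv[k, 1]:iv[k, 2]))
  if (gene$strand == "-") rev(pos) else pos
}

# Pick a position and alt allele inside `gene` realising `consequence`.
# Codon arithmetic is done directly from the genetic code here, so the
# generator does not depend on the classifier it is meant to test.
plant_site <- function(gene, consequence, seqchar) {
  iv <- gene_intervals(gene)
  gc <- Biostrings::GENETIC_CODE
  base_at <- function(p) substr(seqchar, p, p)
  if (consequence %in% c("missense", "synonymous", "stop_gained",
                         "stop_lost")) {
    cpos <- toy_cds_positions(gene)
    codon_ids <- if (consequence == "stop_lost") 100L else
      sample(2:99, 98L)           # keep ATG start intact
    for (ci in codon_ids) {
      p3 <- cpos[(ci - 1L) * 3L + 1:3]
      codon <- vapply(p3, base_at, character(1))
      if (gene$strand == "-") codon <- unname(COMPLEMENT[codon])
      for (within in sample(1:3)) {
        for (nt in sample(setdiff(c("A", "C", "G", "T"), codon[within]))) {
          alt_codon <- codon; alt_codon[within] <- nt
          ar <- gc[[paste(codon, collapse = "")]]
          aa <- gc[[paste(alt_codon, collapse = "")]]
          hit <- switch(consequence,
            missense = ar != "*" && aa != "*" && ar != aa,
            synonymous = ar == aa,
            stop_gained = ar != "*" && aa == "*",
            stop_lost = ar == "*" && aa != "*")
          if (hit) {
            gpos <- p3[within]
            galt <- if (gene$strand == "-") unname(COMPLEMENT[nt]) else nt
            # steer clear of splice zones (3 bp from any exon edge)
            edges <- as.vector(iv$exons)
            if (min(abs(gpos - edges)) > 3) {
              return(list(pos = gpos, ref = base_at(gpos), alt = galt))
            }
          }
        }
      }
    }
    stop("could not plant ", consequence, " in ", gene$gene_id)
  }
  pick_in <- function(ivm, inset = 10L) {
    p <- sample((ivm[1, 1] + inset):(ivm[1, 2] - inset), 1L)
    ref <- base_at(p)
    list(pos = p, ref = ref,
         alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1L))
  }
  switch(consequence,
    five_prime_utr = pick_in(iv$utr5),
    three_prime_utr = pick_in(iv$utr3),
    splice_region = {
      # 5 bp into the first intron from the donor-side exon edge
      p <- iv$exons[1, 2] + 5L
      ref <- base_at(p)
      list(pos = p, ref = ref,
           alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1L))
    },
    intronic = {
      # deep intron: > 8 bp from both junctions
      p <- iv$exons[1, 2] + 250L
      ref <- base_at(p)
      list(pos = p, ref = ref,
           alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1L))
    },
    stop("unknown planted consequence: ", consequence))
}

#' Simulate background genotype counts for a synthetic genome
#'
#' Generates the per-site genotype counts of a `synthetic_config`'s
#' background polymorphism — coalescent windows or i.i.d. Balding-Nichols
#' draws — including any configured sweep injection, without touching the
#' file system. Used internally by [generate_dataset()] and directly for
#' scan-calibration studies (e.g. the false-positive rate of the Z rule
#' on sweep-free genomes).
#'
#' @param config A `synthetic_config`.
#' @param seed Optional seed (`NULL` leaves the RNG stream alone).
#' @return A `site_table` (ref/alt alleles are placeholders until
#'   [generate_dataset()] fills them from the reference sequence).
#' @export
simulate_background_sites <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n1 <- config$n_pop1; n2 <- config$n_pop2
  pops <- config$populations
  wsize <- config$window_size
  bg <- list()
  for (chrom in names(config$chrom_lengths)) {
    n_win <- config$chrom_lengths[[chrom]] %/% wsize
    for (w in seq_len(n_win)) {
      offset <- (w - 1L) * wsize
      if (config$background == "coalescent") {
        sw <- simulate_window(config$model,
                              stats::setNames(c(2L * n1, 2L * n2), pops))
        tab <- haplotypes_to_genotypes(sw, chrom = chrom)
        tab$pos <- tab$pos + offset
      } else {
        S <- config$iid_sites_per_window
        F <- config$iid_fst
        pa <- stats::rbeta(S, 2, 2)
        shape <- (1 - F) / F
        p1 <- stats::rbeta(S, pa * shape, (1 - pa) * shape)
        p2 <- stats::rbeta(S, pa * shape, (1 - pa) * shape)
        c1 <- bn_counts(p1, n1); c2 <- bn_counts(p2, n2)
        tab <- data.frame(chrom = chrom,
                          pos = sort(sample.int(wsize, S)) + offset,
                          ref = "N", alt = "N",
                          hom_ref_1 = c1$hom_ref, het_1 = c1$het,
                          hom_alt_1 = c1$hom_alt, miss_1 = 0L,
                          hom_ref_2 = c2$hom_ref, het_2 = c2$het,
                          hom_alt_2 = c2$hom_alt, miss_2 = 0L,
                          stringsAsFactors = FALSE)
      }
      # sweep injection: replace frequencies with strongly diverged ones
      is_sweep <- !is.null(config$sweep_windows) &&
        any(config$sweep_windows$chrom == chrom &
              config$sweep_windows$start == offset + 1L)
      if (is_sweep && nrow(tab) > 0) {
        e1 <- stats::rbeta(nrow(tab), 1, config$sweep_beta)
        e2 <- stats::rbeta(nrow(tab), 1, config$sweep_beta)
        c1 <- bn_counts(1 - e1, n1); c2 <- bn_counts(e2, n2)
        tab$hom_ref_1 <- c1$hom_ref; tab$het_1 <- c1$het
        tab$hom_alt_1 <- c1$hom_alt
        tab$hom_ref_2 <- c2$hom_ref; tab$het_2 <- c2$het
        tab$hom_alt_2 <- c2$hom_alt
      }
      bg[[length(bg) + 1L]] <- tab
    }
  }
  bg <- do.call(rbind, bg)
  rownames(bg) <- NULL
  new_site_table(bg, pops, c(n1, n2))
}

# Balding-Nichols genotype-count draw for one population at many sites.
bn_counts <- function(p_pop, n) {
  dose <- vapply(p_pop, function(p) {
    g <- stats::rbinom(n, 2L, p)
    c(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, numeric(3))
  list(hom_ref = dose[1, ], het = dose[2, ], hom_alt = dose[3, ])
}

#' Generate a ground-truthed synthetic dataset bundle
#'
#' Writes a complete analysis input set to `dir`: a multi-sample VCF of
#' biallelic SNPs (with per-site missingness), a GFF3 of toy gene models,
#' the reference FASTA, a sample/population map, a pathway membership
#' table plus background gene list, and a truth table listing every
#' planted sweep window, fixed functional variant, and the enriched
#' pathway. Deterministic given `config$seed`.
#'
#' @param config A `synthetic_config`.
#' @param dir Output directory (created if needed).
#' @return List with the file paths (`vcf`, `gff3`, `fasta`, `popmap`,
#'   `pathways`, `background`, `truth`) and the `truth` data.frame.
#' @export
generate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  n1 <- config$n_pop1; n2 <- config$n_pop2
  pops <- config$populations
  wsize <- config$window_size

  # genome + genes; a couple of non-planted genes are relocated into each
  # sweep window so sweeps also carry genic (functional) divergent sites
  genes <- place_genes(config$chrom_lengths, n_genes = 20L)
  if (!is.null(config$sweep_windows)) {
    movable <- setdiff(seq_along(genes),
                       seq_along(config$planted_variants))
    for (s in seq_len(nrow(config$sweep_windows))) {
      for (j in 1:2) {
        if (length(movable) == 0L) break
        gi <- movable[length(movable)]
        movable <- movable[-length(movable)]
        genes[[gi]]$chrom <- config$sweep_windows$chrom[s]
        genes[[gi]]$start <- config$sweep_windows$start[s] +
          c(100000L, 300000L)[j]
      }
    }
  }
  seqs <- lapply(names(config$chrom_lengths), function(chrom) {
    s <- random_dna(config$chrom_lengths[[chrom]])
    for (g in genes) if (g$chrom == chrom) s <- imprint_gene(s, g)
    s
  })
  names(seqs) <- names(config$chrom_lengths)

  truth <- list()
  planted <- list()

  # planted fixed variants: one distinct gene per entry
  if (length(config$planted_variants) > 0) {
    stopifnot(length(config$planted_variants) <= length(genes))
    for (i in seq_along(config$planted_variants)) {
      cons <- config$planted_variants[i]
      g <- genes[[i]]
      site <- plant_site(g, cons, seqs[[g$chrom]])
      planted[[i]] <- data.frame(
        chrom = g$chrom, pos = site$pos, ref = site$ref, alt = site$alt,
        hom_ref_1 = 0L, het_1 = 0L, hom_alt_1 = n1, miss_1 = 0L,
        hom_ref_2 = n2, het_2 = 0L, hom_alt_2 = 0L, miss_2 = 0L,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        type = "fixed_variant", chrom = g$chrom, start = site$pos,
        end = site$pos, gene = g$gene_id, consequence = cons,
        ref = site$ref, alt = site$alt, pathway = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  planted <- if (length(planted)) do.call(rbind, planted) else NULL

  # background variation per window, with sweep injection
  bg <- as.data.frame(simulate_background_sites(config))
  bg$call_1 <- NULL; bg$call_2 <- NULL
  if (!is.null(config$sweep_windows))
    for (s in seq_len(nrow(config$sweep_windows)))
      truth[[length(truth) + 1L]] <- data.frame(
        type = "sweep_window", chrom = config$sweep_windows$chrom[s],
        start = config$sweep_windows$start[s],
        end = config$sweep_windows$start[s] + wsize - 1L,
        gene = NA_character_, consequence = NA_character_,
        ref = NA_character_, alt = NA_character_,
        pathway = NA_character_, stringsAsFactors = FALSE)

  # missingness on background sites: remove m genotypes per site uniformly
  # without replacement across the three classes (multivariate
  # hypergeometric, drawn class by class with vectorised rhyper)
  if (config$missing_rate > 0 && nrow(bg) > 0) {
    S <- nrow(bg)
    knock_out <- function(hr, he, ha, n, m) {
      g_hr <- stats::rhyper(S, hr, he + ha, m)
      g_he <- stats::rhyper(S, he, ha, m - g_hr)
      g_ha <- m - g_hr - g_he
      list(hr = hr - g_hr, he = he - g_he, ha = ha - g_ha, miss = m)
    }
    m1 <- stats::rbinom(S, n1, config$missing_rate)
    m2 <- stats::rbinom(S, n2, config$missing_rate)
    k1 <- knock_out(bg$hom_ref_1, bg$het_1, bg$hom_alt_1, n1, m1)
    bg$hom_ref_1 <- k1$hr; bg$het_1 <- k1$he
    bg$hom_alt_1 <- k1$ha; bg$miss_1 <- k1$miss
    k2 <- knock_out(bg$hom_ref_2, bg$het_2, bg$hom_alt_2, n2, m2)
    bg$hom_ref_2 <- k2$hr; bg$het_2 <- k2$he
    bg$hom_alt_2 <- k2$ha; bg$miss_2 <- k2$miss
  }

  # drop background collisions with planted positions; fill ref/alt
  if (!is.null(planted)) {
    key <- paste(bg$chrom, bg$pos)
    bg <- bg[!key %in% paste(planted$chrom, planted$pos), ]
  }
  base_at <- function(chrom, p) substr(seqs[[chrom]], p, p)
  bg$ref <- mapply(base_at, bg$chrom, bg$pos)
  bg$alt <- vapply(bg$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))

  all_sites <- rbind(bg, planted)
  all_sites <- all_sites[order(all_sites$chrom, all_sites$pos), ]
  sites <- new_site_table(all_sites, pops, c(n1, n2))

  # file outputs
  paths <- list(vcf = file.path(dir, "variants.vcf"),
                gff3 = file.path(dir, "genes.gff3"),
                fasta = file.path(dir, "genome.fa"),
                popmap = file.path(dir, "popmap.tsv"),
                pathways = file.path(dir, "pathways.tsv"),
                background = file.path(dir, "background_genes.txt"),
                truth_path = file.path(dir, "truth.tsv"))
  sample_names <- c(paste0(pops[1], seq_len(n1)), paste0(pops[2], seq_len(n2)))
  write_sites_vcf(sites, paths$vcf, sample_names = sample_names)
  utils::write.table(data.frame(sample = sample_names,
                                population = rep(pops, c(n1, n2))),
                     paths$popmap, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_toy_gff3(genes, config$chrom_lengths, paths$gff3)
  gseq <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(gseq, paths$fasta, width = 70L)

  # pathways: enriched pathway takes the first `enriched_size` slots, its
  # hits being genes planted with *functional* consequences
  gene_ids <- vapply(genes, `[[`, "", "gene_id")
  filler <- sprintf("BG%05d", seq_len(config$pathway_background_size -
                                        length(gene_ids)))
  background_genes <- c(gene_ids, filler)
  func_genes <- gene_ids[seq_along(config$planted_variants)][
    is_putatively_functional(config$planted_variants)]
  enr <- c(func_genes,
           sample(filler, max(0L, config$enriched_size - length(func_genes))))
  pw <- list("Planted enriched pathway" = enr)
  for (j in seq_len(config$n_pathways - 1L))
    pw[[sprintf("Decoy pathway %02d", j)]] <-
      sample(filler, config$pathway_size)
  memb <- do.call(rbind, lapply(names(pw), function(nm)
    data.frame(pathway = nm, gene = pw[[nm]], stringsAsFactors = FALSE)))
  utils::write.table(memb, paths$pathways, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(background_genes, paths$background)
  truth[[length(truth) + 1L]] <- data.frame(
    type = "enriched_pathway", chrom = NA_character_, start = NA_integer_,
    end = NA_integer_, gene = NA_character_, consequence = NA_character_,
    ref = NA_character_, alt = NA_character_,
    pathway = "Planted enriched pathway", stringsAsFactors = FALSE)
  truth <- do.call(rbind, truth)
  utils::write.table(truth, paths$truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(paths, list(truth = truth))
}

write_toy_gff3 <- function(genes, chrom_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (chrom in names(chrom_lengths))
    writeLines(sprintf("##sequence-region %s 1 %d", chrom,
                       chrom_lengths[[chrom]]), con)
  fmt <- function(chrom, type, s, e, strand, phase, attrs)
    sprintf("%s\ttoy\t%s\t%d\t%d\t.\t%s\t%s\t%s", chrom, type, s, e,
            strand, phase, attrs)
  for (g in genes) {
    iv <- gene_intervals(g)
    span <- range(iv$exons)
    writeLines(fmt(g$chrom, "gene", span[1], span[2], g$strand, ".",
                   sprintf("ID=%s", g$gene_id)), con)
    writeLines(fmt(g$chrom, "mRNA", span[1], span[2], g$strand, ".",
                   sprintf("ID=%s;Parent=%s", g$tx_id, g$gene_id)), con)
    emit <- function(type, m, phased = FALSE) {
      rows <- seq_len(nrow(m))
      if (phased) {
        lens <- m[, 2] - m[, 1] + 1L
        order5 <- if (g$strand == "-") rev(rows) else rows
        ph <- integer(nrow(m))
        acc <- 0L
        for (k in order5) { ph[k] <- (3L - acc %% 3L) %% 3L; acc <- acc + lens[k] }
      }
      for (k in rows)
        writeLines(fmt(g$chrom, type, m[k, 1], m[k, 2], g$strand,
                       if (phased) as.character(ph[k]) else ".",
                       sprintf("ID=%s.%s%d;Parent=%s", g$tx_id,
                               tolower(type), k, g$tx_id)), con)
    }
    emit("exon", iv$exons)
    emit("CDS", iv$cds, phased = TRUE)
    emit("five_prime_UTR", iv$utr5)
    emit("three_prime_UTR", iv$utr3)
  }
  invisible(path)
}

#' Score pipeline output against a synthetic truth table
#'
#' Computes precision and recall for sweep-window detection, fixed
#' functional variant identification (position + consequence), and
#' whether the planted enriched pathway is ranked first and significant
#' after Bonferroni correction.
#'
#' @param results A [run_scan()] result list (needs `windows`,
#'   `divergent_effects`, `enrichment`).
#' @param truth Truth data.frame from [generate_dataset()].
#' @return List with `sweeps`, `fixed_variants` (each precision/recall),
#'   `consequence_accuracy`, and `pathway` (rank, significant, detected).
#' @export
evaluate_against_truth <- function(results, truth) {
  out <- list()
  tw <- truth[truth$type == "sweep_window", ]
  w <- results$windows
  flagged <- paste(w$chrom[w$outlier], w$start[w$outlier])
  truthw <- paste(tw$chrom, tw$start)
  out$sweeps <- list(
    recall = if (nrow(tw)) mean(truthw %in% flagged) else NA_real_,
    precision = if (length(flagged)) mean(flagged %in% truthw) else NA_real_,
    n_flagged = length(flagged), n_planted = nrow(tw))

  tv <- truth[truth$type == "fixed_variant" &
                is_putatively_functional(truth$consequence), ]
  de <- results$divergent_effects
  fixed <- de[de$category == "fixed" &
                is_putatively_functional(de$consequence), ]
  found_key <- paste(fixed$chrom, fixed$pos, fixed$consequence)
  truth_key <- paste(tv$chrom, tv$start, tv$consequence)
  out$fixed_variants <- list(
    recall = if (nrow(tv)) mean(truth_key %in% found_key) else NA_real_,
    precision = if (nrow(fixed))
      mean(paste(fixed$chrom, fixed$pos) %in%
             paste(tv$chrom, tv$start)) else NA_real_,
    n_found = length(unique(paste(fixed$chrom, fixed$pos))),
    n_planted = nrow(tv))

  tall <- truth[truth$type == "fixed_variant", ]
  eff <- results$effects
  match_cons <- vapply(seq_len(nrow(tall)), function(i) {
    rows <- eff[eff$chrom == tall$chrom[i] & eff$pos == tall$start[i], ]
    want <- if (tall$consequence[i] == "intronic") "non_functional"
            else tall$consequence[i]
    want %in% rows$consequence
  }, logical(1))
  out$consequence_accuracy <- mean(match_cons)

  tp <- truth[truth$type == "enriched_pathway", ]
  if (nrow(tp) && !is.null(results$enrichment)) {
    en <- results$enrichment
    rank <- match(tp$pathway[1], en$pathway)
    out$pathway <- list(rank = rank,
                        significant = isTRUE(en$p_adj[rank] < 0.05),
                        detected = isTRUE(rank == 1L) &&
                          isTRUE(en$p_adj[rank] < 0.05))
  } else out$pathway <- list(rank = NA, significant = NA, detected = NA)
  out
}
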