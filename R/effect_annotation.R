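#' Load transcript gene models from GFF3 + reference FASTA
#'
#' Builds one gene model per mRNA/transcript feature: ordered exons, CDS
#' and UTR intervals (1-based inclusive), strand and gene id, with the
#' reference sequence attached for codon lookups. UTRs are taken from
#' explicit `five_prime_UTR` / `three_prime_UTR` features when present,
#' otherwise derived as exonic-minus-CDS and partitioned by side relative
#' to the CDS in transcript orientation. Transcripts whose total CDS
#' length is not divisible by 3 are skipped with a warning.
#'
#' @param gff3_path Path to a GFF3 file with gene/mRNA/exon/CDS features.
#' @param fasta_path Path to the reference FASTA; must contain every
#'   chromosome referenced by a kept transcript.
#' @return A `gene_model_set`: a list of transcript models, each a list
#'   with `gene_id`, `tx_id`, `chrom`, `strand`, and interval matrices
#'   `exons`, `cds`, `utr5`, `utr3` (columns start, end); the genome is in
#'   `attr(, "genome")`.
#' @export
load_gene_models <- function(gff3_path, fasta_path) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(gff3_path)
  type <- as.character(gr$type)
  tx <- gr[type %in% c("mRNA", "transcript")]
  if (length(tx) == 0L) stop("no mRNA/transcript features in ", gff3_path)

  parent_of <- function(x) {
    p <- x$Parent
    vapply(as.list(p), function(v) if (length(v)) v[[1]] else NA_character_,
           character(1))
  }
  feat <- gr[type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")]
  feat_parent <- parent_of(feat)
  feat_type <- as.character(feat$type)

  ivmat <- function(g) {
    if (length(g) == 0L) return(NULL)
    m <- cbind(start = GenomicRanges::start(g), end = GenomicRanges::end(g))
    m[order(m[, 1]), , drop = FALSE]
  }

  models <- list()
  for (i in seq_along(tx)) {
    tid <- tx$ID[i]
    gid <- parent_of(tx[i])
    chrom <- as.character(GenomicRanges::seqnames(tx[i]))
    strand <- as.character(GenomicRanges::strand(tx[i]))
    mine <- feat[feat_parent == tid]
    mtype <- feat_type[feat_parent == tid]
    exons <- ivmat(mine[mtype == "exon"])
    cds <- ivmat(mine[mtype == "CDS"])
    utr5 <- ivmat(mine[mtype == "five_prime_UTR"])
    utr3 <- ivmat(mine[mtype == "three_prime_UTR"])
    if (is.null(exons)) next
    if (!is.null(cds)) {
      cds_len <- sum(cds[, 2] - cds[, 1] + 1)
      if (cds_len %% 3 != 0) {
        warning("transcript ", tid, " skipped: CDS length ", cds_len,
                " not divisible by 3")
        next
      }
    }
    if (!chrom %in% names(genome))
      stop("chromosome ", chrom, " referenced by ", tid,
           " absent from FASTA")
    if (is.null(utr5) && is.null(utr3) && !is.null(cds)) {
      d <- derive_utrs(exons, cds, strand)
      utr5 <- d$utr5; utr3 <- d$utr3
    }
    models[[length(models) + 1L]] <- list(
      gene_id = gid, tx_id = tid, chrom = chrom, strand = strand,
      exons = exons, cds = cds, utr5 = utr5, utr3 = utr3)
  }
  attr(models, "genome") <- genome
  class(models) <- "gene_model_set"
  models
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat("gene model set:", length(x), "transcripts on",
      length(unique(vapply(x, `[[`, "", "chrom"))), "chromosome(s)\n")
  invisible(x)
}

# exonic minus CDS, split into 5' and 3' sides in transcript orientation
derive_utrs <- function(exons, cds, strand) {
  ex <- IRanges::IRanges(exons[, 1], exons[, 2])
  cd <- IRanges::IRanges(cds[, 1], cds[, 2])
  rest <- IRanges::setdiff(ex, cd)
  if (length(rest) == 0L) return(list(utr5 = NULL, utr3 = NULL))
  lo <- rest[IRanges::end(rest) < min(cds[, 1])]
  hi <- rest[IRanges::start(rest) > max(cds[, 2])]
  tomat <- function(r) if (length(r) == 0L) NULL else
    cbind(start = IRanges::start(r), end = IRanges::end(r))
  if (strand == "+") list(utr5 = tomat(lo), utr3 = tomat(hi))
  else list(utr5 = tomat(hi), utr3 = tomat(lo))
}

in_intervals <- function(pos, iv) {
  if (is.null(iv)) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (k in seq_len(nrow(iv))) out <- out | (pos >= iv[k, 1] & pos <= iv[k, 2])
  out
}

# genomic CDS positions in transcript (5'->3') order
cds_positions <- function(model) {
  if (is.null(model$cds)) return(integer(0))
  pos <- unlist(lapply(seq_len(nrow(model$cds)),
                       function(k) model$cds[k, 1]:model$cds[k, 2]))
  if (model$strand == "-") rev(pos) else pos
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Severity ranking of consequence labels
#'
#' Used for gene-level summaries and the exclusive-category spectrum mode.
#' Higher rank = more severe.
#' @export
CONSEQUENCE_SEVERITY <- c(
  non_functional = 1, synonymous = 2, three_prime_utr = 3,
  five_prime_utr = 4, splice_region = 5, missense = 6,
  frameshift = 7, stop_lost = 8, stop_gained = 9)

#' Consequences regarded as putatively functional
#'
#' Everything that can alter protein structure (missense, stop gain/loss,
#' frameshift) or proximal gene regulation (5'-UTR, 3'-UTR, splice region).
#' Synonymous and non-genic/intronic sites are not.
#'
#' @param consequence Character vector of consequence labels.
#' @return Logical vector.
#' @export
is_putatively_functional <- function(consequence) {
  consequence %in% c("missense", "stop_gained", "stop_lost", "frameshift",
                     "five_prime_utr", "three_prime_utr", "splice_region")
}

#' Classify SNPs against gene models
#'
#' A simplified variant-effect predictor for biallelic SNPs. For every
#' site x overlapping transcript it reports one consequence row:
#' CDS positions are translated (reference vs alternative codon, standard
#' genetic code, in transcript orientation) into synonymous / missense /
#' stop_gained / stop_lost; UTR intervals give five_prime_utr /
#' three_prime_utr; positions within the splice zone of an exon-intron
#' junction (1-3 bp exonic, 1-8 bp intronic, covering both the canonical
#' donor/acceptor dinucleotides and the wider splice region) give
#' splice_region; everything else, including deep-intronic and intergenic
#' sites, is non_functional. An exonic site that also lies in a splice
#' zone additionally gets a splice_region row.
#'
#' @param sites Data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (a `site_table` works).
#' @param models A `gene_model_set` from [load_gene_models()].
#' @return Data.frame with `chrom`, `pos`, `ref`, `alt`, `gene_id`,
#'   `tx_id`, `consequence`, `aa_ref`, `aa_alt`. Sites overlapping no
#'   transcript get a single row with `gene_id = NA` and
#'   `consequence = "non_functional"`.
#' @export
classify_variants <- function(sites, models) {
  genome <- attr(models, "genome")
  res <- list()
  hit <- rep(FALSE, nrow(sites))
  for (m in models) {
    span <- range(m$exons)
    sel <- which(sites$chrom == m$chrom & sites$pos >= span[1] &
                   sites$pos <= span[2])
    if (length(sel) == 0L) next
    hit[sel] <- TRUE
    res[[length(res) + 1L]] <-
      classify_in_transcript(sites[sel, , drop = FALSE], m, genome)
  }
  out <- if (length(res)) do.call(rbind, res) else NULL
  if (any(!hit)) {
    rest <- sites[!hit, c("chrom", "pos", "ref", "alt"), drop = FALSE]
    rest$gene_id <- NA_character_; rest$tx_id <- NA_character_
    rest$consequence <- "non_functional"
    rest$aa_ref <- NA_character_; rest$aa_alt <- NA_character_
    out <- rbind(out, rest)
  }
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

#' @rdname classify_variants
#' @export
classify_variant <- function(sites, models) classify_variants(sites, models)

classify_in_transcript <- function(sub, m, genome) {
  n <- nrow(sub)
  consequence <- rep("non_functional", n)
  aa_ref <- rep(NA_character_, n); aa_alt <- rep(NA_character_, n)
  chromseq <- genome[[m$chrom]]

  cpos <- cds_positions(m)
  idx <- match(sub$pos, cpos)
  in_cds <- !is.na(idx)
  if (any(in_cds)) {
    gc <- Biostrings::GENETIC_CODE
    for (j in which(in_cds)) {
      i <- idx[j]
      codon_start <- ((i - 1) %/% 3) * 3 + 1
      codon_pos <- cpos[codon_start:(codon_start + 2)]
      bases <- vapply(codon_pos, function(p)
        as.character(Biostrings::subseq(chromseq, p, p)), character(1))
      altb <- sub$alt[j]
      if (m$strand == "-") {
        bases <- unname(COMPLEMENT[bases])
        altb <- unname(COMPLEMENT[altb])
      }
      ref_codon <- paste(bases, collapse = "")
      within <- (i - 1) %% 3 + 1
      alt_bases <- bases; alt_bases[within] <- altb
      alt_codon <- paste(alt_bases, collapse = "")
      ar <- gc[[ref_codon]]; aa <- gc[[alt_codon]]
      aa_ref[j] <- ar; aa_alt[j] <- aa
      consequence[j] <-
        if (ar != "*" && aa == "*") "stop_gained"
        else if (ar == "*" && aa != "*") "stop_lost"
        else if (ar == aa) "synonymous" else "missense"
    }
  }
  consequence[!in_cds & in_intervals(sub$pos, m$utr5)] <- "five_prime_utr"
  consequence[!in_cds & in_intervals(sub$pos, m$utr3)] <- "three_prime_utr"

  sp <- splice_zone(sub$pos, m$exons)
  # intronic (or otherwise unlabelled) splice-zone sites become splice_region
  promote <- sp & consequence == "non_functional"
  consequence[promote] <- "splice_region"

  out <- data.frame(chrom = sub$chrom, pos = sub$pos, ref = sub$ref,
                    alt = sub$alt, gene_id = m$gene_id, tx_id = m$tx_id,
                    consequence = consequence, aa_ref = aa_ref,
                    aa_alt = aa_alt, stringsAsFactors = FALSE)
  # exonic consequences co-occurring with a splice zone: extra row
  extra <- which(sp & !promote)
  if (length(extra)) {
    add <- out[extra, ]
    add$consequence <- "splice_region"
    add$aa_ref <- NA_character_; add$aa_alt <- NA_character_
    out <- rbind(out, add)
  }
  out
}

# TRUE where pos lies within the splice zone of an internal exon junction:
# 1-3 bp into the exon or 1-8 bp into the intron.
splice_zone <- function(pos, exons) {
  n_ex <- nrow(exons)
  out <- rep(FALSE, length(pos))
  if (n_ex < 2L) return(out)
  exonic <- in_intervals(pos, exons)
  for (k in seq_len(n_ex)) {
    if (k < n_ex) {  # junction at exon end (intron follows)
      b <- exons[k, 2]
      out <- out | (exonic & pos >= b - 2 & pos <= b) |
        (!exonic & pos >= b + 1 & pos <= b + 8)
    }
    if (k > 1L) {    # junction at exon start (intron precedes)
      b <- exons[k, 1]
      out <- out | (exonic & pos >= b & pos <= b + 2) |
        (!exonic & pos >= b - 8 & pos <= b - 1)
    }
  }
  out
}

#' Reduce multi-transcript effects to one row per site
#'
#' Keeps, for each (chrom, pos), the single most severe consequence by
#' [CONSEQUENCE_SEVERITY] (ties broken by first occurrence).
#'
#' @param effects Data.frame from [classify_variants()].
#' @return Data.frame with one row per site.
#' @export
most_severe_effects <- function(effects) {
  sev <- CONSEQUENCE_SEVERITY[effects$consequence]
  ord <- order(effects$chrom, effects$pos, -sev)
  eff <- effects[ord, ]
  key <- paste(eff$chrom, eff$pos)
  out <- eff[!duplicated(key), ]
  rownames(out) <- NULL
  out
}
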