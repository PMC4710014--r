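---
title: "Methods: windowed Fst scans, functional annotation and the coalescent null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed Fst scans, functional annotation and the coalescent null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(canidscan)
```

# The analysis in one paragraph

Domestication leaves two complementary genomic signatures: windows of
elevated allele-frequency differentiation between the domesticated
population and its wild progenitor (selective sweeps), and individual
variants — fixed or at high frequency for alternative alleles — whose
predicted molecular consequence makes them plausible targets of the
selection itself. `canidscan` implements the full chain that connects
them: per-site Fst, a windowed Z-score scan, variant-effect
classification, pathway over-representation of the genes carrying
functional divergent sites, category-level statistics, and a
structured-coalescent neutral null that asks whether demography alone
could produce the windows the scan flags.

# The Fst estimator

Per site we compute Weir & Cockerham's (1984) θ̂ for two populations of
diploids from genotype counts (hom-ref, het, hom-alt). Writing `n_i`,
`p_i`, `h_i` for the sample size, alt-allele frequency and observed
heterozygote frequency in population *i*, the estimator forms the
moment corrections n̄ and n_c and the three variance components

* `a` — among populations,
* `b` — among individuals within populations,
* `c` — within individuals (half the average heterozygote frequency),

and reports θ̂ = a/(a+b+c). Properties the tests pin down: θ̂ = 1
exactly at a fixed difference; θ̂ ≤ 0 when both populations have
identical counts (estimates can be negative — they are *not* clamped,
because clamping would bias window means upward); θ̂ is invariant to
allele relabelling and population order; sites monomorphic across both
populations, or with no called genotypes in one of them, carry an `NA`
sentinel and are excluded downstream. The test suite verifies agreement
to 1e-10 with an independently coded sums-of-squares (nested ANOVA)
evaluation of the same estimator on 1,000 random genotype
configurations, plus hand-frozen values (13/18 for the 4-vs-4 worked
case).

# The windowed scan

Windows tile each chromosome as `[(k-1)·500kb + 1, k·500kb]`, 1-based
inclusive, so position 500,000 belongs to window 1 and 500,001 to
window 2. The window statistic is the *unweighted* mean of the defined
per-site θ̂; the ratio-of-sums estimator Σa/Σ(a+b+c) is computed
alongside because windowed-Fst tools differ in their default and the
choice is not always stated — both are reported, and either can drive
the outlier flags. Windows with fewer than `min_sites` (default 10)
defined sites are excluded from the Z-transform. Z-scores use the
genome-wide mean and n−1 standard deviation over all defined windows —
autosomes and X alike, so a single threshold applies everywhere — and
the outlier rule is one-sided and inclusive: Z(Fst) ≥ 5.

A structural point worth knowing when designing simulations: with K
windows and a single extreme window, the largest attainable Z is
(K−1)/√K (≈ 4.4 at K = 20, ≈ 8.8 at K = 80), because the outlier
inflates the standard deviation it is judged against. A Z ≥ 5 rule is
therefore only meaningful on genomes of roughly 30+ windows; this is
why the synthetic genome defaults to 2 × 20 Mb (80 windows of 500 kb)
rather than something smaller.

# Effect classification

The classifier is a deliberately simplified re-implementation of the
semantics of mainstream variant-effect predictors, restricted to
biallelic SNPs and the categories the analysis needs: for each
transcript overlapping a site, CDS positions are translated (reference
versus alternative codon, standard genetic code, in transcript
orientation — minus-strand variants are complemented) into
synonymous/missense/stop-gain/stop-loss; UTR intervals give the two UTR
labels; positions within the splice zone of an internal exon–intron
junction are splice_region. The splice zone follows the common
convention: 1–3 bp into the exon and 3–8 bp into the intron, with the
canonical 1–2 bp donor/acceptor positions also reported as
splice_region since the downstream tables use a single coarse splice
category. Deep-intronic and intergenic sites are non_functional.
"Putatively functional" = anything except synonymous and
non_functional. UTRs absent from the annotation are derived as
exonic-minus-CDS, partitioned by side relative to the CDS in transcript
orientation; transcripts whose CDS length is not a multiple of 3 are
skipped with a warning. A site in several transcripts keeps one row per
transcript; gene-level summaries use a fixed severity order
(stop_gained > stop_lost > frameshift > missense > splice_region >
5′-UTR > 3′-UTR > synonymous > non_functional). Frameshift is defined
for completeness but unreachable with SNP input.

# Divergent sites, genes and pathways

Sites with θ̂ ≥ 0.75 (inclusive) are "high"; "fixed" additionally
requires |θ̂ − 1| ≤ 1e-12 *and* the two populations monomorphic for
opposite alleles among called genotypes — the biological definition,
which protects against floating-point accidents. Genes map to their
putatively functional divergent sites (a gene whose divergent sites are
all synonymous is absent; a site shared by overlapping transcripts
counts for both genes). Each divergent site is labelled with its
containing 500 kb window and whether that window or an immediate
neighbour is a scan outlier.

Enrichment uses the gene, not the site, as the sampling unit. The
default test is the one-sided binomial tail P(X ≥ k) with n = sample
size and p = K/M (pathway size over background size) — the classic
over-representation test — with the hypergeometric (one-sided Fisher)
tail as an alternative mode, since published analyses do not always
state which was used. Expected counts are n·K/M. Bonferroni correction
multiplies by the number of *tested* pathways; an "Unclassified"
pseudo-pathway is tabulated but excluded from testing and from the
correction denominator.

# Category statistics

The bin spectrum cross-tabulates divergent sites by Fst bin
([0.85–0.9), [0.9–0.95), [0.95–1), and exactly-1 as its own bin — fixed
differences are a qualitatively distinct class) and consequence
category, as percentages of sites per bin. Because a site can carry
several labels, the default mode counts it once per category
(percentages can then sum above 100); an exclusive-by-severity mode is
provided, as published figures rarely state which convention they use.

The flanking contrast computes mean θ̂ in a 50 kb window centred on
each putatively functional divergent site (inclusive bounds, truncated
at chromosome edges, focal site included), groups the values by
category — 5′-UTR, 3′-UTR, missense, splice region, stop gained, with
synonymous as the neutral reference — and applies a classic
equal-variance one-way ANOVA followed by Tukey's HSD (studentized range
with (k, N−k) df), via `stats::aov`/`stats::TukeyHSD`. The tests pin the
standard identities: df = (k−1, N−k), F = t² for two groups, q = √2·|t|,
and order invariance.

# The coalescent null

The simulator is a continuous-time structured coalescent: within a deme
of diploid size N, k lineages coalesce at rate k(k−1)/(4N) per
generation; migration moves single lineages between demes at
backwards-in-time rates m_ij; at a split time the derived deme's
lineages re-label into the ancestral deme; deme sizes and migration
rates can change at epoch boundaries. Times are in generations, sizes
diploid. Mutations are dropped on branches as a Poisson process at
μ per bp per generation under infinite sites, so every simulated column
is biallelic and segregating.

Recombination within a 500 kb window is approximated by B independent
non-recombining blocks (default B = 50), which preserves the
variance-reducing effect of intra-window recombination on window-mean
Fst at a small fraction of the cost of an ancestral recombination
graph. Larger B narrows the null; the choice is exposed and its effect
is the main knob a user should sensitivity-check. Lineages left in
demes that can never coalesce (no migration, no further events) raise a
fatal model-misspecification error rather than hanging.

Simulated haplotypes are paired into diploids and pushed through the
*same* genotype-count and θ̂ code path as empirical VCF data, so the
null and the observation cannot drift apart numerically. Engine
validation in the tests: pairwise TMRCA ≈ 2N and exponential waiting
times; pairwise diversity ≈ 4Nμ within 3 Monte-Carlo standard errors;
the unfolded site-frequency spectrum ∝ 1/i; mean Fst ≈ 1/(1 + 16Nm) in
the symmetric two-deme island model; monotone decrease of Fst with
migration; and a segregating-site cross-check against msprime with
matched parameters.

The shipped demography (`inst/extdata/demography_dog_wolf.yaml`) is
*illustrative*: a domesticated deme with a post-split bottleneck
(N = 2,500, within the published 700–3,200 range for the ancestral dog
population), a wild deme of 10,000 joining an ancestral population of
15,000 at 3,000 generations, and weak symmetric migration (1e-4). It
reproduces the structure — split, bottleneck, migration — not any
inferred parameter set; under it the neutral window-mean Fst
distribution centres near 0.19.

# The synthetic generator and what passing tests mean

`generate_dataset()` emulates the study conditions: 67 + 7 diploids, a
2 × 20 Mb toy genome carrying 20 three-exon genes (300 bp CDS framed by
real start/stop codons, UTRs, 500 bp introns, alternating strands),
background polymorphism from the coalescent engine (a fast i.i.d.
Balding–Nichols mode at background Fst 0.14 exists for unit tests), 5 %
missing genotypes, two injected sweep windows (per-site allele
frequencies pushed to ~0.95 divergence, giving window means ~0.89), a
panel of planted fixed variants covering every reachable consequence
category (placed clear of splice zones unless a splice consequence is
requested), and a pathway table in which one pathway truly contains the
planted functional genes. Everything planted is recorded in a truth
table, and `evaluate_against_truth()` scores precision/recall for
sweeps, fixed functional variants, consequence labels and the enriched
pathway. Two of the non-planted genes are relocated into each sweep
window so sweeps also carry genic divergent sites.

What the synthetic data does *not* emulate: linkage disequilibrium
between the injected sweep sites (they are drawn independently given
the sweep frequencies), genotyping error, indels and multi-allelic
sites, variable gene density, or realistic chromosome-scale
recombination maps. Passing the end-to-end tests therefore demonstrates
that the machinery is correct and calibrated under the stated
generative model, not that the thresholds are optimal for any real
dataset.

# Numerical and design choices

* Call-rate filter: a site is kept iff called fraction ≥ 0.5 in *both*
  populations, boundary inclusive. Haploid or phased genotypes are
  counted as allele pairs; phase is ignored (only counts matter).
* Monomorphic sites and empty windows carry `NA` sentinels, never 0.
* Fixed-site tolerance 1e-12 plus the monomorphism guard.
* Bin boundaries left-inclusive; exactly 1 its own bin.
* The Z-transform refuses constant input (no dispersion) rather than
  returning zeros.
* Empirical exceedance p-values use the (1 + #{null ≥ obs})/(n + 1)
  correction so no window reports p = 0.
* Problem sizes in tests are desk-scale by design: hundreds of
  coalescent replicates per closed-form check (tolerances are stated in
  Monte-Carlo standard errors), 80-window genomes end to end, 20 seeds
  for the false-positive calibration of the Z ≥ 5 rule.

# Known limitations

* Two populations only; the estimator is the r = 2 specialisation.
* The classifier handles SNPs; frameshift requires indel input it never
  receives.
* Block-wise recombination is an approximation; tail quantiles of the
  null are somewhat conservative at small B.
* The enrichment test treats genes as exchangeable — gene length and
  SNP density are not modelled, a known source of optimism in all
  over-representation analyses of variant-derived gene sets.
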