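---
title: "Methods: genomic co-localization of co-expressed and co-interacting genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic co-localization of co-expressed and co-interacting genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colocnet)
```

## The question and the statistic

Functionally related genes — members of the same pathway, subunits of the
same complex, co-expressed partners — are often not scattered randomly
along chromosomes but sit near each other in gene order. `colocnet`
quantifies this per gene. Given a genome annotation with `N` genes and an
interaction network (co-expression plus protein interaction edges, e.g. a
STRING combined-score edge list thresholded at 150 on the 0–1000 scale),
every gene `g` gets:

* `T` — its total number of network partners anywhere in the genome;
* `L` — the number of those partners among the genes occupying the
  gene-order offsets `−W … −1, +1 … +W` on the same chromosome
  (the *window*, default `W = 10`);
* `n_window` — the number of eligible window genes.

The genome-wide likelihood of a partner is `T / (N − 1)`; the local
likelihood is `L / n_window`; and the **co-localization fold-change** is

$$FC = \frac{L / n_\mathrm{window}}{T / (N-1)}.$$

Under random gene placement the window is an unbiased sample of the
genome, so `E[L | T] = T · n_window / (N − 1)` and `FC` centers on 1
(hypergeometric sampling of the window from the genome). `FC ≥ 2` is the
conventional call for non-random co-localization, with descriptive bins
`[2, 5)`, `[5, 20)`, `[20, 50)`, `[50, ∞)`. No per-gene p-value is
attached: `FC` is reported as a descriptive ratio, and calibration is
demonstrated on simulated null genomes instead (see below).

### Ortholog-group exclusion

Tandemly duplicated genes are each other's best co-expression partners and
would masquerade as co-localization. Window genes belonging to the focal
gene's ortholog group (KO-style groups; genes missing from the table are
singletons) are therefore removed from both `L` and `n_window`. The
genome-wide `T` is left untouched: the exclusion is defined within the
window, and removing group members genome-wide would require a global
duplicate map the inputs do not provide.

### Denominator choices

Two places where the definition is genuinely open were resolved as
follows:

* **Genome-wide denominator is `N − 1`**, all annotated genes except the
  focal gene, not the (smaller) network universe. The annotation is the
  common universe in which windows are defined; genes without edges occupy
  window slots and must count in both denominators symmetrically.
* **`n_window` counts the window genes that actually exist** after
  truncation at chromosome ends and after group exclusion, making the
  local likelihood a proper frequency. Fixing the denominator at `2W`
  would bias terminal genes downward for no reason; with truncation, `FC`
  is invariant under reversing a chromosome's gene order or relabeling
  chromosomes, which the test suite checks.

Genes with `T = 0` (absent from the network) or `n_window = 0` (alone on
a contig) have no defined `FC`; they are excluded from summaries with an
explicit reason rather than propagating `NaN`.

## Distance decay

`distance_decay()` asks a finer question: at each gene-order rank
`k = 1 … W`, what fraction of genes has at least one partner among its (up
to two) neighbors at distance exactly `k`? In real genomes this likelihood
declines with `k`, consistent with recombination separating distant pairs
more often. Two conditioning decisions:

* Only genes with `T > 0` are eligible — otherwise the curve scales with
  network coverage rather than with co-localization.
* No ortholog-group exclusion is applied at this stage; the curve is a
  property of the raw partner relation, and the per-gene `FC` already
  handles duplicates where calls are made.

## Cross-species neighborhood overlap

For two species joined by a strictly one-to-one homolog map, every window
partner event of species A — partner `p` at offset `o` from focal gene
`gA` — is checked in species B: it is *conserved* (an overlap) when `p`'s
homolog is a partner of `gA`'s homolog `gB` **and** occupies offset `o`
or the mirrored offset `−o` in `gB`'s window. The mirror rule absorbs
segmental inversions and whole-chromosome orientation differences without
any synteny-block inference: it is applied per event, not per segment,
because events are extracted individually. Overlap therefore requires
homolog identity of the partner, not mere occupancy of the slot by some
other partner.

Counting is directional (from species A's events) and each event counts
at most once even if both the same and the mirrored slot match. On
one-to-one maps the total overlap count is symmetric under swapping the
species, which is property-tested. Homolog pairs missing annotation or
network data on either side are excluded with reason codes rather than
silently dropped.

## Linkage disequilibrium

Co-localized pathway genes can only confer a joint fitness advantage if
their alleles co-segregate, so the package closes the loop with classical
two-locus LD over SNPs flanking genes of interest. From phased haplotypes
(phasing is required; no EM reconstruction from genotypes):

$$D = p_{AB} - p_A p_B, \qquad
D' = \frac{|D|}{D_\mathrm{max}}, \qquad
r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)},$$

with `D_max = min(p_A(1−p_B), (1−p_A)p_B)` when `D > 0` and
`min(p_A p_B, (1−p_A)(1−p_B))` when `D < 0`; `D' = 0` when `D = 0`, and
`D'` is reported unsigned in `[0, 1]` (heatmap convention: complete
linkage `D' = 1`, random segregation `D' = 0`). Internally all four
quantities are computed from integer haplotype counts, so `D'` and `r²`
are single divisions of exact integer products and can never exceed 1 by
floating-point error. Monomorphic sites raise an error — never a silent
zero.

Flanking SNPs are selected nearest-by-bp from the 5′ and 3′ flanks,
balanced across flanks while supply allows, capped at 100 and warned
below 60; the flank width defaults to 50 kb and is configurable, since
only the SNP count range is externally fixed.

## The synthetic-data generators

Real inputs of this analysis are large database downloads; the package
instead ships generators that emulate their structure with known ground
truth, serialized beside every dataset:

* `generate_genome()` — non-overlapping genes with exponential spans and
  gaps on `n_chrom` chromosomes.
* `generate_network()` — background edges i.i.d. at `p_bg` over all
  pairs, plus either planted clusters (runs of consecutive genes whose
  internal pairs gain edges at `min(1, f·p_bg)`, default span 5,
  emulating biosynthetic-gene-cluster blocks) or a geometric rank-decay
  kernel `a·exp(−d/λ)`. Scores are uniform on `[min_score, 1000]` —
  the analysis only thresholds them.
* `generate_species_pair()` — species B as a renamed copy with identity
  homologs, degraded by per-gene relocation (`shuffle_rate`), random
  non-overlapping segmental inversions, and binomial edge retention.
* `generate_haplotype_panel()` — a founder-copying model: each haplotype
  copies one of two complementary founders and switches to a different
  founder between adjacent sites with probability `c`. `c → 0` gives
  complete linkage; with two founders `c = 0.5` makes adjacent sites
  exactly independent. `two_site_panel()` builds exact panels from the
  four haplotype class counts for analytic checks.

Every generator is a pure function of its parameters and seed; a master
seed fans out to per-component substreams so adding a generator never
perturbs existing outputs.

What the generators do **not** emulate: real degree distributions
(STRING is heavy-tailed, the background here is Erdős–Rényi), gene-family
evolution, expression-derived edge correlation, coalescent genealogies,
or population structure. Passing tests on these inputs demonstrate the
*correctness and calibration of the statistics*, not biological
conclusions about any particular genome.

## Validation design and problem sizes

The test suite validates along five lines, with sizes chosen to keep the
full run around a minute or two:

1. **Exact oracle agreement.** On random fixtures up to 200 genes,
   `coloc_stats()`, `distance_decay()` and `overlap_events()` must agree
   *exactly* with quadratic brute-force reimplementations that enumerate
   all gene pairs and offsets with plain loops.
2. **Null calibration.** On a 5,000-gene genome with a uniform random
   network of mean degree 20 and no planted structure, the mean `FC` over
   genes with `T ≥ 10` must lie within 3 standard errors of 1, and fewer
   than 10% of genes reach `FC ≥ 2` at `W = 10`.
3. **Enrichment recovery.** Clusters planted at enrichment factors
   `f ∈ {5, 20}` must be recovered: median planted `FC ≥ f/2`, and the
   planted `FC ≥ 2` rate must exceed the background rate by at least 0.5.
   This target fixes the experiment's geometry: with cluster span `s`, the
   attainable `FC` is roughly `1 + (s−1)·f/(2W)`, so only window-filling
   clusters (`s = 2W + 1 = 21`) can reach `f/2` at `f = 20`. The recovery
   experiment therefore plants span-21 clusters in a dense interactome
   (2,000 genes, `p_bg = 0.035`, i.e. mean degree 70, within the range of
   score-thresholded STRING networks); the generator's default span stays
   at 5 for ordinary cluster emulation.
4. **Cross-species invariants.** Identity comparison conserves every
   event; whole-chromosome inversion leaves overlap counts unchanged
   (the mirror rule); complete shuffling drives conservation to chance
   (< 2% of events at 1,000 genes).
5. **LD properties.** 1,000 fuzzed panels keep `D'` and `r²` in `[0, 1]`
   and invariant (up to `D`'s sign) under allele relabeling; `r² = 1`
   implies `D' = 1`; and the copying model reaches mean `D' > 0.95` at
   `c = 0.001` with 200 haplotypes.

The decay-kernel recovery check runs 10 seeds at 2,000 genes and allows
at most one seed with a non-monotone estimated curve, the smallest
realizable operationalization of a ≤ 5% violation rate.

## Numerical and degenerate-input policy

* Order indices are dense and 0-based per chromosome; ties on start
  coordinate break by `(end, gene_id)`, so results are independent of
  input row order. Coordinates are 0-based half-open internally; GFF3 is
  converted on read. Strand is ignored throughout — the analysis is about
  gene order only.
* Duplicate network rows collapse keeping the maximum score
  (order-independent and conservative for directional STRING dumps);
  self edges are dropped; edges touching unannotated genes are dropped
  and counted.
* `FC` is never `NaN`: undefined cases carry an `excluded_reason`.
* Empty networks after filtering warn (a data condition); an empty
  network passed to `distance_decay()` errors (the curve is undefined).

## Limitations

* `FC` is descriptive; genes with small `T` have high-variance `FC`, and
  callers should condition on `T` (as the calibration checks do) before
  interpreting tails.
* One-to-one homology only; paralog-rich families are excluded rather
  than resolved.
* The LD module computes statistics; it does not phase, prune, or model
  population structure.
* The per-event mirror rule recovers inverted events but does not
  detect or report inversion breakpoints.
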