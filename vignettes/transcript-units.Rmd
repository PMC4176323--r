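---
title: "Transcript units from TSS-PAS mate-pair tags: models and methods"
author: "endmate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcript units from TSS-PAS mate-pair tags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endmate)
```

## The measurement and its noise

A mate-pair full-length cDNA tag library links, for each captured mRNA
molecule, a short sequence tag at the transcription start site (TSS, marked
by replacing the cap with a synthetic oligo) to a tag at the poly(A)
addition site (PAS, marked by oligo-dT priming) — or, in the TSS/Random
variant, to a random internal position whose distance from the TSS reflects
the size-selected insert length. Because both ends come from one molecule,
the data resolve questions bulk 5'-end or 3'-end assays cannot: which
alternative promoter pairs with which alternative terminator, whether a
start in one gene runs through into the terminator of its neighbour, and
whether two far-apart genes are joined by a genomic rearrangement.

Three library-construction artefacts shape every analysis choice in this
package:

* **5' truncation** — incomplete cap replacement tags an internal position
  instead of the true TSS, scattering spurious 5' tags along the mRNA;
* **internal priming** — oligo-dT annealing to a genomic A-rich stretch
  produces a false PAS upstream of the true one;
* **chimeric ligation** — during circularisation a 5' end is joined to the
  3' end of a different molecule, producing tag pairs that connect two
  unrelated transcripts at random.

## Clustering and expression

Tag ends are clustered per chromosome and strand on a fixed grid of 500-bp
bins (`cluster_tags()`). A fixed grid is deterministic and order
independent; the price, recorded as a limitation, is that a tag cloud
straddling a grid boundary becomes two clusters. Each cluster carries
per-library counts, a representative position (the modal tag position, ties
to the smallest coordinate), and expression in parts per million (ppm):
count × 10^6 / library total. Clusters are kept when they exceed 5 ppm
(strictly) in at least one library — libraries are independently
constructed, so evidence in any one tissue suffices.

Whether to merge clusters across libraries before or after the ppm filter
is genuinely open; this package filters per library and unions the
survivors, which keeps the filter interpretable per tissue.

The concentration of a gene's tags into one bin is screened against a null
in which the gene's `N` same-kind tags fall uniformly on its mature mRNA of
length `L` (the mRNA, not the genomic span, because truncation and internal
priming both act along the transcript): the bin count is then Poisson with
mean `N·min(w, L)/L` and `cluster_poisson_pvalue()` reports the upper tail.
A real TSS bin concentrates ~95% of the tags under 5% truncation noise and
reaches astronomically small p-values once a gene has on the order of a
hundred tags; the package's screening experiment
(`eval_cluster_screening()`) runs at such depths. A literal 10-tag gene
cannot reach p < 1e-10 for any mRNA longer than the bin — the interesting
regime is the deeply sequenced one.

## Gene association and cis-features

A TSC is associated with a gene model when its bin overlaps the 50-kb
window upstream of the annotated 5' end or lies in the first exon; a PAC
symmetrically at the 3' side (`associate_clusters()`). Clusters inside
internal exons are reported but excluded: an end tag there is more
plausibly truncation or internal priming than a genuine boundary. When a
cluster links to several genes, downstream per-gene analyses use the link
nearest its terminus (`cluster_gene_map()`).

Sequence context is scanned with fixed windows around the representative
position, all transcript-oriented: perfect `AATAAA` hexamers in `[-40, 0)`
of a PAC (the canonical signal sits ~10–30 bp upstream of cleavage; the
window is configurable because no single placement is universal), genomic
A-runs of ≥ 6 in `(0, +20]` downstream (the standard internal-priming
heuristic), and the IUPAC consensus `TATAWAWR` starting in `[-40, -20)` of
a TSC. The TATA consensus replaces proprietary position-weight matrices;
an exact-match consensus is reproducible and errs on the conservative
side. CpG islands are consumed as intervals and flagged on ≥ 1 bp bin
overlap.

## Pairing statistics

For each gene the package cross-tabulates how often TSC *i* is joined to
PAC *j* by one cDNA (`build_pair_matrix()`). Under independent end
selection the expected count is `e_ij = T_i·P_j/N`, and
`pair_independence_pvalue()` reports the Poisson upper tail of the observed
count at that mean — the natural contingency null with a Poisson tail,
stated explicitly so results are reproducible.

Two properties of this statistic matter for interpretation:

* With `e_ij` **re-estimated from the observed marginals** the test is
  conservative under the null: the marginals absorb most of the cells'
  freedom (a 3×3 table keeps 4 of 9 degrees of freedom), so at α = 0.05
  well under 1% of null cells are flagged. This direction of error is safe
  — independent ends are almost never called coupled — and is consistent
  with the observation that the vast majority of genes show no
  TSC–PAC correlation.
* When the expectation is **known** (here, from the generator's site
  weights; in general from any external reference) the tail probability is
  exactly calibrated up to count discreteness. `pair_independence_pvalue()`
  accepts such expectations via `expected`, and the package's calibration
  experiment (`eval_independence_calibration()`) shows ~4–5% of null cells
  flagged at α = 0.05 in that mode.

A pairing is **preferred** (`select_preferred()`) when it exceeds 5 ppm and
10 tags (both strict), deviates from independence at p < 0.05, is the
strict row and column maximum of its gene's matrix (the TSC and PAC
mutually select each other; ties disqualify, deterministically), and
carries more than half the tags of its TSC or its PAC. Counts are pooled
over libraries and the ppm criterion applies to the pooled pair, because
preference is a property of the gene, not of one tissue; raw (unadjusted)
p-values are used, as the share and mutuality filters do the heavy
lifting — a Benjamini–Hochberg column is available in
`geneset_enrichment()` output where multiplicity is the point.

Tissue specificity of any unit is summarised by `z = (x − μ)/σ` with
`x = log2(ppm + 1)` across the 18 libraries, population σ, and `z ≡ 0`
for constant units — conventions chosen so mean(z) = 0 and sd(z) = 1 hold
exactly. Switching units are tissue pairs where one unit has z > 2 in one
tissue and the other unit z > 2 in another (`detect_switching_pairs()`).
Overlap between two units of one gene is the interval Jaccard of their
TSC-to-PAC spans (symmetric and bounded; an overlap/shorter-span variant is
available by flag, since the denominator convention is not dictated by the
data).

## Connected units and fusion transcripts

A pairing whose TSC belongs to gene A and PAC to adjacent gene B (same
chromosome and strand, gap below 3 Mb, pooled ppm > 5) is a **connected
unit** — read-through transcription. Pairs joining genes on different
chromosomes, or more than 3 Mb apart, cannot be read-through and are
candidate **fusion transcripts** (`detect_fusions()`), counted only from
supporting pairs with mapping quality strictly above 37 on both ends and
reported only above 5 ppm pooled support. The mapping-quality gate removes
repeat-mediated mismappings; the ppm gate removes chimeric ligation, which
scatters its pairs thinly over the quadratic space of gene pairs. The
same-chromosome distance is measured between gene bodies (0 when they
overlap). Same-chromosome opposite-strand pairs under 3 Mb satisfy neither
definition and are dropped: the distance rule alone decides fusion status.

## Genome-guided assembly

Between a TSC and a PAC, every genomic coordinate is labelled `transcript`
if covered by at least one aligned tag block, `intron` if inside the gap of
at least one split tag, else `unknown`; a coordinate both covered and
spanned is `transcript`, because direct coverage is the stronger evidence.
The **integrity** of a model is the fraction of coordinates labelled
transcript or intron; `assembly_report()` counts models strictly above a
0.95 cut. Regions are defined per TSC–PAC pair from representative
positions (base-level resolution), so alternative-promoter products are
assembled separately by construction. Split tags are not required to show
canonical splice motifs — the evidence is the alignment gap itself.

## The synthetic study

`sim_config()` + `simulate_dataset()` generate the full study: 18
libraries (14 tissues, 4 cell lines) of oligo-dT TSS-PAS pairs, optional
TSS/Random libraries in the three insert-size fractions (0.5–1, 1–2,
2–5 kb), a two-chromosome assembly (so inter-chromosomal fusions are
plantable) of non-overlapping genes with 4–8 exons, up to three
alternative TSSs/PASs per gene in distinct 500-bp bins, planted
preferred couplings at share 0.9, log-normal tissue-biased expression
(per-gene baseline sd 1.5 log2 units, per-library deviation sd 1, a 10%
subset boosted +3 log2 in one tissue to exercise Z > 2), and the three
noise processes at their default rates: 5% truncation (5' tag uniform on
the mRNA), 1% internal priming (3' tag at a planted genomic A-run, so the
QC scan can find it), 1% chimeric re-pairing (whole 3' ends permuted
within a library). Poly(A) signals are planted at 72% of PASs, TATA boxes
at 15% of TSSs and CpG islands at 60% — the frequencies the scans are
expected to report back.

What the generator does **not** emulate: sequencing errors on bases, PCR
duplicates, fragment GC bias, overlapping genes, gradual promoter shapes
(every site is a point), and a realistic gene count. The last matters for
one experiment: with only hundreds of genes, a realistic expression
dispersion concentrates a large share of each library on a few genes, so
1% chimeras between the two most expressed genes can exceed 5 ppm — a
regime the real data (10^4 expressed genes, shares ≤ ~1%) never enters.
The fusion-calibration experiment therefore flattens expression
(`expr_base_sd = 0.2`) to keep per-gene-pair chimera expectations far
below the threshold, which is the regime the screening logic relies on.
Passing tests consequently show that the *rules* behave as designed in
their intended regime, not that desk-scale simulations reproduce the
published tallies, which derive from the deposited sequencing data.

Planted fusions are emitted deterministically at
`max(1, round(ppm × 1e-6 × depth))` supporting pairs per library: at
desk-scale depths a Poisson draw around a fractional expectation would
often plant nothing, making recovery experiments meaningless; at depths
≥ 10^5 the rounding is exact and ppm calibration unaffected.

## Numerical choices and degenerate inputs

Coordinates are 0-based half-open throughout; a PAS tag's position is the
last transcribed base. Poisson and hypergeometric tails come from R's
`ppois`/`phyper` (exact to ≤ 1e-12 relative error in the tested range) and
are cross-checked in the test suite against term-wise summation oracles
that avoid those functions. Modal-position and argmax ties resolve to the
smallest coordinate; tied matrix maxima disqualify a cell from preference;
1×1 pair matrices get p = 1 (no alternative pairing exists); empty tag
sets cluster to empty tables, while empty cluster sets in a comparison are
an error (the fraction is undefined). The ppm pseudocount for Z-scores is
1 ppm; the fold-density pseudocount is 1e-9 with 50-bp bins (neither is
dictated by the method; both are configurable).

## Problem sizes used by the validation experiments

The `eval_*()` functions (also run by `scripts/acceptance.R`) use: 200
genes × 18 libraries × 12,000 pairs/library for independence calibration
(smallest cell expectations ≥ ~5, so discreteness barely bites); 200 genes
× 16,000 pairs/library for preferred-pair recovery (every planted unit
carries ≥ 50 pairs, the regime the selection thresholds assume); 100 genes
× 2,000 pairs/library for cluster screening (≥ 100 tags/gene); 20
replicates of 500 genes × 4 libraries × 200,000 pairs for fusion
recovery/false calls; 20 tiled genes plus 1,000 random instances for
assembly. These sizes were chosen once, on the statistical grounds given
above, as the package's own desk-scale rendering of the study conditions.

## Known limitations

Grid clustering splits boundary-straddling clusters; assembly does not
deconvolve isoforms sharing one TSC–PAC; the TATA consensus is a stand-in
for matrix scanning; GO enrichment takes a flat term-to-gene map (no DAG
propagation); the connected-unit gap is measured between annotated gene
bodies, so unannotated intervening genes are invisible; and the
pair-independence test's estimated-marginal mode is conservative, as
documented above.
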