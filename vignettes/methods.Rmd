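---
title: "Models and methods behind piezoregulon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind piezoregulon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piezoregulon)
```

piezoregulon analyses how hydrostatic pressure reshapes gene expression in
*Thermococcales*, and how much of that response is attributable to promoters
carrying binding sites of known regulators, above all SurR — the ArsR-type
master switch of sulfur/hydrogen electron flow that binds GTT*n*₃AAC (short)
and GTT*n*₃AAC*n*₅GTT (long) motifs. This vignette records the models the
package implements, the defaults and why they were chosen, and what the
synthetic benchmark does and does not establish.

## Promoters

A promoter is defined operationally as the `promoter_length` (default 200)
bases immediately upstream of the annotated start codon, on the coding
strand, its 3' end abutting the first codon base. Three design points were
genuinely open:

* **No masking.** Promoters may overlap upstream CDS or other promoters. In
  a gene-dense archaeal genome (median intergenic gap on the order of 100
  bp) most 200-bp windows do overlap something; masking rules vary between
  studies and any choice removes real binding sites, so the literal window
  is used.
* **Truncate, don't skip.** A gene starting 50 bp from the contig edge gets
  a 50-bp promoter flagged `truncated`; a gene starting at position 1 gets
  an empty one. Dropping such genes would silently shrink the analysis
  universe.
* **Linear contigs.** Archaeal chromosomes are circular, but assemblies are
  linear strings and coordinates near the origin are assembly artefacts
  anyway; no wrap-around is attempted.

Annotations are trusted: start codons are not validated (a warning is
emitted if a CDS does not begin ATG/GTG/TTG, as happens with annotation
slippage or rare initiators). For multi-segment CDS, the segment containing
the start codon (lowest start on `+`, highest end on `-`) anchors the
promoter.

## Gapped motif scanning

Patterns are ordered conserved blocks separated by fixed-length wildcard
gaps, written `GTTn{3}AACn{5}GTT`. A window matches when its conserved-block
positions carry at most `max_mismatch` mismatches; gap positions match
anything; an `N` in the genome never matches a conserved position (an
ambiguous base is no evidence of a binding site). The default budget is 0;
hits with exactly one mismatch form the separate "mutated motif" report and
are excluded from regulon membership by default, since a mutated site's
affinity is unknown without an EMSA.

Both strands are scanned by default and reverse-strand hits are mapped back
to forward offsets. The short SurR motif is its own reverse complement, so
for it both-strand scanning changes nothing — a property the test suite
verifies exhaustively over all 4⁹ nine-mers. A window matching on both
strands is reported once, on the promoter strand.

**Distances.** The reported distance is the 1-based position of the motif's
5'-most base counting back from the base immediately preceding the start
codon (`distance_from = "5prime"`; a motif filling the promoter's last
*span* bases has distance = *span*). Published tables rarely state their
anchor; the convention here is self-consistent and switchable
(`"3prime"` anchors at the motif's 3'-most base instead).

**Nested hits.** Because the long motif begins with a complete short motif,
every long hit contains a short hit at the same offset. `scan_promoters()`
reports both, which is the honest raw scan; `collapse_nested_hits()` removes
hits fully contained in a longer pattern's hit, which reproduces the
occurrence-count convention of published motif tables (a composite site
counted once, under the long motif).

**Chance hits.** On an i.i.d. uniform 200-mer the short motif has
192 windows × 4⁻⁶ ≈ 0.047 expected hits (6 conserved positions; palindromy
means both-strand scanning adds none). The suite checks the empirical rate
on 10,000 random promoters against this analytic value; it is also the
yardstick for how many motif-bearing promoters in a real genome are expected
by chance alone (≈ 4.6% of promoters).

## Normalization

* **TPM** for visualization and cross-sample comparison: counts divided by
  gene length in kb, each sample rescaled to sum to 10⁶. Invariant to
  per-sample count rescaling; columns sum to 10⁶ by construction.
* **RLE / median-of-ratios size factors** for testing: per-gene geometric
  means across samples form a pseudo-reference; a sample's factor is the
  median ratio to it. Genes with any zero count are excluded from the
  median (the log-geometric-mean convention); factors are rescaled to
  geometric mean 1 so fitted means stay on the counts scale. On simulated
  data with planted log-uniform [0.5, 2] distortions and 2,000 genes, the
  planted factors are recovered within 5%. The estimator assumes most genes
  are not differentially expressed; fixtures that violate this by design
  (every gene planted) supply their known factors instead.
* **Low-expression filter**: keep genes with CPM ≥ 1 (raw library sizes) in
  at least 3 samples — one full replicate group in the 3 × 3 design. The
  threshold is the field's standard practice; both knobs are exposed.

## Negative-binomial differential expression

The test is deliberately simple enough to state completely:

1. **Dispersion.** Per gene, method of moments on size-factor-normalized
   counts within each condition, `α̂ = max(0, (s² − m)/m²)`, averaged across
   conditions. A trend `α(μ) = a₀ + a₁/μ` is fitted by least squares over
   genes with positive moment estimates, and the final dispersion is
   `0.5·trend + 0.5·moment`, floored at 10⁻⁸. With 3 replicates the moment
   estimator is very noisy; the 50% blend borrows strength across genes the
   way mainstream NB pipelines do, without their additional machinery.
2. **Effect and test.** Condition level `q_c` = mean normalized count +
   0.5 pseudocount (keeps all-zero genes finite: log2fc = 0, p = 1);
   `log2fc = log2(q_B/q_A)`; delta-method variance
   `Var(ln q_c) = (1/n_c²) Σ_j (1/(s_j q_c) + α)`; two-sided normal p-value
   on the Wald ratio.
3. **Calls.** Benjamini–Hochberg adjustment across genes; a gene is called
   in a direction when adjusted p < `alpha` (default 0.01, the strict 1%
   rule; 0.05 is a config option).

Calibration on simulated data (fixed seeds, sizes noted): null raw p-values
at 5,000 genes give a KS distance from uniform below 0.05 and a type-I rate
in [0.03, 0.07]; with 10% planted 4-fold changes the realized FDR at
alpha = 0.01 stays below 0.05 across 20 seeds × 3 contrasts (1,000 genes
each); dispersion recovery brackets the truth for Poisson (α → 0) and
NB (α = 0.1) data.

**Precision limit worth knowing.** With *n* = 3 replicates the sampling sd
of the log2 fold-change estimate is bounded below by
`sqrt(2α/n)/ln 2` — about 0.26 log2 units at α = 0.05 and 0.37 at α = 0.1 —
no matter how high the counts. Per-gene effect estimates within ±0.3 of the
truth can therefore be expected for only ~73% of genes at α = 0.05, a
consequence of the design, not the estimator: the estimate is unbiased
(mean error ≲ 0.01) and the suite asserts exactly the analytically
predicted recovery fraction.

**Clustering.** `zscore_cluster()` standardizes each gene to mean 0/sd 1
(zero-variance genes dropped), then clusters samples agglomeratively with
Euclidean distance and average linkage (UPGMA). Sample columns are taken in
sorted order so leaf order is deterministic; heights match a brute-force
O(n³) agglomeration in the tests. PCA (`plot_sample_pca()`) is a diagnostic
only — no outlier removal is performed.

## Regulon summaries

* `expand_locus_range()` expands compact cluster notation
  (`A7C91_RS04230-04165`) by the annotation's uniform tag increment
  (default 5), zero-padded to the first endpoint's width, descending ranges
  and dropped leading zeros allowed; a non-multiple span is a hard error
  because it signals the wrong step. The bundled hydrogen/sulfur cluster
  table expands exactly to its recorded CDS totals.
* `overlap_stats()` reports counts plus percentages rounded half-up to one
  decimal (integral values print without a decimal, matching the usual
  "8 and 8.7%" style). The "pressure-regulated" set is by default the union
  of significant genes over the three pairwise contrasts — the most
  inclusive reading, documented here because other rules (per-contrast,
  intersection) are defensible too.
* `cluster_summary()` renders a zero as `"nd"`, interpreting "not detected"
  as "no member called in that direction" — every populated cell in such
  tables is a positive count.
* `ease_score()` is the conservative enrichment statistic: the one-tailed
  Fisher/hypergeometric upper tail after removing one hit from the
  list-hits cell (floored at 0, original margins kept), so a single-gene
  overlap can never be significant and the penalized p is never smaller
  than the plain Fisher p. `enrichment_score()` is −log₁₀ of the geometric
  mean of member EASE p-values; a score above 1 means the group's
  geometric-mean p is below 0.1. Term membership tables are user-supplied;
  no ontology database is bundled or queried.

## The synthetic benchmark

`generate_genome()` emulates the target study's genome scale: ~2,000
strand-mixed CDS on one contig, log-normal CDS lengths (median 900 bp,
clamped to [150, 6000], codon-multiple), geometric intergenic gaps
(mean 120 bp), locus tags incrementing by 5, and motifs planted in a
Bernoulli(0.08) subset of promoters at distances uniform on
[span, 200] — planting overwrites background bases so coordinates stay
stable, and flanks are widened so planted promoters are never truncated and
never overwrite each other. `generate_counts()` draws
`NB(mean = s_j · μ_i · 2^(Δ_ij), dispersion α)` with log-normal baselines
(meanlog 4, sdlog 1.5), log-uniform [0.5, 2] size factors, 10% planted
|log2fc| = 2 effects with random sign in one random condition, for 3
conditions × 3 replicates. All randomness flows from the single `seed`.

What it deliberately does not model: operon structure and shared promoters,
GC/codon composition, positional bias of binding sites, read-level noise
(counts are drawn directly, there is no FASTQ stage), sample swaps or batch
effects, and dispersion that varies with condition. Passing tests therefore
demonstrate correctness of the arithmetic and calibration of the statistics
under the stated generative model — not robustness to the full messiness of
real RNA-seq, where normalization and dispersion estimation carry most of
the practical risk.

Test problem sizes were chosen so the default suite completes in a few
minutes: genomes of 50–2,126 genes, count matrices of 500–10,000 genes, 20
seeds for the FDR study. The acceptance script scales the same analyses to
a 2,126-CDS genome — the size of the real assembly it emulates.

## Known limitations

* Pairwise two-group contrasts only; no GLM covariates, no likelihood-ratio
  tests, no multi-factor designs.
* No indel-tolerant motif matching: a published composite site with a
  deletion inside the motif will only surface via the mismatch report if it
  still aligns block-wise.
* The mutated-motif report covers substitutions in conserved blocks only.
* EASE operates on user-supplied term tables; fuzzy annotation clustering
  (kappa-based seeding of term groups) is out of scope.
* The NB Wald test is anticonservative in principle for very low counts and
  n = 2 replicates; the shipped calibration checks cover the 3-replicate,
  moderate-count regime the pipeline targets.
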