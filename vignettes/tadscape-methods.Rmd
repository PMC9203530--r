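---
title: "Models and methods behind tadscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tadscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadscape)
```

`tadscape` is an analysis layer for chromatin spatial organization in large
plant genomes. This vignette is the package's own account of the models it
implements, the parameters that matter, what the synthetic-data generators
emulate, and where the design was genuinely open and a choice had to be
made.

## Coordinates and containers

All coordinates are 0-based, half-open; the bin index of a position is
`floor(pos / bin_size)`. A `genome_layout` fixes chromosome names, lengths
and one bin size; everything binned (contact matrices, tracks, expression)
refers to it. Contact matrices are per-chromosome dense symmetric matrices
wrapped with masking and balancing metadata; every other object is a plain
tibble, so results compose with dplyr verbs.

## Contact-map statistics

**Balancing.** Iterative correction (Sinkhorn-style): per-bin weights are
updated by `b <- b * sqrt(rowsum / mean(rowsum))` until unmasked row sums
agree with their mean to a relative tolerance (default `1e-5`, maximum 200
iterations; non-convergence returns the best iterate with a warning). Bins
with zero marginal, plus the bottom 1% of non-zero marginals, are masked —
standard Hi-C practice for unmappable or low-coverage bins. Balancing
preserves symmetry and the zero pattern; the balanced matrix is rescaled to
the input total so counts stay interpretable. An exact Knight–Ruiz solver
would converge faster but to the same doubly-balanced matrix (it is unique
up to scale for a symmetric non-negative matrix), and every downstream
statistic here depends only on that structure.

**Observed/expected.** Each entry is divided by the mean over unmasked
entries at the same diagonal offset of the same chromosome. Offsets with
zero mean are undefined (`NA`), not zero. O/E is invariant to global
rescaling of the input.

**Distance profile.** The long/short contact ratio is the summed contacts at
distance > 20 Mb over the sum at ≤ 20 Mb. The diagonal (offset 0) is
excluded from the short-range sum: self-ligation artifacts dominate it and
its inclusion would compress the ratio. Whether the ratio should use raw or
balanced counts is not settled; both work (the function takes either), and
the ratio is invariant under symmetric duplication of entries. Cross-sample
comparison of per-chromosome ratio vectors uses a paired two-sided Wilcoxon
signed-rank test.

## Compartments and subcompartments

A/B labels come from PC1 of the covariance of the Pearson correlation matrix
of O/E. The sign of an eigenvector is arbitrary, so orientation is automated
with a track: the sign is chosen so that bins with positive PC1 have the
higher mean gene density, which makes `A` the gene-rich side. Flipping the
orientation track provably flips all labels; bins masked during balancing
stay unlabeled.

The eight ranked subcompartments (A1.1 = rank 8 down to B2.2 = rank 1) are
produced by *recursive PC1 bisection*: level 1 is the A/B split; inside each
part the correlation submatrix is re-decomposed and split again, each
sub-split oriented by the same track, to 4 and then 8 parts. This is a
declared simplified stand-in for likelihood-based nested clustering: it
produces the same label vocabulary and rank semantics, which is all the
downstream statistics (enrichment by rank, rank-shift switching tables)
consume. Two open points were settled as package choices: the rank order
within each split follows the mean orientation-track value (higher track →
higher rank), mirroring the association of rank with gene/activity content;
and a part too small to split (< 2 bins, or with a degenerate PC1) inherits
the top rank of its parent's range rather than failing.

Per-label enrichment is `log2(median(track | label) / median(track | all))`
with a `1e-9` pseudocount guarding zero medians, so it is invariant to
positive rescaling of the track. Switching tables tabulate per-bin rank
shifts into `{<-2, -2, -1, 0, 1, 2, >2}` and also report the level-1 A/B
agreement fraction.

## Domains, classes and boundary profiles

**Calling.** The per-bin insulation-style signal is the mean contact in the
`window_bins × window_bins` submatrix straddling the diagonal (upstream rows
× downstream columns, clipped at ends). Boundaries are local minima whose
depth below the lower of the two nearest flanking local maxima exceeds
`min_drop` of that maximum — a ratio criterion, so calls are invariant to
global scaling. Defaults `window_bins = 5`, `min_drop = 0.1` at 40-kb bins
recover planted domains at fold ≥ 1.5 in simulation (the test suite pins
fold 2 at full recovery ± 1 bin). Runs of ≥ `window_bins` masked bins split
domains as gaps. The caller is deliberately a single simple method: domain
callers are a crowded tool space, and the package's contribution is the
comparison and classification layer, which also accepts external BED calls.

**Comparison.** Domain bodies are conserved at > 80% *reciprocal* overlap
(both lengths), matched greedily by overlap, ties leftmost. Boundaries are
single bins; two boundaries match when their intervals overlap or the
edge-to-edge gap is strictly less than one bin size. Coverage similarity is
base-pair Jaccard, computed with IRanges interval arithmetic and verified
against per-bp brute force in tests.

**Classification.** Per-domain mean feature values (TE/gene density, overall
methylation, H3K4me3, H3K9me2, H3K27me3) are z-standardized per feature,
clustered by complete-linkage on Euclidean distance, and cut at k = 3.
Groups are auto-labeled from their diagnostic z-means: highest mean
gene + H3K4me3 → `active`; of the rest, highest LTR + H3K9me2 → `HDF`;
remainder → `inactive`. The group means are returned so a user can audit the
labeling. Per-domain features are means (not sums) of bin values — sums
would confound class with domain length.

**Boundary profiles.** For each offset in ±`flank_bp` (default 500 kb), the
mean ± SE of a track over all boundaries; boundaries near chromosome ends
contribute only their in-genome offsets.

## Loops

Loops enter as BEDPE. Merging across resolutions groups loops transitively
when both anchor-midpoint distances are within 25 kb; each group is replaced
by the anchor-midpoint medians snapped to the finest contributing resolution
grid, which makes the operation idempotent. Sharing between tissues uses the
same 25-kb both-anchor rule against loops of *other* tissues. The
anchor–boundary association reports the anchor fraction on boundary bins,
the chance expectation (boundary-bin share of the genome), a two-sided
Fisher's exact test on the 2×2 bin table, and — because the chance
calculation for the reciprocal "domains with anchored boundaries" statistic
could be done analytically or by shuffling, and the right choice is not
obvious — both an analytic expectation and a seeded uniform-placement
permutation null (default 1,000 replicates).

## Variants, synteny breaks and enrichment

**QV.** `−10·log10(variant sites / covered sites)`; zero variant sites is
capped at QV 99 rather than infinity.

**Variant profiles.** Sliding 40-kb windows at 5-kb steps within ±500 kb of
boundary midpoints. Observed is the summed SNP count (or deletion-covered
bp) over boundaries; expected assumes homogeneity: genome-wide density times
summed in-genome window bp. Windows clipped at chromosome ends shrink the
expectation proportionally — the homogeneity assumption is silent on edges,
and proportional clipping is the only choice that conserves totals.
Insertions are excluded throughout (they are unreliable between draft plant
assemblies). Observed and expected are summed (not averaged) across
boundaries; under homogeneity the ratio is identical either way.

**Break detection.** Reference-sorted blocks chain when they share query
chromosome and strand, keep query-order consistency, and have reference and
query gaps ≤ 100 kb; chains under 10 kb are dropped (both exposed). A break
is emitted at the reference midpoint between consecutive chains that differ
in query chromosome or strand or violate collinearity — a gap alone is not a
break. Overlapping reference blocks resolve to the longer with a warning.
Detection is invariant to splitting a block into abutting collinear pieces.

**Break enrichment.** Breaks map to the relative position within their
domain, histogrammed into `n_rel_bins` (default 10) cells; each cell is
divided by the mean alignable fraction of the genomic bins mapping to it —
this removes the bias that boundary-proximal sequence is more alignable,
which would otherwise manufacture enrichment. The observed statistic is the
normalized count in the two terminal (boundary-proximal) cells; how many
cells count as "boundary" is not canonical, so the cell count is a
parameter. The null re-places the same number of breaks on bins with
probability proportional to alignable fraction, 100 seeded replicates by
default; the empirical p uses the add-one rule `(1 + #{null ≥ obs}) /
(n_perm + 1)`, which cannot return 0 at finite replicates. Calibration is
tested: on null-generated breaks, the test rejects at the nominal 5% rate.

## Methylation, coverage, expression

A cytosine is *heavily methylated* when methylated reads are ≥ 25% of its
mapped reads; a bin's level is the percentage of heavy sites among its
covered sites, per context. The "overall" level pools the sites of all three
contexts before applying the rule — pooling keeps the result a bounded
percentage with the same semantics, whereas summing three percentages would
not; this reading of the sum rule is the package's choice, and pooled levels
provably lie within the per-context range at equal site counts. Bins with no
covered sites are `NA`, distinct from 0, and are omitted from bedGraph
export. Coverage tracks assign each fragment to the bin of its midpoint
(read-count semantics at bin scale), scaled to CPM.

Expression: CPM per sample, tissue values as replicate means, testable bins
at tissue-mean CPM strictly > 0.5. Tau is `Σ(1 − r_i)/(n − 1)` with
`r_i = x_i / max(x)`: 0 for uniform, 1 for single-tissue expression, and
monotone under decreasing any non-max value. Fold-change classes use a 0.25
CPM pseudocount on both sides of the ratio — bins passing the CPM filter can
still have a zero in one tissue, and the pseudocount (exposed as a
parameter) keeps ratios finite; `up`/`down` are strict twofold exceedances,
everything else `stable`. Conserved-vs-specific comparisons use a one-sided
Wilcoxon *rank-sum* test (the groups are unpaired bin sets; a paired
signed-rank option exists for matched designs).

## The synthetic-data generators

The generators exist so every stage is testable with known truth; their
defaults define the package's reference study conditions.

- **Contact maps**: Poisson counts around
  `mean_depth · (|i−j|+1)^(−α) · fold^[same domain] · loop_fold^[anchor pair]`.
  This is the simplest generative model whose O/E has a closed form, so
  recovery tests compare against analytic expectations rather than fitted
  ones. Defaults: α = 1, domain fold 2, loop fold 3, depth 50, 2% of bins
  zeroed as gaps to exercise masking.
- **Tracks**: class-conditional normals with the directionality expected of
  plant chromatin (active: gene/H3K4me3 high; HDF: LTR/H3K9me2 high;
  inactive: methylation high); methylation fractions clamped to [0, 1], the
  overall track the mean of the three contexts.
- **Variants**: homogeneous Poisson positions thinned by the depletion
  factor within a half-width of boundary midpoints; deletion lengths
  geometric with mean 300 bp — long enough to span windows, short enough not
  to dominate any.
- **Synteny blocks**: abutting blocks split exactly at planted break
  positions, query identity switching across each break, per-block alignable
  fraction from a user profile of relative domain position.
- **Expression**: negative-binomial counts, library sizes varying ≤ 2-fold,
  a fraction of bins with one tissue up-shifted. Defaults `base_mean = 100`,
  `size = 20`: a 40-kb bin pools reads over many genes, so per-bin counts
  run high and replicate-averaged tissue means are only mildly
  overdispersed; under these conditions the null (no planted effect) yields
  mean tau below 0.2, i.e. the index reads "unspecific" where nothing was
  planted.
- Domain sizes per class (means 8/15/20 bins for active/inactive/HDF) are
  exposed parameters: real per-class size distributions are not pinned
  beyond HDF domains running large, so the generator takes means rather than
  fixing shapes.

What the generators do *not* emulate: restriction-fragment resolution
effects, the Rabl anti-diagonal signal of some plant tissues, trans
contacts, correlated noise between adjacent bins, read-level artifacts.
Passing recovery tests therefore demonstrates the statistics are implemented
correctly and calibrated under their stated assumptions — not that any
particular biological effect size will be observed in real tissue.

## Numerical choices and degenerate inputs

- Balancing tolerance `1e-5` relative on row sums; masked bins carry `NA`
  weights.
- Degenerate PC1 (zero variance) is an error at the top level and a
  stop-subdividing condition inside the bisection.
- Greedy matching (domains: by overlap, boundaries: nearest-first) breaks
  ties leftmost, so results are permutation-stable.
- Empty inputs: empty loop/boundary sets yield `NA` fractions with a
  warning, all-masked chromosomes an empty domain call, all-zero expression
  vectors `NA` tau.
- The pipeline forks one global seed per stage by hashing the stage name
  (kept under 2^31), so stages are reproducible independently and the
  summary JSON is byte-identical across same-seed reruns.

## Problem sizes

The bundled demo configuration is two 20-Mb chromosomes at 40-kb bins (1,000
bins), 100 permutations, five tissues × three replicates — small enough to
run interactively in seconds while leaving every statistic's sampling error
well inside the test tolerances. All thresholds are echoed into the run
summary so a run is self-describing.

## Limitations

- The subcompartment caller is a stand-in: it shares the rank semantics but
  not the likelihood machinery of nested-clustering methods, and agreement
  with them on real data is not claimed.
- The domain caller is one insulation-style method; on real maps users may
  prefer importing calls from dedicated tools (supported via BED).
- Only intra-chromosomal analysis; no inter-chromosomal normalization.
- Loop detection, read alignment, differential-expression model fitting and
  genome assembly are out of scope by design.
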