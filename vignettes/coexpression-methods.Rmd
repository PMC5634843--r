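---
title: "Methods: from read counts to co-expression clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from read counts to co-expression clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexnet)
```

# Overview

`coexnet` turns gene models and per-sample RNA-seq read counts into
normalized expression matrices, Pearson co-expression networks, and
Markov-cluster (MCL) gene modules, with sample quality control and
network diagnostics along the way. This vignette explains the models and
procedures each stage implements, the parameters that matter, and the
design choices made where more than one reasonable convention exists.

# Gene models and lengths

TPM and RPKM both divide by a gene length, so the first stage derives
one length per gene from a GFF3 annotation. Because downstream counting
only accepts reads that map unambiguously to a single gene model,
annotations with multiple splice isoforms per gene would reject every
read falling on sequence shared between isoforms. `select_representative()`
therefore keeps a single representative transcript per gene: the one
whose coding-segment union is longest. Two conventions are fixed here:

* **Overlap merging.** Segments of the representative transcript are
  merged before summing, so a base covered by two overlapping CDS rows
  counts once in the normalization denominator. Double-counting would
  silently deflate the expression of genes with redundant annotation
  rows.
* **Tie-breaking.** When two isoforms tie on merged length, the
  lexicographically smallest transcript id wins, making builds
  reproducible regardless of file order.

The feature type collected defaults to `"CDS"`; annotations without CDS
rows can use `"exon"`. Coordinates are handled in GFF3's 1-based
inclusive convention end to end.

# Union-mode read counting

`count_sample()` classifies each primary SAM record with a fixed
precedence: unmapped records (`not_aligned`), then multi-hit records by
the NH tag (`alignment_not_unique`), then records under the MAPQ cutoff
(`too_low_quality`, cutoff 10 by default, the HTSeq convention), and
finally the union-mode overlap test: the set of genes whose
representative segments overlap any M/=/X block of the alignment must
have size exactly one, otherwise the read is `no_feature` (zero genes)
or `ambiguous` (two or more). N and D CIGAR operations split or extend
blocks on the reference and contribute no aligned bases.

Every record lands in exactly one bucket, so gene counts plus the five
special counters always equal the number of primary records — a
conservation identity the `count_result` constructor enforces and the
test suite checks on every fixture. Two simplifications are deliberate:
mates of a pair are counted as independent records (fragment-level
pairing is out of scope), and strand handling defaults to unstranded
because public compendia mix library protocols; `forward` and `reverse`
modes are available when the protocol is known.

# Normalization

With counts `c(g,s)`, lengths `L(g)` (bases) and per-sample assigned
totals `N(s)`:

* **RPKM:** `c(g,s) * 1e9 / (L(g) * N(s))`.
* **TPM:** length-normalized rates `c(g,s)/L(g)` rescaled so each
  sample's values sum to one million.

`N(s)` is the sum of gene-assigned counts, not total mapped reads: it is
the only total recoverable from count files alone. Tools that divide by
total mapped reads will report slightly smaller RPKM values; comparisons
should use one convention throughout. TPM columns summing to `1e6`
(relative tolerance `1e-6`), the identity TPM = column-renormalized
RPKM, and invariance of TPM to doubling a sample's depth are all tested
properties. Matrices serialize as TSV with a `# normalization:` header
and six significant digits; full precision is kept in memory.

# Quality control

Two per-sample metrics flag problematic samples: the overall genome
mapping rate parsed from the mapper's own summary (TopHat2
`align_summary.txt` or HISAT2 stderr), and the coding fraction
`100 * assigned / (total - not_aligned)`. The mapped denominator keeps
ambiguous, low-quality and multi-mapped records: they did align to the
genome, they simply were not assignable to one coding gene. Defaults
warn strictly below 65% (genome) and 40% (coding). Flagged samples are
*reported, never removed* — rRNA-depleted or tissue-mixture samples can
fail these screens while remaining biologically informative, so
exclusion (`drop_samples()`, or the pipeline's `exclude_flagged` switch)
is always an explicit user decision.

# Co-expression networks

Correlations are computed on the TPM matrix (a warning is raised for
other normalizations). Each profile is centered and unit-normalized
once; the correlation matrix is then assembled from blockwise
cross-products. The block size (default 1000 genes) bounds peak memory
and is contractually invisible: every block split yields bitwise
identical results, which the suite verifies against a naive per-pair
two-pass oracle at `1e-10`. Genes with zero variance have undefined
correlations and are excluded with a logged reason rather than emitting
NaNs.

Three derived products follow:

* **Neighbor table** — for each gene the `k` (default 1000) strongest
  co-expressed partners by *signed* correlation. Ranking by absolute
  value was rejected: co-expression means coordinated expression, and
  anti-correlation is a distinct phenomenon a user should query
  separately.
* **Global network** — all pairs with correlation strictly above the
  cutoff (default 0.7, the usual recommendation when the network feeds
  MCL). Boundary values equal to the cutoff are excluded; edge counts
  are therefore non-increasing in the cutoff.
* **Neighborhoods** — the induced subgraph around a query gene at a
  (usually stricter, e.g. 0.925) cutoff, for focused visualization.

# Markov clustering

`mcl_cluster()` implements MCL directly: build the weighted adjacency
from the edge list, add self-loops, column-normalize to a stochastic
flow matrix, then alternate expansion (matrix squaring), inflation
(entrywise power `r`, columns renormalized) and pruning (entries below
`1e-5` zeroed) until the largest entry change drops below `1e-6` or 100
iterations pass. Clusters are the attractor systems of the limit matrix;
each node joins the system holding the largest share of its column's
flow, with ties resolved toward the smaller cluster index so the result
is always a partition.

Parameter choices, none of which the upstream workflow literature pins
down, are the canonical ones: inflation 2.0 (larger values fragment
clusters, and the suite checks cluster counts are monotone in
inflation), expansion fixed at 2, and self-loop weight 1.0 — equal to
the maximum possible correlation weight, which guarantees aperiodicity
without letting the loop dominate any real edge. If pruning ever leaves
a column empty, the node is pinned on itself and emerges as a singleton;
singletons are kept as size-1 clusters with an export flag to drop them.
A dense-matrix implementation is used deliberately: thresholded
co-expression networks at desk scale (thousands of nodes) fit easily,
and sparsity would be an invisible optimization.

# Diagnostics

* **Degree distribution and power law.** Co-expression networks are
  typically scale-free: node frequency falls off as a power of degree,
  a straight line in log-log space. `fit_power_law()` is an ordinary
  least-squares fit on `(log10 k, log10 f)` over observed degrees — a
  straight-line diagnostic, not a maximum-likelihood exponent estimate
  (Clauset-style fitting with cutoff estimation is out of scope). Raw
  OLS on heavy-tailed samples is biased by sparsely populated tail bins,
  so the simulation used to validate exponent recovery draws 2000
  degrees over support 1..15, where every bin's expected count is large
  enough for the line to be meaningful; there the fitted slope recovers
  a planted exponent of −2.5 within ±0.3.
* **PCA.** Values are transformed `log2(x+1)` (stabilizing the
  right-skewed TPM scale), genes centered across samples, samples
  projected by SVD. Component signs are fixed so the largest-magnitude
  gene loading is positive, making coordinates deterministic across
  platforms.
* **Sample dendrogram.** Distance `1 - PCC` between `log2(x+1)` columns
  with average linkage; zero-variance samples (undefined correlation)
  are flagged and appended after the clustered leaves. Exported as
  Newick.

The `log2(x+1)` transform, gene centering, OLS log-log fit, and
`1 - PCC`/average-linkage distances are this package's concrete choices
where the upstream methods are not fully specified; each is stated here
so results can be reproduced or deliberately varied.

# Synthetic data: what it emulates and what it does not

`generate_modular_counts()` emulates a bulk RNA-seq compendium with
planted co-expression modules. Per module `m`, a latent per-sample
activity `a_m(s) = exp(N(0, activity_sd))`; per gene, a log-normal
baseline (`meanlog log(100)`, `sdlog` 1 — a realistic right-skewed mean
expression distribution); module-gene means `baseline * a_m(s) *
library_scale(s)`, background means `baseline * library_scale(s)`;
counts negative-binomial with variance `mean + mean^2/dispersion`.
Activity is multiplicative on the shared baseline precisely so TPM
(which removes the library scale) preserves the planted correlation
structure. Defaults — 5 modules × 40 genes, 200 background genes, 60
samples, `activity_sd` 1.5, dispersion 10 — describe a small but
realistic compendium in which module recovery is a meaningful benchmark:
at these settings within-module TPM correlations average ≈ 0.85 while
module-to-background correlations sit near zero (slightly negative, a
genuine compositional effect of the shared TPM denominator).

What the generator does *not* emulate: sequencing error, splice-aware
alignment ambiguity, batch effects, GC or length bias, and tissue-level
mean-variance structure. Passing the recovery benchmark therefore shows
the pipeline's inference machinery is sound, not that real compendia of
this size will yield equally clean modules.

`generate_sam_fixture()` constructs reads that fall into each counting
category *by construction* (placement inside exactly one gene, spliced
placement spanning two genes, placement beyond all annotation, unmapped
flags, NH:i:2 tags, MAPQ 0) and returns the exact expected
`count_result`, giving an end-to-end oracle for the counter.
`generate_qc_fixture()` emits parseable mapper summaries and count
results hitting requested QC percentages to one decimal (counts are
built over 1000 mapped records, so tenths of a percent are exactly
representable).

# Pipeline

`run_pipeline()` executes lengths → (optional) counting → aggregation →
QC → optional exclusion → TPM/RPKM → correlations → neighbor table →
network → MCL → diagnostics, writing each artifact plus a JSON manifest
under the output directory. Configuration is a two-section INI
(`[paths]`, `[parameters]`); validation reports *every* missing field
and path in one pass rather than failing on the first. A failing stage
halts with its name and leaves earlier artifacts intact; with
`resume = true`, stages whose artifacts exist are loaded rather than
recomputed. All stages are deterministic, so identical inputs give
byte-identical TSV artifacts — a tested contract.

# Problem sizes used in the test suite

The suite exercises the pipeline at deliberately small scales chosen as
the package's own benchmark conditions: 50-gene × 20-sample matrices for
oracle comparisons, 400-gene × 60-sample planted-module compendia
(5 seeds) for recovery, 2000-draw degree sequences for the power-law
diagnostic, and 6–16-node graphs for MCL structure. These sizes make the
properties sharp (exact ground truth, enumerable oracles) while keeping
any single test cheap; nothing in the implementation is specialized to
them, and the block-size and dense-matrix choices above describe how the
same code behaves at compendium scale.

# Known limitations

* Fragment-level paired-end counting and HTSeq's `intersection-strict` /
  `intersection-nonempty` modes are not implemented; mates count twice.
* RPKM's read total is the assigned-read total (see above).
* The power-law fit is a diagnostic, not an estimator; exponents from
  sparse tails are biased toward zero.
* MCL here is the canonical dense algorithm; graphs with hundreds of
  thousands of nodes would need a sparse implementation.
* Between-sample normalizations (TMM, quantile, size factors) are out of
  scope; TPM/RPKM normalize within samples only.
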