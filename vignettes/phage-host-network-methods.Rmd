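---
title: "Methods: structure and sequence sharing in phage-bacteria killing networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure and sequence sharing in phage-bacteria killing networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagenet)
```

## The data model

Everything in this package starts from a binary killing matrix: bacterial
strains as rows, phages as columns, a 1 wherever a phage lysed a strain in an
agar overlay assay. Large environmental surveys of this kind are sparse
(connectance around 0.02), organized into modules of phages and hosts that
interact mostly with each other, carry a weak nested component, and contain
many exclusive one-to-one phage-host pairs. The package implements the
statistics used to characterize that architecture, the host-range concordance
statistic used to relate it to phage taxonomy, exact 25-mer sharing networks
used to relate it to gene flow, and a read cross-recruitment simulation used
to quantify false-positive detection between related reference genomes.

Summary properties follow the conventional symbols: host count $H$, phage
count $P$, interactions $I$, size $M = H \times P$, connectance $C = I/M$,
and mean interactions per host ($L_H = I/H$) and phage ($L_P = I/P$). All
values are held at full precision; `render_properties()` applies the display
convention (2 decimals for $C$, 1 for $L_H$ and $L_P$, half-up) separately so
rounding never leaks into downstream computation. Hosts killed by no phage
are kept by the readers and removed only by the explicit
`filter_to_infected_hosts()` step, because the choice of host panel is an
analysis decision, not a parsing one.

## Bipartite modularity

Barber's bipartite modularity of a joint host/phage partition is

$$Q_b = \frac{1}{I} \sum_{ij} \left(A_{ij} - \frac{k_i d_j}{I}\right)
\delta(g_i, h_j),$$

with $k_i$ the host degree, $d_j$ the phage degree, and the sum restricted to
pairs in the same module. `leading_eigenvector_modules()` maximizes $Q_b$ by
recursive bisection: on each candidate group the modularity matrix
$B_{ij} = A_{ij} - k_i d_j / I$ (degrees always from the full matrix) is
restricted to the group and its leading singular triplet computed; hosts
split by the sign of the left singular vector, phages by the right. Because
the within-split sum equals $(\sum B + s^\top B t)/2$ for side vectors
$s, t \in \{\pm 1\}$, the leading singular pair is the natural relaxation of
the discrete problem. Entries exactly zero are assigned to the positive side
so results are deterministic. An optional Kernighan-Lin pass then greedily
relocates single nodes between the halves, each node at most once per pass,
and keeps the best strictly improving prefix of moves; passes repeat until no
prefix improves. A split is accepted only when the total $Q_b$ strictly
increases, which guarantees the returned partition never scores below the
single-module baseline of 0. The a-posteriori interaction ratio
$Q_r = 2W/I - 1$, with $W$ the interactions falling inside modules, is
reported alongside.

On small matrices the optimum can be computed exactly by enumerating all
joint set partitions; the test suite uses that enumeration as an independent
oracle and requires the spectral + KL search to attain it on at least 90 of
100 random 4x4 matrices. Planted-partition recovery is checked at 30x30 with
3-6 modules, within-block fill 0.8 and background 0.02, where the normalized
mutual information between detected and planted labels must reach 0.9 in at
least 95% of seeds.

## Nestedness and null models

`nodf()` implements nestedness by overlap and decreasing fill: each ordered
pair of rows with strictly decreasing positive degree scores the fraction of
the smaller row's interactions contained in the larger one's, likewise for
columns, and NODF is the total score over the number of row plus column
pairs, reported on [0, 1] (some software multiplies by 100). The
implementation is cross-checked in the tests against `vegan::nestednodf()`
on random matrices.

Significance uses an equiprobable null: each replicate places exactly $I$
ones uniformly at random among the $M$ cells, so connectance is preserved
exactly per replicate while all cells are exchangeable. The exactly-$I$
(hypergeometric) reading was chosen over independent Bernoulli($C$) cells
because preserving overall connectivity per replicate is the stated property
of the ensemble; both agree in expectation. Results carry the ensemble mean
and standard deviation, $z$-score (flagged undefined when the ensemble is
degenerate) and the percentile of replicates at or below the observed value.
Replicate counts are a runtime dial, not a model choice: drivers here use
100-1000 replicates, and the self-consistency test (a matrix drawn from the
null should be unremarkable under it) uses the cheap NODF statistic at 60
replicates over 50 draws.

## Host-range concordance

A phage's killing profile $x$ over $m$ hosts is normalized to
$p = x / \sum_j x_j$ and a group of $n$ phages is scored by the scaled host
range divergence

$$D_h = \frac{H\!\left(\tfrac{1}{n}\sum_i p_i\right) - \tfrac{1}{n}\sum_i H(p_i)}
{\log_2 n},$$

the generalized Jensen-Shannon divergence of the profiles normalized by its
maximum. Entropies are in bits because the $\log_2 n$ normalizer fixes the
base. $D_h = 0$ means identical host ranges, $D_h = 1$ pairwise disjoint
ones; concordance is $1 - D_h$. For $n = 2$ this reduces to the ordinary
Jensen-Shannon divergence. Zero-kill phages have no defined profile and are
excluded before normalization (an error if passed explicitly).

Group analyses run at species or genus level. Genus concordance can be
computed from all members — which weights the many high-overlap within-species
pairs and therefore rises with uneven species abundances — or from one
representative per species, drawn uniformly with an explicit seed since no
selection rule is canonical. Both modes are exposed; the package makes no
claim about which ordering holds in general, only (and testably) that
duplicating members of the most concordant species never lowers group
concordance. Level comparisons use a two-sided Welch test; morphotype
kill-breadth comparisons use equal-variance Student tests (with a defined
degenerate fallback: equal constant samples give $t = 0$, $p = 1$); life
history comparisons use the two-sample Kolmogorov-Smirnov test. The relative
contribution of recombination to mutation is composed as
$r/m = (R/\theta)\,\delta\,\nu$ from externally estimated components — the
estimation itself (conserved-block alignment and recombination inference) is
out of scope and consumed from a table — and groups are tested against
$r/m = 1$ with a one-sample Wilcoxon signed-rank test, exact for $n \le 25$.

## Sequence sharing

`kmer_profile()` stores the exact set of canonical k-mers (lexicographic
minimum of each window and its reverse complement; windows with non-ACGT
symbols skipped), k defaulting to 25. Exact sets are used instead of MinHash
sketches: a sketch large enough to hold every k-mer of the largest genome is
lossless, so the exact intersection is the same quantity without the
approximation machinery. Pair scores are the shared count, Jaccard index,
the Mash-style distance $-\tfrac{1}{k}\ln\tfrac{2J}{1+J}$, and the binary
sharing flag used for networks. Host sharing over phage pairs
(`host_sharing_vector()`) uses the identical pair ordering so the two binary
vectors align, and `binary_mutual_information()` relates them with a plug-in
2x2 estimator in bits — deliberately uncorrected, since the quantity of
interest is the observed association, bounded by 1 bit.

## Cross-recruitment simulation

`simulate_reads()` is a simplified paired-end simulator: uniform fragment
start, Normal outer distance truncated to [2 x read length, genome length],
read 2 reverse-complemented, substitution errors at a flat per-base rate
(0.001 by default; indels and quality models are deliberately omitted as
negligible for k-mer mapping), constant "I" qualities. Defaults are 100,000
pairs of 250 bp reads at outer distance 500 +/- 50. `pseudo_map()` maps a
read when any of its canonical 31-mers occurs in the reference profile — the
defining behaviour of pseudo-alignment — and computes reference coverage as
the union of the reference intervals of matched 31-mers. Since
pseudo-alignment yields no base-level alignment, this k-mer-interval coverage
is an approximation, as is the Lander-Waterman expected coverage
$1 - e^{-\text{mapped reads} \times \text{read length}/L}$ used for the
evenness ratio. Detection requires coverage >= 0.1, observed/expected
>= 0.3 and >= 10 mapped reads, all three simultaneously.

A longer read overlapping a shared segment by at least 31 bases from more
start positions recruits more reads per segment, so references sharing a
single segment with a sequenced genome are called present more often at
250 bp than at 100 bp. The package asserts only this direction, on a fixture
whose shared segment is a large fraction of a short reference so the
coverage and evenness gates are open and the mapped-read gate discriminates;
with tool-specific coverage accounting the magnitude would differ.

## The synthetic study system

`generate_matrix()` plants near-equal module blocks (remainder to the first
blocks, for determinism) filled at `within_fill` against a `between_fill`
background, appends exclusive one-to-one pairs and an optional strict
triangle block (square, strictly decreasing degrees, so its stand-alone NODF
is exactly 1), then shuffles rows and columns. `generate_host_range_groups()`
gives each species a template kill vector — species within a genus share a
controlled core fraction of their hosts — and members flip template bits at a
noise rate (members left with no kills get their template's first host back,
keeping profiles defined). `generate_genomes()` builds one random template
per species, copies it into members at `species_identity`, plants verbatim
transfer segments, and enforces no-flow pools by resampling offending
genomes until cross-pool 25-mer sharing is exactly zero (uniform ACGT
composition; GC content is not modeled). All generators are pure functions
of configuration plus seed.

These generators emulate the statistical skeleton of a real survey — sparsity,
modularity, singletons, species-structured host ranges, within-taxon sequence
identity, planted transfers — but not phylogenetic signal, bloom-driven
abundance structure, receptor genetics, or realistic genome composition.
Passing tests on synthetic data therefore validate the algorithms and their
contracts, not ecological conclusions about any particular data set.

The analysis drivers under `analysis/` run the whole sequence at deliberately
modest sizes (a 78x78 matrix, 24 host-range phages, eight 5 kb genomes,
hundreds of read pairs); every statistic scales to survey-sized inputs
(hundreds of strains, tens of thousands of pairs) in minutes, with the
brute-force partition enumeration — usable only far below 10 nodes — kept
strictly to test oracles.

## Known limitations

- The leading-eigenvector + KL search is a heuristic; on adversarial
  matrices it can return a local optimum (the tests bound this at >= 90/100
  exact hits on small random matrices).
- Coverage in the pseudo-mapper is k-mer-interval based, so absolute
  detection rates are not comparable to any specific read-mapping tool; only
  directions and orders of magnitude are.
- The Wilcoxon test falls back to the normal approximation for n > 25 or in
  the presence of ties, as usual.
- Weighted interaction matrices, LP-BRIM style module detection and directed
  transfer inference are out of scope.
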