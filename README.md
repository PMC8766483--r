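# phagenet

Structure and sequence sharing in phage-bacteria interaction networks.

Large host-range surveys assay hundreds of bacterial strains against
hundreds of phages and record killing as a binary matrix. `phagenet` is an R
package for the statistical anatomy of such matrices and of the phage
genomes behind them, aimed at microbial ecologists working with
phage-bacteria interaction networks (PBINs):

- **Network structure** — summary properties (connectance $C = I/M$, mean
  interactions $L_H$, $L_P$), exclusive one-to-one singleton pairs, Barber
  bipartite modularity $Q_b$ maximized by recursive leading-eigenvector
  bisection with Kernighan-Lin tuning, the a-posteriori interaction ratio
  $Q_r = 2W/I - 1$, NODF nestedness, and equiprobable null-model
  significance ($z$-scores and percentiles against random matrices with the
  same dimensions and exactly the same fill).
- **Host-range concordance** — the scaled host range divergence
  $D_h = \mathrm{gJSD}(p_1, \ldots, p_n) / \log_2 n$ of killing-probability
  profiles, group analyses by phage species and genus (all-members or
  single-representative), Welch/Student/Kolmogorov-Smirnov comparisons, the
  $r/m = (R/\theta)\,\delta\,\nu$ composition with a one-sample Wilcoxon
  test against 1, and Spearman association of concordance with $r/m$.
- **Sequence sharing** — exact canonical 25-mer profiles, pairwise shared
  counts, Jaccard and Mash-style distances, binary sharing networks, and
  mutual information between sequence sharing and host sharing over phage
  pairs.
- **Cross-recruitment** — a simplified paired-end read simulator and a
  31-mer pseudo-mapper with coverage/evenness/read-count detection
  thresholds, for quantifying false-positive detection between related
  reference genomes in metagenomic read mapping.
- **Synthetic data** — seeded generators for matrices with planted modules,
  singletons and nested blocks; taxonomies with species-structured host
  ranges; and genome sets with controlled within-species identity, planted
  transfer segments and no-flow pools. Every pipeline stage is testable
  without any external download.

## Worked example

```r
library(phagenet)

# a synthetic survey: 4 planted modules, 12 exclusive one-to-one pairs,
# a 6x6 strictly nested block, shuffled
gen <- generate_matrix(matrix_gen_config(
  n_hosts = 60, n_phages = 60, n_modules = 4,
  within_fill = 0.55, between_fill = 0.005,
  n_singletons = 12, nested_block = 6, seed = 2026))
m <- gen$matrix

print(matrix_properties(m))
#> H=78 P=78 S=156 I=519 M=6084 C=0.09 L_H=6.7 L_P=6.7

nrow(singleton_pairs(m))
#> [1] 12

part <- leading_eigenvector_modules(m, kl_tuning = TRUE)
print(part)
#> module_partition: 17 modules, Qb = 0.7692, Qr = 0.9807

print(equiprobable_null(m, "qb_max", n_replicates = 200, seed = 42))
#> qb_max: observed 0.7692, null mean 0.3582 (sd 0.0073), z = 56.24, percentile 100.0 (200 reps)
```

The detected modularity (0.77) towers over the equiprobable null
(mean 0.36), the 12 planted singleton pairs are recovered exactly, and the
17 modules are the 4 planted blocks plus the nested block and the 12
singletons. `analysis/01_simulate.R` through `analysis/05_cross_mapping.R`
run this and the host-range, sequence-sharing and cross-recruitment stages
end to end, writing tables under `results/`.

Host-range concordance on a taxonomy-structured system:

```r
tax <- list(g1 = c(s1 = 4, s2 = 4), g2 = c(s3 = 4, s4 = 4), g3 = c(s5 = 4, s6 = 4))
hr <- generate_host_range_groups(tax, n_hosts = 80, kill_breadth = 6, noise = 0.02, seed = 2027)
sp <- group_concordance(hr$matrix, hr$annotations, level = "species")
gn <- group_concordance(hr$matrix, hr$annotations, level = "genus")
compare_levels(sp$concordance, gn$concordance)$p_value
#> [1] 6.65e-05   (species concordance far exceeds genus concordance)
```

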