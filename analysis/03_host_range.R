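#!/usr/bin/env Rscript
# Step 3: host-range concordance by species and genus, the level comparison,
# and the recombination/concordance statistics on the simulated r/m table.

suppressPackageStartupMessages(library(phagenet))

m <- read_interaction_matrix("results/sim_hostrange_matrix.tsv")
ann <- read_phage_annotations("results/sim_annotations.tsv")

sp <- group_concordance(m, ann, level = "species")
gn_all <- group_concordance(m, ann, level = "genus", mode = "all_members")
gn_rep <- group_concordance(m, ann, level = "genus",
                            mode = "single_representative", seed = 7)
conc <- rbind(sp, gn_all, gn_rep)
write.table(conc, "results/concordance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("species concordance: mean %.3f over %d groups\n",
            mean(sp$concordance), nrow(sp)))
cat(sprintf("genus concordance (all members): mean %.3f over %d groups\n",
            mean(gn_all$concordance), nrow(gn_all)))

cmp <- compare_levels(sp$concordance, gn_all$concordance)
cat(sprintf("species vs genus Welch t = %.3f, p = %.3g\n",
            cmp$statistic, cmp$p_value))

# recombination relative to mutation per group, tested against 1
rm_tab <- read_rm_table("results/sim_rm_table.tsv")
wt <- rm_group_test(rm_tab$r_over_m)
cat(sprintf("r/m values: %s\n", paste(signif(rm_tab$r_over_m, 3), collapse = " ")))
cat(sprintf("one-sample Wilcoxon vs 1: V = %g, p = %.4f\n",
            wt$statistic, wt$p_value))

# association between genus concordance and r/m (paired arbitrarily by order
# here; with real data the pairing is by group id)
n <- min(nrow(gn_all), nrow(rm_tab))
rho <- concordance_rm_correlation(gn_all$concordance[seq_len(n)],
                                  rm_tab$r_over_m[seq_len(n)])
cat(sprintf("Spearman rho (concordance vs r/m): %s\n",
            if (rho$defined) sprintf("%.3f", rho$rho) else "undefined"))
write.table(cbind(rm_tab, wilcoxon_p = wt$p_value),
            "results/rm_analysis.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
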