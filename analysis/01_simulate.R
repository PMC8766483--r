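#!/usr/bin/env Rscript
# Step 1: generate the synthetic study system every later step analyses --
# a killing matrix with planted modules, a nested block and singleton pairs;
# a two-level phage taxonomy with species-structured host ranges; genomes
# with controlled 25-mer sharing; and a small table of recombination
# parameter estimates per group.

suppressPackageStartupMessages(library(phagenet))
dir.create("results", showWarnings = FALSE)

seed <- 2026

# interaction matrix emulating a sparse nested-modular survey
mat <- generate_matrix(matrix_gen_config(
  n_hosts = 60, n_phages = 60, n_modules = 4,
  within_fill = 0.55, between_fill = 0.005,
  n_singletons = 12, nested_block = 6, seed = seed))
write_interaction_matrix(mat$matrix, "results/sim_matrix.tsv")
writeLines(paste(names(mat$host_modules), mat$host_modules, sep = "\t"),
           "results/sim_host_modules.tsv")
writeLines(paste(names(mat$phage_modules), mat$phage_modules, sep = "\t"),
           "results/sim_phage_modules.tsv")

# taxonomy-structured host ranges: 3 genera x 2 species x 4 members
tax <- list(g1 = c(s1 = 4, s2 = 4), g2 = c(s3 = 4, s4 = 4),
            g3 = c(s5 = 4, s6 = 4))
hr <- generate_host_range_groups(tax, n_hosts = 80, kill_breadth = 6,
                                 template_overlap = 0, noise = 0.02,
                                 seed = seed + 1)
write_interaction_matrix(hr$matrix, "results/sim_hostrange_matrix.tsv")
write.table(hr$annotations, "results/sim_annotations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# genomes: two no-flow pools (emulating non-tailed vs tailed) plus one
# planted 60 bp within-pool transfer
gcfg <- genome_gen_config(
  taxonomy = list(gA = c(s1 = 2, s2 = 2), gB = c(s3 = 2), gC = c(s4 = 2)),
  genome_length = 5000, species_identity = 0.98,
  planted_transfers = data.frame(donor = "gA.s1.1", recipient = "gA.s2.1",
                                 length = 60, count = 1),
  no_flow_partition = list(tailed = c("gA", "gB"), nontailed = "gC"),
  seed = seed + 2)
gen <- generate_genomes(gcfg)
write_genomes_fasta(gen$genomes, "results/sim_genomes.fasta")
write.table(gen$annotations, "results/sim_genome_annotations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# recombination parameter estimates (as consumed from external inference)
rm_tab <- data.frame(group_id = paste0("g", 1:8),
                     R_over_theta = c(0.08, 0.2, 0.35, 0.15, 0.4, 0.1, 0.5, 0.25),
                     delta = c(150, 220, 180, 300, 250, 120, 400, 200),
                     nu = c(0.04, 0.06, 0.05, 0.03, 0.07, 0.02, 0.06, 0.05))
write.table(rm_tab, "results/sim_rm_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

p <- matrix_properties(mat$matrix)
cat("simulated killing matrix:", p$H, "hosts x", p$P, "phages,",
    p$I, "interactions, connectance", signif(p$C, 3), "\n")
cat("host-range system:", ncol(hr$matrix), "phages in",
    length(unique(hr$annotations$species_group)), "species /",
    length(unique(hr$annotations$genus_group)), "genera\n")
cat("genomes:", length(gen$genomes), "sequences of",
    nchar(gen$genomes[[1]]), "bp\n")
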