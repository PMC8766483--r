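test_that("planted block matrices unshuffle to their blueprint", {
  cfg <- matrix_gen_config(10, 10, n_modules = 2, within_fill = 1,
                           between_fill = 0, seed = 3)
  gen <- generate_matrix(cfg)
  # planted partition scores exactly the two-equal-block closed form
  expect_equal(gen$partition$Qb, 0.5)
  expect_equal(gen$partition$Qr, 1)
  # unshuffling by planted labels restores block-diagonal structure
  ord_h <- order(gen$host_modules)
  ord_p <- order(gen$phage_modules)
  A <- unclass(gen$matrix)[ord_h, ord_p]
  expect_true(all(A[1:5, 1:5] == 1) && all(A[1:5, 6:10] == 0))
  expect_true(all(A[6:10, 6:10] == 1) && all(A[6:10, 1:5] == 0))
})

test_that("singletons and nested blocks are planted verbatim", {
  cfg <- matrix_gen_config(8, 8, n_modules = 2, within_fill = 0.9,
                           between_fill = 0, n_singletons = 5,
                           nested_block = 4, seed = 5)
  gen <- generate_matrix(cfg)
  expect_equal(dim(gen$matrix), c(8L + 4L + 5L, 8L + 4L + 5L))
  sp <- singleton_pairs(gen$matrix)
  expect_equal(nrow(sp), 5)
  # the nested sub-block alone is perfectly nested
  nested_hosts <- names(gen$host_modules)[gen$host_modules == 3]
  nested_phages <- names(gen$phage_modules)[gen$phage_modules == 3]
  sub <- interaction_matrix(unclass(gen$matrix)[nested_hosts, nested_phages])
  expect_equal(nodf(sub)$nodf, 1)
})

test_that("generators are pure functions of config and seed", {
  cfg <- matrix_gen_config(12, 12, n_modules = 3, seed = 9)
  expect_identical(generate_matrix(cfg)$matrix, generate_matrix(cfg)$matrix)
  cfg2 <- matrix_gen_config(12, 12, n_modules = 3, seed = 10)
  expect_false(identical(generate_matrix(cfg)$matrix,
                         generate_matrix(cfg2)$matrix))
  gcfg <- genome_gen_config(list(g1 = c(s1 = 2)), genome_length = 1500, seed = 4)
  expect_identical(generate_genomes(gcfg)$genomes, generate_genomes(gcfg)$genomes)
  t1 <- generate_host_range_groups(list(g1 = c(s1 = 2, s2 = 2)), seed = 2)
  t2 <- generate_host_range_groups(list(g1 = c(s1 = 2, s2 = 2)), seed = 2)
  expect_identical(unclass(t1$matrix), unclass(t2$matrix))
})

test_that("generated connectance converges to the fill-weighted expectation", {
  cfg <- matrix_gen_config(200, 200, n_modules = 4, within_fill = 0.6,
                           between_fill = 0.05, seed = 13)
  gen <- generate_matrix(cfg)
  C <- matrix_properties(gen$matrix)$C
  expected <- 0.6 * 0.25 + 0.05 * 0.75  # equal blocks: 1/4 of cells within
  expect_lt(abs(C - expected) / expected, 0.1)
})

test_that("flat fills carry no planted signal for the null test", {
  cfg <- matrix_gen_config(12, 12, n_modules = 3, within_fill = 0.25,
                           between_fill = 0.25, seed = 17)
  gen <- generate_matrix(cfg)
  r <- equiprobable_null(gen$matrix, "qb_max", n_replicates = 40, seed = 8)
  expect_lt(abs(r$z_score), 3)
})

test_that("planted modules are recovered across seeds (parameter recovery)", {
  ok <- 0L
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    k <- 3 + (s %% 4)  # module counts 3-6
    cfg <- matrix_gen_config(30, 30, n_modules = k, within_fill = 0.8,
                             between_fill = 0.02, seed = 200 + s)
    gen <- generate_matrix(cfg)
    part <- leading_eigenvector_modules(gen$matrix)
    nmi <- partition_recovery_nmi(part, gen$host_modules, gen$phage_modules)
    if (nmi >= 0.9) ok <- ok + 1L
  }
  expect_gte(ok / n_seeds, 0.95)
})

test_that("genome generator controls identity, transfers and no-flow pools", {
  # perfect species identity -> identical members
  cfg1 <- genome_gen_config(list(g1 = c(s1 = 2)), genome_length = 2000,
                            species_identity = 1, seed = 6)
  g1 <- generate_genomes(cfg1)$genomes
  tab <- pairwise_sharing(lapply(names(g1), function(id)
    kmer_profile(g1[[id]], 25, id)))
  expect_equal(tab$jaccard, 1)
  # one planted 60 bp transfer -> >= 36 shared 25-mers donor/recipient
  cfg2 <- genome_gen_config(list(gA = c(s1 = 1), gB = c(s2 = 1)),
                            genome_length = 3000, species_identity = 1,
                            planted_transfers = data.frame(
                              donor = "gA.s1.1", recipient = "gB.s2.1",
                              length = 60, count = 1), seed = 7)
  g2 <- generate_genomes(cfg2)$genomes
  tab2 <- pairwise_sharing(lapply(names(g2), function(id)
    kmer_profile(g2[[id]], 25, id)))
  expect_gte(tab2$shared_count, 36)
  # no-flow pools share zero 25-mers across pools
  cfg3 <- genome_gen_config(list(gA = c(s1 = 2), gB = c(s2 = 2)),
                            genome_length = 2500, species_identity = 0.97,
                            no_flow_partition = list(pool1 = "gA", pool2 = "gB"),
                            seed = 8)
  out3 <- generate_genomes(cfg3)
  profs <- lapply(names(out3$genomes), function(id)
    kmer_profile(out3$genomes[[id]], 25, id))
  tab3 <- pairwise_sharing(profs)
  genus_of <- out3$annotations$genus_group[match(c(tab3$genome_a),
                                                 out3$annotations$phage_id)]
  genus_of_b <- out3$annotations$genus_group[match(c(tab3$genome_b),
                                                   out3$annotations$phage_id)]
  cross <- genus_of != genus_of_b
  expect_true(all(tab3$shared_count[cross] == 0))
  expect_true(any(tab3$shared_count[!cross] > 0))
  # transfer shorter than k rejected at config time
  expect_error(genome_gen_config(list(g = c(s = 1)), planted_transfers =
                                   data.frame(donor = "a", recipient = "b",
                                              length = 10, count = 1)),
               ">= k")
})

test_that("host-range groups reproduce the species/genus concordance contrast", {
  tax <- list(g1 = c(s1 = 3, s2 = 3), g2 = c(s3 = 3, s4 = 3))
  out <- generate_host_range_groups(tax, n_hosts = 60, kill_breadth = 6,
                                    template_overlap = 0, noise = 0, seed = 5)
  sp <- group_concordance(out$matrix, out$annotations, level = "species")
  expect_true(all(sp$concordance == 1))
  gn <- group_concordance(out$matrix, out$annotations, level = "genus")
  expect_true(all(gn$concordance < 1))
  expect_true(all(sp$concordance > max(gn$concordance)))
  # degenerate host universe rejected
  expect_error(generate_host_range_groups(tax, n_hosts = 1), ">= 2 hosts")
  expect_error(generate_host_range_groups(tax, n_hosts = 8, kill_breadth = 6),
               "too small")
})

test_that("low-noise groups separate species from genus concordance end to end", {
  tax <- list(g1 = c(s1 = 4, s2 = 4), g2 = c(s3 = 4, s4 = 4),
              g3 = c(s5 = 4, s6 = 4))
  out <- generate_host_range_groups(tax, n_hosts = 80, kill_breadth = 6,
                                    template_overlap = 0, noise = 0.02, seed = 31)
  sp <- group_concordance(out$matrix, out$annotations, level = "species")
  gn <- group_concordance(out$matrix, out$annotations, level = "genus")
  cmp <- compare_levels(sp$concordance, gn$concordance)
  expect_lt(cmp$p_value, 0.01)
})
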