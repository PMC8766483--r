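test_that("scaled divergence matches the entropy-formula oracle", {
  # identical profiles -> 0
  m_id <- interaction_matrix(cbind(p1 = c(1, 1, 0), p2 = c(1, 1, 0),
                                   p3 = c(1, 1, 0)))
  expect_equal(scaled_divergence(m_id), 0)
  # disjoint profiles -> 1
  m_dis <- interaction_matrix(cbind(p1 = c(1, 0, 0), p2 = c(0, 1, 0),
                                    p3 = c(0, 0, 1)))
  expect_equal(scaled_divergence(m_dis), 1)
  # worked half-overlap pair: mixture entropy 1.5 bits, mean entropy 1
  m_half <- interaction_matrix(cbind(p1 = c(1, 1, 0), p2 = c(0, 1, 1)))
  expect_equal(scaled_divergence(m_half), 0.5)
  # n = 2 equals the pairwise Jensen-Shannon divergence in bits
  p1 <- c(0.5, 0.5, 0); p2 <- c(0, 0.5, 0.5)
  mix <- (p1 + p2) / 2
  h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  jsd <- h(mix) - (h(p1) + h(p2)) / 2
  expect_equal(scaled_divergence(list(a = p1, b = p2)), jsd)
  # zero-kill profile is a named hard error
  m_bad <- interaction_matrix(cbind(p1 = c(1, 0), dead = c(0, 0)))
  expect_error(scaled_divergence(m_bad), "dead")
})

test_that("scaled divergence ignores host order and unkilled hosts", {
  set.seed(2)
  A <- cbind(p1 = rbinom(8, 1, 0.5), p2 = rbinom(8, 1, 0.5),
             p3 = rbinom(8, 1, 0.5))
  A[1, ] <- 1L  # guarantee kills
  m <- interaction_matrix(A)
  d0 <- scaled_divergence(m)
  perm <- interaction_matrix(A[sample(nrow(A)), ])
  expect_equal(scaled_divergence(perm), d0)
  # append a host killed by nobody
  m_plus <- interaction_matrix(rbind(A, c(0L, 0L, 0L)))
  expect_equal(scaled_divergence(m_plus), d0)
})

test_that("group concordance handles modes, skips and degenerate groups", {
  # genus of two species with disjoint single-host profiles -> concordance 0
  m <- interaction_matrix(cbind(p1 = c(1, 0), p2 = c(0, 1)))
  ann <- small_annotations(c("p1", "p2"), c("s1", "s2"), c("g1", "g1"))
  res <- group_concordance(m, ann, level = "genus")
  expect_equal(res$concordance, 0)
  expect_equal(res$n, 2)
  # species level: both species have a single member -> skipped
  res_sp <- group_concordance(m, ann, level = "species")
  expect_equal(nrow(res_sp), 0)
  expect_setequal(attr(res_sp, "skipped"), c("s1", "s2"))
  # all-members exceeds single-representative when one species dominates
  A <- cbind(matrix(rep(c(1L, 1L, 0L, 0L), 10), 4),
             lone = c(0L, 0L, 1L, 1L))
  colnames(A) <- c(paste0("q", 1:10), "lone")
  m2 <- interaction_matrix(A)
  ann2 <- small_annotations(colnames(A),
                            c(rep("sA", 10), "sB"), rep("g", 11))
  all_mode <- group_concordance(m2, ann2, level = "genus", mode = "all_members")
  rep_mode <- group_concordance(m2, ann2, level = "genus",
                                mode = "single_representative", seed = 3)
  expect_gt(all_mode$concordance, rep_mode$concordance)
  expect_equal(rep_mode$n, 2)
  # unknown phage in the matrix is a hard error
  expect_error(group_concordance(m2, ann2[-1, ], level = "genus"),
               "without annotation")
})

test_that("duplicating members of the most concordant species never lowers concordance", {
  set.seed(8)
  A <- cbind(p1 = c(1L, 1L, 0L, 0L), p2 = c(1L, 1L, 0L, 0L),
             p3 = c(0L, 1L, 1L, 0L))
  ann <- small_annotations(c("p1", "p2", "p3"), c("s1", "s1", "s2"),
                           rep("g", 3))
  base <- group_concordance(interaction_matrix(A), ann, level = "genus")$concordance
  A2 <- cbind(A, p4 = A[, "p1"])
  ann2 <- rbind(ann, small_annotations("p4", "s1", "g"))
  dup <- group_concordance(interaction_matrix(A2), ann2, level = "genus")$concordance
  expect_gte(dup, base)
})

test_that("level comparison is a two-sided Welch test with degenerate fallback", {
  same <- compare_levels(c(0.2, 0.5, 0.8), c(0.2, 0.5, 0.8))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  sep <- compare_levels(c(0, 0, 0.1), c(0.9, 1, 1))
  expect_lt(sep$p_value, 0.01)
  # agreement with the closed-form Welch computation
  x <- c(0, 0, 0.1); y <- c(0.9, 1, 1)
  tval <- (mean(x) - mean(y)) / sqrt(var(x) / 3 + var(y) / 3)
  expect_equal(sep$statistic, tval)
  # both samples constant and equal -> t = 0, p = 1
  const <- compare_levels(c(1, 1), c(1, 1))
  expect_equal(const$p_value, 1)
})

test_that("morphotype kill statistics summarize and test pairwise", {
  m <- interaction_matrix(matrix(c(1L, 1L, 1L, 0L,   # p1 kills 3
                                   1L, 1L, 0L, 0L,   # p2 kills 2
                                   1L, 0L, 0L, 0L,   # p3 kills 1
                                   1L, 1L, 1L, 1L),  # p4 kills 4
                                 nrow = 4),
                          host_ids = paste0("h", 1:4),
                          phage_ids = paste0("p", 1:4))
  ann <- small_annotations(paste0("p", 1:4), paste0("s", 1:4), paste0("g", 1:4),
                           morphotype = c("myovirus", "myovirus",
                                          "siphovirus", "siphovirus"))
  out <- morphotype_kill_stats(m, ann)
  expect_equal(out$summary$mean[out$summary$morphotype == "myovirus"], 2.5)
  expect_equal(out$summary$sd[out$summary$morphotype == "siphovirus"],
               stats::sd(c(1, 4)))
  expect_equal(nrow(out$tests), 1)
  # identical groups -> t = 0, p = 1 (degenerate-variance contract)
  ann_same <- small_annotations(paste0("p", 1:4), paste0("s", 1:4), paste0("g", 1:4),
                                morphotype = c("a", "a", "b", "b"))
  m_same <- interaction_matrix(matrix(c(1L, 0L, 0L, 0L,
                                        1L, 0L, 0L, 0L,
                                        1L, 0L, 0L, 0L,
                                        1L, 0L, 0L, 0L), nrow = 4))
  out_same <- morphotype_kill_stats(m_same, ann_same)
  expect_equal(out_same$tests$t, 0)
  expect_equal(out_same$tests$p_value, 1)
  # clearly separated groups
  m_sep <- interaction_matrix(rbind(matrix(1L, 5, 4),
                                    cbind(matrix(0L, 3, 2), matrix(1L, 3, 2))))
  out_sep <- morphotype_kill_stats(m_sep, ann_same)
  expect_lt(out_sep$tests$p_value, 0.01)
})

test_that("life-history KS test hits its boundary cases", {
  expect_equal(life_history_ks(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(life_history_ks(1:10, 11:20)$D, 1)
  expect_error(life_history_ks(numeric(0), 1:3), "nonempty")
})

test_that("r/m composition is exact multiplication with sign guard", {
  expect_equal(rm_value(0.1, 100, 0.05)$r_over_m, 0.5)
  expect_equal(rm_value(0, 7, 3)$r_over_m, 0)
  expect_equal(rm_value(100, 0.05, 0.1)$r_over_m, 0.5)  # factor order irrelevant
  expect_error(rm_value(-1, 1, 1), "nonnegative")
})

test_that("one-sample Wilcoxon against 1 uses the exact distribution at small n", {
  # all six values above 1: two-sided exact p = 2/2^6
  p6 <- rm_group_test(c(1.2, 1.4, 1.6, 2, 3, 10))
  expect_equal(p6$p_value, 2 / 64)
  expect_true(p6$exact)
  # symmetric values around 1
  expect_equal(rm_group_test(c(0.5, 1.5))$p_value, 1)
  # single informative value
  expect_equal(rm_group_test(2)$p_value, 1)
  expect_error(rm_group_test(c(1, 1)), "no information")
  # monotone: p decreases as n grows with all values above 1
  ps <- vapply(3:8, function(n) rm_group_test(1 + seq_len(n))$p_value, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("concordance/r-m correlation is Spearman with constant-input flag", {
  expect_equal(concordance_rm_correlation(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(concordance_rm_correlation(1:5, 5:1)$rho, -1)
  flat <- concordance_rm_correlation(rep(1, 4), 1:4)
  expect_false(flat$defined)
  expect_true(is.na(flat$rho))
  expect_error(concordance_rm_correlation(1:2, 1:2), ">= 3")
})

test_that("r/m tables round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("group_id\tR_over_theta\tdelta\tnu",
               "g1\t0.1\t100\t0.05", "g2\t0.2\t50\t0.1"), path)
  tab <- read_rm_table(path)
  expect_equal(tab$r_over_m, c(0.5, 1))
  expect_equal(tab$group_id, c("g1", "g2"))
})
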