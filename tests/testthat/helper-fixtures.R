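# shared fixtures built in code

# g fully connected a x b blocks on the diagonal
block_matrix <- function(g, a, b) {
  m <- matrix(0L, g * a, g * b)
  for (i in seq_len(g)) {
    m[((i - 1) * a + 1):(i * a), ((i - 1) * b + 1):(i * b)] <- 1L
  }
  interaction_matrix(m)
}

block_partition <- function(m, g, a, b) {
  module_partition(m,
                   stats::setNames(rep(seq_len(g), each = a), rownames(m)),
                   stats::setNames(rep(seq_len(g), each = b), colnames(m)))
}

strict_triangle <- function(n) {
  interaction_matrix(outer(seq_len(n), seq_len(n),
                           function(i, j) as.integer(j <= n - i + 1)))
}

# exhaustive Qb optimum over all joint set partitions of the hosts+phages
# (independent brute-force oracle; enumerates partitions recursively)
set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  smaller <- set_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(n))
  }
  out
}

brute_force_qb <- function(m) {
  nh <- nrow(m); np <- ncol(m)
  I <- sum(m)
  B <- unclass(m) - outer(rowSums(m), colSums(m)) / I
  best <- -Inf
  for (p in set_partitions(nh + np)) {
    lab <- integer(nh + np)
    for (b in seq_along(p)) lab[p[[b]]] <- b
    hm <- lab[seq_len(nh)]; pm <- lab[nh + seq_len(np)]
    q <- sum(B[outer(hm, pm, `==`)]) / I
    if (q > best) best <- q
  }
  best
}

random_binary_matrix <- function(nr, nc, p = 0.4) {
  repeat {
    m <- matrix(stats::rbinom(nr * nc, 1, p), nr, nc)
    if (sum(m) >= 1) return(interaction_matrix(m))
  }
}

small_annotations <- function(phage_ids, species, genus,
                              morphotype = "unknown",
                              life_history = "unknown") {
  data.frame(phage_id = phage_ids, species_group = species,
             genus_group = genus,
             morphotype = rep_len(morphotype, length(phage_ids)),
             life_history = rep_len(life_history, length(phage_ids)),
             stringsAsFactors = FALSE)
}
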