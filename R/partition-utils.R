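#' Normalized mutual information between two labelings
#'
#' Plug-in mutual information between two categorical labelings of the same
#' nodes, normalized by the arithmetic mean of the label entropies (natural
#' convention for partition-recovery scoring). 1 for identical partitions up
#' to relabeling, 0 for independent ones; defined as 1 when both labelings are
#' single-cluster.
#'
#' @param a,b equal-length label vectors.
#' @return NMI in \[0, 1\].
#' @export
partition_nmi <- function(a, b) {
  if (length(a) != length(b) || !length(a)) stop("labelings must have equal length >= 1")
  joint <- table(a, b) / length(a)
  pa <- rowSums(joint); pb <- colSums(joint)
  hx <- entropy_bits(pa); hy <- entropy_bits(pb)
  if (hx == 0 && hy == 0) return(1)
  mi <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb)) {
    if (joint[i, j] > 0) {
      mi <- mi + joint[i, j] * log2(joint[i, j] / (pa[i] * pb[j]))
    }
  }
  unname(2 * mi / (hx + hy))
}

#' Joint NMI of a detected module partition against planted labels
#'
#' Concatenates host and phage labels (hosts first) on both sides and scores
#' them with [partition_nmi()].
#'
#' @param part a `module_partition`.
#' @param host_modules,phage_modules named ground-truth label vectors.
#' @return NMI in \[0, 1\].
#' @export
partition_recovery_nmi <- function(part, host_modules, phage_modules) {
  detected <- c(part$host_assignment[names(host_modules)],
                part$phage_assignment[names(phage_modules)])
  truth <- c(host_modules, phage_modules)
  partition_nmi(as.character(detected), as.character(truth))
}
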