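#' Canonical k-mer profile of a genome
#'
#' Extracts every k-length window of the sequence, skips windows containing
#' characters outside A/C/G/T, and stores each k-mer in canonical form: the
#' lexicographic minimum of the k-mer and its reverse complement, so profiles
#' are strand-independent. With `positions = TRUE` the (0-based) start
#' positions of every window are retained, which the pseudo-mapper needs to
#' translate k-mer matches into reference coverage.
#'
#' @param sequence a DNA string (character scalar).
#' @param k k-mer length (>= 1; default 25).
#' @param genome_id identifier stored in the profile.
#' @param positions also keep window start positions (default `FALSE`).
#' @return A list of class `kmer_profile`: `genome_id`, `k`, `kmers` (unique
#'   canonical k-mers), `length` (sequence length), and when requested
#'   `kmer_positions` (data frame `kmer`, `pos`, one row per window).
#' @export
kmer_profile <- function(sequence, k = 25, genome_id = "genome",
                         positions = FALSE) {
  if (k < 1) stop("k must be >= 1")
  sequence <- toupper(as.character(sequence))
  L <- nchar(sequence)
  if (L < k) {
    return(structure(list(genome_id = genome_id, k = k,
                          kmers = character(0), length = L,
                          kmer_positions = if (positions)
                            data.frame(kmer = character(0), pos = integer(0))),
                     class = "kmer_profile"))
  }
  starts <- seq_len(L - k + 1)
  kmers <- substring(sequence, starts, starts + k - 1)
  valid <- !grepl("[^ACGT]", kmers)
  kmers <- kmers[valid]
  starts <- starts[valid]
  canon <- canonical_kmers(kmers)
  out <- structure(list(genome_id = genome_id, k = k,
                        kmers = unique(canon), length = L),
                   class = "kmer_profile")
  if (positions) {
    out$kmer_positions <- data.frame(kmer = canon, pos = starts - 1L,
                                     stringsAsFactors = FALSE)
  }
  out
}

# lexicographic min of each k-mer and its reverse complement
canonical_kmers <- function(kmers) {
  if (!length(kmers)) return(character(0))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  ifelse(kmers <= rc, kmers, rc)
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat(sprintf("kmer_profile '%s': %d distinct canonical %d-mers (sequence %d bp)\n",
              x$genome_id, length(x$kmers), x$k, x$length))
  invisible(x)
}

#' Canonical k-mer profiles for a FASTA file or sequence set
#'
#' @param x path to a (multi-)FASTA file, a named character vector of
#'   sequences, or a `Biostrings::DNAStringSet`; record ids become genome ids.
#' @param k k-mer length.
#' @param positions keep window positions (see [kmer_profile()]).
#' @return Named list of `kmer_profile` objects.
#' @export
kmer_profiles <- function(x, k = 25, positions = FALSE) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  lapply(stats::setNames(names(seqs), names(seqs)), function(id) {
    kmer_profile(seqs[[id]], k = k, genome_id = id, positions = positions)
  })
}

#' Pairwise k-mer sharing between genomes
#'
#' Scores every unordered pair of genomes by exact intersection of their
#' canonical k-mer sets: the shared count, the Jaccard index J over the union,
#' the Mash-style distance `-(1/k) * log(2J / (1 + J))` (0 when the sets are
#' identical, Inf when disjoint), and the binary sharing indicator
#' (`shared_count >= 1`) used for sharing networks.
#'
#' @param profiles list of >= 2 [kmer_profile()] objects built with one k.
#' @return A data frame of class `pair_sharing_table` with one row per
#'   unordered pair: `genome_a`, `genome_b`, `shared_count`, `jaccard`,
#'   `mash_distance`, `binary_share`. Pair order is
#'   `utils::combn` order over the profile list, the same ordering
#'   [host_sharing_vector()] uses over phages.
#' @export
pairwise_sharing <- function(profiles) {
  if (length(profiles) < 2) stop("need >= 2 profiles")
  ks <- vapply(profiles, function(p) p$k, numeric(1))
  if (length(unique(ks)) != 1) stop("profiles built with mixed k: ",
                                    paste(unique(ks), collapse = ", "))
  k <- ks[1]
  ids <- vapply(profiles, function(p) p$genome_id, character(1))
  pairs <- utils::combn(seq_along(profiles), 2)
  n <- ncol(pairs)
  shared <- integer(n); jac <- numeric(n)
  for (r in seq_len(n)) {
    a <- profiles[[pairs[1, r]]]$kmers
    b <- profiles[[pairs[2, r]]]$kmers
    s <- length(intersect(a, b))
    u <- length(a) + length(b) - s
    shared[r] <- s
    jac[r] <- if (u > 0) s / u else 0
  }
  out <- data.frame(genome_a = ids[pairs[1, ]], genome_b = ids[pairs[2, ]],
                    shared_count = shared, jaccard = jac,
                    mash_distance = mash_distance(jac, k),
                    binary_share = shared >= 1,
                    stringsAsFactors = FALSE)
  class(out) <- c("pair_sharing_table", class(out))
  out
}

#' Mash distance from a Jaccard index
#'
#' `d = -(1/k) * log(2J / (1 + J))`; 0 iff J = 1, Inf when J = 0.
#'
#' @param jaccard Jaccard index in \[0, 1\]. @param k k-mer length.
#' @return Distance value(s).
#' @export
mash_distance <- function(jaccard, k) {
  ifelse(jaccard > 0, -(1 / k) * log(2 * jaccard / (1 + jaccard)), Inf)
}

#' Binary host-sharing vector over phage pairs
#'
#' For every unordered pair of phage columns, 1 if the two phages kill at least
#' one common host, else 0. Pair ordering matches [pairwise_sharing()] over the
#' same phage order, so the two vectors can be compared directly.
#'
#' @param m an [interaction_matrix()].
#' @return A data frame `phage_a`, `phage_b`, `shares_host` (integer 0/1).
#' @export
host_sharing_vector <- function(m) {
  A <- unclass(m)
  co <- crossprod(A)   # phage x phage common-host counts
  pairs <- utils::combn(seq_len(ncol(A)), 2)
  data.frame(phage_a = colnames(A)[pairs[1, ]],
             phage_b = colnames(A)[pairs[2, ]],
             shares_host = as.integer(co[cbind(pairs[1, ], pairs[2, ])] > 0),
             stringsAsFactors = FALSE)
}

#' Mutual information between two binary pair vectors
#'
#' Plug-in empirical mutual information from the 2x2 joint frequency table, in
#' bits (log2, with 0 log 0 = 0). Used to ask whether phage pairs that share
#' sequence also share hosts; bounded by min of the marginal entropies, hence
#' by 1 bit.
#'
#' @param a,b equal-length binary vectors (0/1 or logical).
#' @return Mutual information in bits.
#' @export
binary_mutual_information <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b) || !length(a)) stop("vectors must have equal length >= 1")
  if (!all(a %in% c(0L, 1L)) || !all(b %in% c(0L, 1L))) stop("vectors must be binary")
  n <- length(a)
  joint <- table(factor(a, c(0, 1)), factor(b, c(0, 1))) / n
  pa <- rowSums(joint); pb <- colSums(joint)
  mi <- 0
  for (i in 1:2) for (j in 1:2) {
    if (joint[i, j] > 0) {
      mi <- mi + joint[i, j] * log2(joint[i, j] / (pa[i] * pb[j]))
    }
  }
  max(unname(mi), 0)
}

#' Write a pair sharing table
#'
#' TSV with header
#' `genome_a, genome_b, shared_count, jaccard, mash_distance, binary_share`.
#'
#' @param tab a `pair_sharing_table`. @param path output file.
#' @return `path`, invisibly.
#' @export
write_sharing_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
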