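#' Configuration for the paired-end read simulator
#'
#' Defaults follow common settings for simulating high-quality viral
#' metagenome reads: 100,000 pairs of 250 bp reads, outer fragment distance
#' 500 with standard deviation 50, and a per-base substitution error rate of
#' 0.001.
#'
#' @param n_reads number of read pairs.
#' @param read_length read length in bases (>= 31 so every read carries at
#'   least one 31-mer).
#' @param error_rate per-base substitution probability in \[0, 1).
#' @param insert_mean mean outer distance (fragment length), bases.
#' @param insert_sd standard deviation of the outer distance, bases.
#' @param seed integer seed.
#' @return A list of class `read_sim_config`.
#' @export
read_sim_config <- function(n_reads = 100000, read_length = 250,
                            error_rate = 0.001, insert_mean = 500,
                            insert_sd = 50, seed = 1L) {
  if (read_length < 31) stop("read_length must be >= 31 for 31-mer mappability")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  structure(list(n_reads = n_reads, read_length = read_length,
                 error_rate = error_rate, insert_mean = insert_mean,
                 insert_sd = insert_sd, seed = as.integer(seed)),
            class = "read_sim_config")
}

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate paired-end reads from a genome
#'
#' A simplified Illumina-style simulator: each fragment start is uniform on
#' the genome, the outer distance is drawn Normal(insert_mean, insert_sd)
#' truncated to \[2 x read_length, genome length\]; read 1 is the fragment
#' prefix and read 2 the reverse complement of the fragment suffix; every base
#' is substituted with probability `error_rate` to a uniformly chosen
#' different base. Quality strings are constant `"I"`. Deterministic given the
#' config seed.
#'
#' @param genome DNA string; must be longer than `insert_mean`.
#' @param config a [read_sim_config()].
#' @param source_id read-name prefix (`@<source>_<i>/1`, `/2`).
#' @return A data frame with columns `name`, `read1`, `read2`.
#' @export
simulate_reads <- function(genome, config, source_id = "sim") {
  genome <- toupper(as.character(genome))
  L <- nchar(genome)
  if (L <= config$insert_mean) stop("genome shorter than the mean insert size")
  n <- config$n_reads
  if (n == 0) {
    return(data.frame(name = character(0), read1 = character(0),
                      read2 = character(0)))
  }
  rl <- config$read_length
  withr::with_seed(config$seed, {
    frag <- round(stats::rnorm(n, config$insert_mean, config$insert_sd))
    frag <- pmin(pmax(frag, 2 * rl), L)
    start <- vapply(frag, function(f) sample.int(L - f + 1, 1), integer(1))
    read1 <- substring(genome, start, start + rl - 1)
    read2 <- revcomp(substring(genome, start + frag - rl, start + frag - 1))
    read1 <- add_substitution_errors(read1, config$error_rate)
    read2 <- add_substitution_errors(read2, config$error_rate)
    data.frame(name = sprintf("%s_%d", source_id, seq_len(n)),
               read1 = read1, read2 = read2, stringsAsFactors = FALSE)
  })
}

add_substitution_errors <- function(reads, rate) {
  if (rate == 0 || !length(reads)) return(reads)
  chars <- strsplit(reads, "", fixed = TRUE)
  vapply(chars, function(v) {
    hit <- which(stats::runif(length(v)) < rate)
    for (i in hit) {
      v[i] <- sample(setdiff(DNA_BASES, v[i]), 1)
    }
    paste(v, collapse = "")
  }, character(1))
}

#' Write simulated read pairs as FASTQ
#'
#' Two four-line-record FASTQ files (`/1` and `/2` suffixes on read names);
#' qualities are constant `"I"`.
#'
#' @param reads data frame from [simulate_reads()].
#' @param prefix output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @return The two paths, invisibly.
#' @export
write_fastq_pairs <- function(reads, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (mate in 1:2) {
    seqs <- reads[[paste0("read", mate)]]
    rec <- rbind(sprintf("@%s/%d", reads$name, mate), seqs, "+",
                 strrep("I", nchar(seqs)))
    writeLines(as.vector(rec), paths[mate])
  }
  invisible(paths)
}

#' Detection thresholds for calling a genome present
#'
#' Defaults mirror common pseudo-alignment detection settings: minimum genome
#' coverage fraction 0.1, minimum ratio of observed to expected coverage 0.3
#' (an evenness guard), and at least 10 mapped reads.
#'
#' @param min_coverage_fraction,min_obs_exp_ratio,min_mapped_reads thresholds
#'   (all >= 0).
#' @return A list of class `detection_criteria`.
#' @export
detection_criteria <- function(min_coverage_fraction = 0.1,
                               min_obs_exp_ratio = 0.3,
                               min_mapped_reads = 10) {
  if (min_coverage_fraction < 0 || min_obs_exp_ratio < 0 || min_mapped_reads < 0) {
    stop("thresholds must be nonnegative")
  }
  structure(list(min_coverage_fraction = min_coverage_fraction,
                 min_obs_exp_ratio = min_obs_exp_ratio,
                 min_mapped_reads = min_mapped_reads),
            class = "detection_criteria")
}

#' Pseudo-map reads against a reference 31-mer profile
#'
#' A read maps if at least one of its canonical 31-mers occurs in the
#' reference profile, the defining behaviour of k-mer pseudo-alignment.
#' Reference coverage is the union of the reference-located intervals
#' `[pos, pos + 30]` of every matched 31-mer (0-based half-open internally),
#' and expected coverage under uniform placement is the Lander-Waterman form
#' `1 - exp(-mapped_reads * read_length / reference_length)`.
#'
#' @param reads character vector of read sequences, or the data frame from
#'   [simulate_reads()] (both mates are mapped).
#' @param reference a [kmer_profile()] built with `k = 31` and
#'   `positions = TRUE`.
#' @param criteria a [detection_criteria()].
#' @param source_genome,reference_genome labels carried into the result.
#' @return A list of class `mapping_result`: `source_genome`,
#'   `reference_genome`, `n_reads`, `mapped_reads`, `covered_fraction`,
#'   `expected_coverage_fraction`, `obs_exp_ratio`, `detected`.
#' @export
pseudo_map <- function(reads, reference, criteria = detection_criteria(),
                       source_genome = "source",
                       reference_genome = reference$genome_id) {
  if (reference$k != 31) stop("pseudo-mapping requires a k = 31 reference profile")
  if (is.null(reference$kmer_positions)) {
    stop("reference profile must be built with positions = TRUE")
  }
  if (is.data.frame(reads)) reads <- c(reads$read1, reads$read2)
  n_reads <- length(reads)
  read_length <- if (n_reads) max(nchar(reads)) else 0
  ref_kmers <- reference$kmer_positions
  # canonicalize all read windows in one batch, then test membership
  wins <- lapply(reads, function(rd) {
    L <- nchar(rd)
    if (L < 31) character(0) else substring(toupper(rd), 1:(L - 30), 31:L)
  })
  read_idx <- rep(seq_along(reads), lengths(wins))
  all_w <- unlist(wins, use.names = FALSE)
  valid <- if (length(all_w)) !grepl("[^ACGT]", all_w) else logical(0)
  uniq <- unique(all_w[valid])
  canon_u <- canonical_kmers(uniq)
  in_ref_u <- canon_u %in% ref_kmers$kmer
  hit_win <- valid
  hit_win[valid] <- in_ref_u[match(all_w[valid], uniq)]
  mapped <- length(unique(read_idx[hit_win]))
  hit_kmers <- unique(canon_u[match(all_w[hit_win], uniq)])
  covered <- 0
  if (length(hit_kmers)) {
    pos <- ref_kmers$pos[ref_kmers$kmer %in% unique(hit_kmers)]
    iv <- IRanges::reduce(IRanges::IRanges(start = pos + 1L, width = 31L))
    covered <- sum(IRanges::width(iv)) / reference$length
  }
  expected <- 1 - exp(-(mapped * read_length) / reference$length)
  ratio <- if (expected > 0) covered / expected else 0
  res <- structure(list(source_genome = source_genome,
                        reference_genome = reference_genome,
                        n_reads = n_reads,
                        mapped_reads = mapped,
                        covered_fraction = covered,
                        expected_coverage_fraction = expected,
                        obs_exp_ratio = ratio,
                        detected = NA),
                   class = "mapping_result")
  res$detected <- detect_presence(res, criteria)
  res
}

#' Apply detection criteria to a mapping result
#'
#' `TRUE` iff covered fraction, observed/expected coverage ratio and mapped
#' read count all reach their thresholds.
#'
#' @param result a `mapping_result` (or any list with `covered_fraction`,
#'   `obs_exp_ratio`, `mapped_reads`).
#' @param criteria a [detection_criteria()].
#' @return Logical flag.
#' @export
detect_presence <- function(result, criteria = detection_criteria()) {
  result$covered_fraction >= criteria$min_coverage_fraction &&
    result$obs_exp_ratio >= criteria$min_obs_exp_ratio &&
    result$mapped_reads >= criteria$min_mapped_reads
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf("%s -> %s: %d/%d reads mapped, coverage %.3f (expected %.3f, ratio %.2f), detected: %s\n",
              x$source_genome, x$reference_genome, x$mapped_reads, x$n_reads,
              x$covered_fraction, x$expected_coverage_fraction,
              x$obs_exp_ratio, x$detected))
  invisible(x)
}

#' Cross-recruitment experiment over a reference panel
#'
#' Simulates reads from one source genome and pseudo-maps them against every
#' reference profile, returning one row per reference with the detection call.
#'
#' @param genomes named character vector of genome sequences.
#' @param source_id name of the genome to simulate reads from.
#' @param config a [read_sim_config()].
#' @param criteria a [detection_criteria()].
#' @return A data frame with one row per reference genome.
#' @export
cross_recruitment <- function(genomes, source_id, config,
                              criteria = detection_criteria()) {
  if (!source_id %in% names(genomes)) stop("unknown source genome: ", source_id)
  reads <- simulate_reads(genomes[[source_id]], config, source_id = source_id)
  rows <- lapply(names(genomes), function(ref_id) {
    prof <- kmer_profile(genomes[[ref_id]], k = 31, genome_id = ref_id,
                         positions = TRUE)
    r <- pseudo_map(reads, prof, criteria, source_genome = source_id)
    data.frame(source_genome = r$source_genome,
               reference_genome = r$reference_genome,
               mapped_reads = r$mapped_reads,
               covered_fraction = r$covered_fraction,
               expected_coverage_fraction = r$expected_coverage_fraction,
               obs_exp_ratio = r$obs_exp_ratio,
               detected = r$detected, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
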