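#' Configuration for the planted-structure matrix generator
#'
#' Describes a synthetic killing matrix with planted module blocks, optional
#' exclusive one-to-one singleton pairs and an optional strictly nested block,
#' emulating the nested-modular architecture with abundant one-to-one
#' infections seen in large environmental phage-host surveys.
#'
#' @param n_hosts,n_phages core dimensions (before singleton/nested additions).
#' @param n_modules number of planted modules (>= 1); block sizes as equal as
#'   possible, remainders going to the first blocks.
#' @param within_fill probability of a 1 inside a planted block.
#' @param between_fill probability of a 1 outside the blocks
#'   (`<= within_fill`).
#' @param n_singletons exclusive one-to-one pairs appended on fresh rows and
#'   columns.
#' @param nested_block optional side length of an appended strictly nested
#'   square block (strictly decreasing row degrees; stand-alone NODF 1).
#' @param seed integer seed.
#' @return A list of class `matrix_gen_config`.
#' @export
matrix_gen_config <- function(n_hosts, n_phages, n_modules = 1,
                              within_fill = 0.9, between_fill = 0.01,
                              n_singletons = 0, nested_block = NULL,
                              seed = 1L) {
  if (between_fill > within_fill) stop("between_fill must be <= within_fill")
  if (within_fill > 1 || between_fill < 0) stop("fills must be in [0, 1]")
  if (n_modules < 1) stop("n_modules must be >= 1")
  if (n_modules > min(n_hosts, n_phages)) {
    stop("more modules than rows or columns available")
  }
  structure(list(n_hosts = n_hosts, n_phages = n_phages,
                 n_modules = n_modules, within_fill = within_fill,
                 between_fill = between_fill, n_singletons = n_singletons,
                 nested_block = nested_block, seed = as.integer(seed)),
            class = "matrix_gen_config")
}

# split n into k near-equal parts, remainder on the first parts
near_equal_sizes <- function(n, k) {
  base <- n %/% k
  sizes <- rep(base, k)
  extra <- n - base * k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  sizes
}

#' Generate a matrix with planted modules, singletons and nesting
#'
#' Builds the planted blocks contiguously, fills within-block cells with
#' probability `within_fill` and the rest with `between_fill`, appends
#' `n_singletons` exclusive one-to-one pairs and the optional strictly nested
#' triangle on fresh rows/columns, then shuffles rows and columns (seeded).
#' Singleton pairs and the nested block each get their own ground-truth module
#' label.
#'
#' @param config a [matrix_gen_config()].
#' @return A list with `matrix` (an [interaction_matrix()]), `partition` (the
#'   planted `module_partition`, computed on the generated matrix), and
#'   `host_modules` / `phage_modules` (named ground-truth label vectors).
#' @export
generate_matrix <- function(config) {
  withr::with_seed(config$seed, {
    hs <- near_equal_sizes(config$n_hosts, config$n_modules)
    ps <- near_equal_sizes(config$n_phages, config$n_modules)
    host_mod <- rep(seq_len(config$n_modules), hs)
    phage_mod <- rep(seq_len(config$n_modules), ps)
    within <- outer(host_mod, phage_mod, `==`)
    fill <- ifelse(within, config$within_fill, config$between_fill)
    A <- matrix(stats::rbinom(length(fill), 1, fill), nrow(within), ncol(within))
    next_mod <- config$n_modules

    if (!is.null(config$nested_block) && config$nested_block > 0) {
      nb <- config$nested_block
      tri <- outer(seq_len(nb), seq_len(nb), function(i, j) as.integer(j <= nb - i + 1))
      A <- rbind(cbind(A, matrix(0L, nrow(A), nb)),
                 cbind(matrix(0L, nb, ncol(A)), tri))
      next_mod <- next_mod + 1L
      host_mod <- c(host_mod, rep(next_mod, nb))
      phage_mod <- c(phage_mod, rep(next_mod, nb))
    }
    if (config$n_singletons > 0) {
      for (s in seq_len(config$n_singletons)) {
        A <- rbind(cbind(A, 0L), c(rep(0L, ncol(A)), 1L))
        next_mod <- next_mod + 1L
        host_mod <- c(host_mod, next_mod)
        phage_mod <- c(phage_mod, next_mod)
      }
    }
    rownames(A) <- sprintf("H%03d", seq_len(nrow(A)))
    colnames(A) <- sprintf("P%03d", seq_len(ncol(A)))
    names(host_mod) <- rownames(A)
    names(phage_mod) <- colnames(A)
    rperm <- sample.int(nrow(A))
    cperm <- sample.int(ncol(A))
    A <- A[rperm, cperm, drop = FALSE]
    host_mod <- host_mod[rownames(A)]
    phage_mod <- phage_mod[colnames(A)]
    m <- interaction_matrix(A)
    part <- if (sum(A) > 0) module_partition(m, host_mod, phage_mod) else NULL
    list(matrix = m, partition = part,
         host_modules = host_mod, phage_modules = phage_mod)
  })
}

#' Configuration for the genome-set generator
#'
#' A two-level taxonomy (genera containing species containing members) of
#' genomes with controlled sequence sharing: members of a species copy a
#' species template at a given identity, verbatim segments can be planted
#' between groups, and genera can be split into "no-flow" pools guaranteed to
#' share zero k-mers across pools.
#'
#' @param taxonomy named list: genus -> named integer vector of member counts
#'   per species, e.g. `list(g1 = c(s1 = 3, s2 = 2))`.
#' @param genome_length genome length in bases.
#' @param species_identity fraction of each member genome copied from its
#'   species template (rest randomized), in \[0, 1\].
#' @param planted_transfers optional data frame `donor`, `recipient`
#'   (genome ids), `length` (bases), `count`.
#' @param no_flow_partition optional named list pool -> character vector of
#'   genera; cross-pool pairs are regenerated until they share zero k-mers.
#' @param k k-mer length used for the no-flow guarantee (default 25).
#' @param seed integer seed.
#' @return A list of class `genome_gen_config`.
#' @export
genome_gen_config <- function(taxonomy, genome_length = 10000,
                              species_identity = 0.98,
                              planted_transfers = NULL,
                              no_flow_partition = NULL, k = 25, seed = 1L) {
  if (species_identity < 0 || species_identity > 1) {
    stop("species_identity must be in [0, 1]")
  }
  if (!is.null(planted_transfers) && any(planted_transfers$length < k)) {
    stop("planted transfer segments must be >= k bases")
  }
  structure(list(taxonomy = taxonomy, genome_length = genome_length,
                 species_identity = species_identity,
                 planted_transfers = planted_transfers,
                 no_flow_partition = no_flow_partition, k = k,
                 seed = as.integer(seed)),
            class = "genome_gen_config")
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Generate genomes with controlled k-mer sharing
#'
#' One random template per species; each member copies `species_identity` of
#' the template positions and randomizes the rest; planted transfers copy
#' verbatim donor segments into recipients at random positions; genera in
#' different no-flow pools are resampled (bounded retries) until every
#' cross-pool genome pair shares zero canonical k-mers. Deterministic given
#' the seed.
#'
#' @param config a [genome_gen_config()].
#' @param max_retries resampling attempts for the no-flow guarantee.
#' @return A list with `genomes` (named character vector; ids
#'   `<genus>.<species>.<member>`) and `annotations` (data frame in
#'   [read_phage_annotations()] layout, morphotype/life_history set to
#'   `"unknown"`).
#' @export
generate_genomes <- function(config, max_retries = 20) {
  withr::with_seed(config$seed, {
    tax <- config$taxonomy
    genomes <- character(0)
    ann <- NULL
    for (genus in names(tax)) {
      for (species in names(tax[[genus]])) {
        template <- random_dna(config$genome_length)
        for (mem in seq_len(tax[[genus]][[species]])) {
          id <- paste(genus, species, mem, sep = ".")
          g <- mutate_from_template(template, config$species_identity)
          genomes[id] <- g
          ann <- rbind(ann, data.frame(phage_id = id,
                                       species_group = paste(genus, species, sep = "."),
                                       genus_group = genus,
                                       morphotype = "unknown",
                                       life_history = "unknown",
                                       stringsAsFactors = FALSE))
        }
      }
    }
    if (!is.null(config$planted_transfers)) {
      pt <- config$planted_transfers
      for (r in seq_len(nrow(pt))) {
        for (cnt in seq_len(pt$count[r])) {
          donor <- genomes[[pt$donor[r]]]
          recip <- genomes[[pt$recipient[r]]]
          len <- pt$length[r]
          from <- sample.int(nchar(donor) - len + 1, 1)
          seg <- substring(donor, from, from + len - 1)
          at <- sample.int(nchar(recip) - len + 1, 1)
          genomes[[pt$recipient[r]]] <- paste0(substring(recip, 1, at - 1), seg,
                                               substring(recip, at + len, nchar(recip)))
        }
      }
    }
    if (!is.null(config$no_flow_partition)) {
      genomes <- enforce_no_flow(genomes, ann, config, max_retries)
    }
    list(genomes = genomes, annotations = ann)
  })
}

mutate_from_template <- function(template, identity) {
  v <- strsplit(template, "", fixed = TRUE)[[1]]
  flip <- which(stats::runif(length(v)) > identity)
  if (length(flip)) v[flip] <- sample(DNA_BASES, length(flip), replace = TRUE)
  paste(v, collapse = "")
}

enforce_no_flow <- function(genomes, ann, config, max_retries) {
  pools <- config$no_flow_partition
  pool_of_genus <- stats::setNames(rep(names(pools), lengths(pools)),
                                   unlist(pools, use.names = FALSE))
  pool <- pool_of_genus[ann$genus_group[match(names(genomes), ann$phage_id)]]
  profiles <- lapply(stats::setNames(names(genomes), names(genomes)), function(id) {
    kmer_profile(genomes[[id]], k = config$k, genome_id = id)$kmers
  })
  for (try in seq_len(max_retries)) {
    offenders <- character(0)
    ids <- names(genomes)
    for (i in seq_along(ids)[-1]) {
      for (j in seq_len(i - 1)) {
        if (!is.na(pool[i]) && !is.na(pool[j]) && pool[i] != pool[j] &&
            length(intersect(profiles[[ids[i]]], profiles[[ids[j]]]))) {
          offenders <- c(offenders, ids[i])
        }
      }
    }
    if (!length(offenders)) return(genomes)
    for (id in unique(offenders)) {
      genomes[[id]] <- mutate_from_template(random_dna(config$genome_length), 1)
      profiles[[id]] <- kmer_profile(genomes[[id]], k = config$k)$kmers
    }
  }
  stop("no-flow pools could not be separated after ", max_retries, " retries")
}

#' Write genomes as multi-FASTA
#'
#' @param genomes named character vector of sequences.
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_genomes_fasta <- function(genomes, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genomes), path)
  invisible(path)
}

#' Generate taxonomically structured host-range groups
#'
#' Each species receives a template kill vector; members copy the template and
#' flip each bit with the noise rate. Species templates inside a genus share a
#' controlled fraction of their killed hosts (`template_overlap`), so with
#' disjoint templates (`template_overlap = 0`) and no noise the species are
#' perfectly concordant while genera are not — the qualitative contrast
#' between species- and genus-level host-range overlap.
#'
#' @param taxonomy named list: genus -> named integer vector of member counts
#'   per species.
#' @param n_hosts number of hosts; must accommodate the disjoint template
#'   parts of every genus.
#' @param kill_breadth hosts killed per species template.
#' @param template_overlap fraction of each template shared within its genus,
#'   in \[0, 1\].
#' @param noise per-bit flip probability for members, in \[0, 1\].
#' @param seed integer seed.
#' @return A list with `matrix` (an [interaction_matrix()]; members with an
#'   all-zero noisy profile get their template's first host back so every
#'   phage kills >= 1 host) and `annotations`.
#' @export
generate_host_range_groups <- function(taxonomy, n_hosts = 60,
                                       kill_breadth = 6,
                                       template_overlap = 0, noise = 0,
                                       seed = 1L) {
  if (noise < 0 || noise > 1) stop("noise must be in [0, 1]")
  if (n_hosts < 2) stop("need >= 2 hosts for meaningful profiles")
  n_species_total <- sum(lengths(taxonomy))
  core <- round(template_overlap * kill_breadth)
  need <- max(vapply(taxonomy, function(sp) {
    core + (kill_breadth - core) * length(sp)
  }, numeric(1)))
  if (need > n_hosts) stop("n_hosts too small for disjoint species templates")
  withr::with_seed(seed, {
    phage_ids <- character(0)
    ann <- NULL
    profiles <- NULL
    host_pool <- seq_len(n_hosts)
    for (genus in names(taxonomy)) {
      sp_names <- names(taxonomy[[genus]])
      genus_hosts <- sample(host_pool, core + (kill_breadth - core) * length(sp_names))
      core_hosts <- genus_hosts[seq_len(core)]
      rest <- setdiff(genus_hosts, core_hosts)
      for (si in seq_along(sp_names)) {
        own <- rest[seq((si - 1) * (kill_breadth - core) + 1,
                        si * (kill_breadth - core))]
        template <- integer(n_hosts)
        template[c(core_hosts, own)] <- 1L
        for (mem in seq_len(taxonomy[[genus]][[sp_names[si]]])) {
          id <- paste(genus, sp_names[si], mem, sep = ".")
          prof <- template
          if (noise > 0) {
            flip <- stats::runif(n_hosts) < noise
            prof[flip] <- 1L - prof[flip]
          }
          if (sum(prof) == 0) prof[c(core_hosts, own)[1]] <- 1L
          profiles <- cbind(profiles, prof)
          phage_ids <- c(phage_ids, id)
          ann <- rbind(ann, data.frame(phage_id = id,
                                       species_group = paste(genus, sp_names[si], sep = "."),
                                       genus_group = genus,
                                       morphotype = "unknown",
                                       life_history = "unknown",
                                       stringsAsFactors = FALSE))
        }
      }
    }
    colnames(profiles) <- phage_ids
    rownames(profiles) <- sprintf("H%03d", seq_len(n_hosts))
    list(matrix = interaction_matrix(profiles), annotations = ann)
  })
}
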