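#' Killing-profile probability vectors for every phage
#'
#' Each phage's binary kill vector x over the m hosts of the matrix is
#' normalized to a probability distribution p = x / sum(x) describing where its
#' killing falls. Phages that kill no host have no defined profile and are
#' excluded (with a message) unless `drop_empty = FALSE`, in which case they
#' raise an error downstream.
#'
#' @param m an [interaction_matrix()].
#' @param drop_empty drop zero-kill phages (default `TRUE`).
#' @return A named list of numeric probability vectors, one per phage.
#' @export
host_range_profiles <- function(m, drop_empty = TRUE) {
  A <- unclass(m)
  kills <- colSums(A)
  if (drop_empty && any(kills == 0)) {
    message("excluding ", sum(kills == 0), " phage(s) with zero kills")
    A <- A[, kills > 0, drop = FALSE]
    kills <- kills[kills > 0]
  }
  lapply(stats::setNames(seq_len(ncol(A)), colnames(A)),
         function(j) A[, j] / kills[j])
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Scaled host-range divergence of a set of phages
#'
#' The generalized Jensen-Shannon divergence of the phages' killing probability
#' vectors, normalized by log2(n):
#' `D_h = (H(mean of p) - mean of H(p)) / log2(n)` with entropies in bits.
#' `D_h = 0` means all host ranges overlap exactly; `D_h = 1` means they are
#' pairwise disjoint. Concordance is `1 - D_h`.
#'
#' @param profiles a list of >= 2 probability vectors over the same host set
#'   (as from [host_range_profiles()]), or an [interaction_matrix()] whose
#'   phage columns are used.
#' @return `D_h` in \[0, 1\].
#' @export
scaled_divergence <- function(profiles) {
  if (inherits(profiles, "interaction_matrix")) {
    kills <- colSums(profiles)
    if (any(kills == 0)) {
      stop("zero-kill profile(s) for phage(s): ",
           paste(colnames(profiles)[kills == 0], collapse = ", "))
    }
    profiles <- host_range_profiles(profiles)
  }
  n <- length(profiles)
  if (n < 2) stop("need >= 2 profiles")
  len <- lengths(profiles)
  if (length(unique(len)) != 1) stop("profiles span different host sets")
  for (nm in names(profiles)) {
    s <- sum(profiles[[nm]])
    if (!isTRUE(all.equal(s, 1))) {
      stop("profile does not sum to 1 (zero-kill phage?): ", nm)
    }
  }
  P <- do.call(rbind, profiles)
  gjsd <- entropy_bits(colMeans(P)) - mean(apply(P, 1, entropy_bits))
  min(max(gjsd / log2(n), 0), 1)
}

#' Host-range concordance of taxonomic phage groups
#'
#' Computes `1 - D_h` for every phage species or genus with at least two
#' usable members. In `all_members` mode every annotated phage with >= 1 kill
#' enters its group's calculation; in `single_representative` mode one phage is
#' drawn uniformly at random (seeded) per species inside each genus first, the
#' conservative counterpoint when species are unevenly sampled.
#'
#' @param m an [interaction_matrix()].
#' @param annotations data frame as from [read_phage_annotations()], covering
#'   every phage of the matrix with >= 1 kill.
#' @param level `"species"` or `"genus"`.
#' @param mode `"all_members"` or `"single_representative"` (only meaningful at
#'   genus level; at species level the modes coincide).
#' @param seed integer seed for representative draws.
#' @return A data frame with one row per usable group: `group_id`, `level`,
#'   `mode`, `n` (profiles used), `D_h`, `concordance`. Groups skipped for
#'   having < 2 usable members are recorded in the `"skipped"` attribute.
#' @export
group_concordance <- function(m, annotations, level = c("species", "genus"),
                              mode = c("all_members", "single_representative"),
                              seed = 1L) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  annotations <- validate_phage_annotations(annotations)
  kills <- colSums(m)
  usable <- colnames(m)[kills > 0]
  unknown <- setdiff(usable, annotations$phage_id)
  if (length(unknown)) {
    stop("phage(s) in matrix without annotation: ",
         paste(unknown, collapse = ", "))
  }
  ann <- annotations[annotations$phage_id %in% usable, , drop = FALSE]
  if (mode == "single_representative") {
    ann <- withr::with_seed(seed, {
      picks <- unlist(lapply(split(ann$phage_id, ann$species_group), function(ids) {
        if (length(ids) == 1) ids else sample(ids, 1)
      }), use.names = FALSE)
      ann[ann$phage_id %in% picks, , drop = FALSE]
    })
  }
  group_col <- if (level == "species") ann$species_group else ann$genus_group
  groups <- split(ann$phage_id, group_col)
  profiles <- host_range_profiles(m[, usable, drop = FALSE])
  skipped <- names(groups)[lengths(groups) < 2]
  groups <- groups[lengths(groups) >= 2]
  if (!length(groups)) {
    res <- data.frame(group_id = character(0), level = character(0),
                      mode = character(0), n = integer(0), D_h = numeric(0),
                      concordance = numeric(0), stringsAsFactors = FALSE)
    attr(res, "skipped") <- skipped
    return(res)
  }
  res <- data.frame(group_id = names(groups),
                    level = level, mode = mode,
                    n = unname(lengths(groups)),
                    D_h = vapply(groups, function(ids) {
                      scaled_divergence(profiles[ids])
                    }, numeric(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  res$concordance <- 1 - res$D_h
  attr(res, "skipped") <- skipped
  res
}

#' Compare concordance distributions between taxonomic levels
#'
#' Two-sided Welch's (unequal-variance) t-test between species-level and
#' genus-level concordance values.
#'
#' @param species_concordances,genus_concordances numeric vectors (>= 2 each).
#' @return A list with `statistic` (t), `df` and `p_value`.
#' @export
compare_levels <- function(species_concordances, genus_concordances) {
  if (length(species_concordances) < 2 || length(genus_concordances) < 2) {
    stop("need >= 2 values per level")
  }
  safe_t_test(species_concordances, genus_concordances, var.equal = FALSE)
}

# t.test wrapper handling zero-variance degenerate samples per contract:
# equal constant samples -> t = 0, p = 1; unequal constants -> |t| = Inf, p = 0
safe_t_test <- function(x, y, var.equal = FALSE) {
  out <- tryCatch({
    tt <- stats::t.test(x, y, var.equal = var.equal)
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
  }, error = function(e) {
    if (grepl("essentially constant", conditionMessage(e))) {
      d <- mean(x) - mean(y)
      list(statistic = if (d == 0) 0 else sign(d) * Inf,
           df = length(x) + length(y) - 2,
           p_value = if (d == 0) 1 else 0)
    } else stop(e)
  })
  out
}

#' Kill-breadth statistics per phage morphotype
#'
#' Mean and standard deviation of strains killed per morphotype, plus all
#' pairwise two-sided Student's (equal-variance) t-tests between morphotypes
#' with >= 2 phages.
#'
#' @param m an [interaction_matrix()].
#' @param annotations data frame covering every phage with a `morphotype`.
#' @return A list with `summary` (data frame: morphotype, n, mean, sd) and
#'   `tests` (data frame: group_a, group_b, t, p_value).
#' @export
morphotype_kill_stats <- function(m, annotations) {
  annotations <- validate_phage_annotations(annotations)
  missing <- setdiff(colnames(m), annotations$phage_id)
  if (length(missing)) {
    stop("phage(s) without morphotype annotation: ", paste(missing, collapse = ", "))
  }
  breadth <- colSums(m)
  morph <- annotations$morphotype[match(colnames(m), annotations$phage_id)]
  by_group <- split(as.numeric(breadth), morph)
  summ <- data.frame(morphotype = names(by_group),
                     n = unname(lengths(by_group)),
                     mean = vapply(by_group, mean, numeric(1)),
                     sd = vapply(by_group, stats::sd, numeric(1)),
                     row.names = NULL, stringsAsFactors = FALSE)
  testable <- names(by_group)[lengths(by_group) >= 2]
  tests <- NULL
  if (length(testable) >= 2) {
    pairs <- utils::combn(testable, 2)
    tests <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                        t = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE)
    for (r in seq_len(ncol(pairs))) {
      tt <- safe_t_test(by_group[[pairs[1, r]]], by_group[[pairs[2, r]]],
                        var.equal = TRUE)
      tests$t[r] <- tt$statistic
      tests$p_value[r] <- tt$p_value
    }
  }
  list(summary = summ, tests = tests)
}

#' Compare kill breadths between life-history strategies
#'
#' Two-sample two-sided Kolmogorov-Smirnov test between kill-breadth values of
#' temperate versus virulent phage groups.
#'
#' @param kill_breadths_temperate,kill_breadths_virulent numeric vectors.
#' @return A list with `D` and `p_value`.
#' @export
life_history_ks <- function(kill_breadths_temperate, kill_breadths_virulent) {
  if (!length(kill_breadths_temperate) || !length(kill_breadths_virulent)) {
    stop("both samples must be nonempty")
  }
  ks <- suppressWarnings(stats::ks.test(kill_breadths_temperate,
                                        kill_breadths_virulent,
                                        alternative = "two.sided"))
  list(D = unname(ks$statistic), p_value = ks$p.value)
}

#' Compose the relative contribution of recombination to mutation
#'
#' r/m = (R/theta) * delta * nu, where R/theta is the recombination-to-mutation
#' rate ratio, delta the mean import length in bases, and nu the nucleotide
#' distance of imported sequence.
#'
#' @param R_over_theta,delta,nu nonnegative values (scalars or equal-length
#'   vectors).
#' @param group_id optional group labels.
#' @return A data frame with the inputs and their product `r_over_m`.
#' @export
rm_value <- function(R_over_theta, delta, nu, group_id = NULL) {
  if (any(R_over_theta < 0) || any(delta < 0) || any(nu < 0)) {
    stop("r/m components must be nonnegative")
  }
  out <- data.frame(R_over_theta = R_over_theta, delta = delta, nu = nu,
                    r_over_m = R_over_theta * delta * nu)
  if (!is.null(group_id)) out <- cbind(group_id = group_id, out)
  out
}

#' Read a table of recombination parameter estimates
#'
#' Comma- or tab-separated with header
#' `group_id,R_over_theta,delta,nu`; the composed `r_over_m` column is added.
#'
#' @param path input table.
#' @return Data frame as from [rm_value()].
#' @export
read_rm_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) == 1) tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group_id", "R_over_theta", "delta", "nu")
  if (!all(need %in% names(tab))) {
    stop("r/m table must have columns: ", paste(need, collapse = ", "))
  }
  rm_value(tab$R_over_theta, tab$delta, tab$nu, group_id = tab$group_id)
}

#' Test whether r/m values exceed 1
#'
#' One-sample two-sided Wilcoxon signed-rank test of the r/m values against 1,
#' exact for n <= 25 (no zero differences or ties permitting).
#'
#' @param rm_values numeric vector with >= 1 value different from 1.
#' @return A list with `statistic` (V), `p_value` and `exact`.
#' @export
rm_group_test <- function(rm_values) {
  if (all(rm_values == 1)) stop("all r/m values equal 1; test carries no information")
  exact <- length(rm_values) <= 25
  wt <- suppressWarnings(stats::wilcox.test(rm_values, mu = 1,
                                            alternative = "two.sided",
                                            exact = exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Rank correlation between concordance and r/m
#'
#' Spearman rank correlation (average ranks for ties) between group-level host
#' range concordance and r/m, paired by group.
#'
#' @param concordances,rm_values numeric vectors of >= 3 paired values.
#' @return A list with `rho` and `defined` (`FALSE` with `rho = NA` when either
#'   input is constant).
#' @export
concordance_rm_correlation <- function(concordances, rm_values) {
  if (length(concordances) != length(rm_values)) stop("inputs must be paired")
  if (length(concordances) < 3) stop("need >= 3 pairs")
  if (stats::sd(concordances) == 0 || stats::sd(rm_values) == 0) {
    return(list(rho = NA_real_, defined = FALSE))
  }
  list(rho = stats::cor(concordances, rm_values, method = "spearman"),
       defined = TRUE)
}
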