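#' Construct a binary phage-bacteria interaction matrix
#'
#' The central object of the package: a binary matrix with bacterial hosts as
#' rows and phages as columns, cell 1 meaning the phage lysed the host in an
#' agar overlay assay and 0 meaning no lysis.
#'
#' @param cells integer or numeric matrix of 0/1 values, hosts in rows and
#'   phages in columns.
#' @param host_ids character vector of unique host identifiers. Defaults to the
#'   rownames of `cells`.
#' @param phage_ids character vector of unique phage identifiers. Defaults to
#'   the colnames of `cells`.
#' @return An `interaction_matrix`: an integer matrix with `dimnames` set and
#'   class attribute `"interaction_matrix"`.
#' @examples
#' m <- interaction_matrix(rbind(h1 = c(1, 1), h2 = c(0, 1)),
#'                         phage_ids = c("p1", "p2"))
#' matrix_properties(m)
#' @export
interaction_matrix <- function(cells, host_ids = rownames(cells),
                               phage_ids = colnames(cells)) {
  cells <- as.matrix(cells)
  if (is.null(host_ids)) host_ids <- sprintf("h%d", seq_len(nrow(cells)))
  if (is.null(phage_ids)) phage_ids <- sprintf("p%d", seq_len(ncol(cells)))
  host_ids <- as.character(host_ids)
  phage_ids <- as.character(phage_ids)
  if (anyDuplicated(host_ids)) {
    stop("duplicate host identifiers: ",
         paste(unique(host_ids[duplicated(host_ids)]), collapse = ", "))
  }
  if (anyDuplicated(phage_ids)) {
    stop("duplicate phage identifiers: ",
         paste(unique(phage_ids[duplicated(phage_ids)]), collapse = ", "))
  }
  if (length(host_ids) != nrow(cells) || length(phage_ids) != ncol(cells)) {
    stop("identifier vectors do not match matrix dimensions")
  }
  bad <- which(!(cells %in% c(0L, 1L)) | is.na(cells))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(cells)) + 1
    j <- ((bad[1] - 1) %/% nrow(cells)) + 1
    stop(sprintf("non-binary cell value %s at host '%s', phage '%s'",
                 format(cells[bad[1]]), host_ids[i], phage_ids[j]))
  }
  storage.mode(cells) <- "integer"
  dimnames(cells) <- list(host_ids, phage_ids)
  class(cells) <- c("interaction_matrix", class(cells))
  cells
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("interaction_matrix: %d hosts x %d phages, %d interactions\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

host_ids <- function(m) rownames(m)
phage_ids <- function(m) colnames(m)

#' Read an interaction matrix from disk
#'
#' Two dialects are supported. `wide-tsv`: tab-separated, first column holds
#' host ids, header row holds phage ids, cells strictly `0`/`1`. `edge-list`: a
#' comma-separated file with header `host,phage`, one row per observed killing
#' interaction; the matrix gets a 1 at every listed pair and 0 elsewhere, rows
#' and columns ordered by first appearance.
#'
#' @param path file to read.
#' @param format `"wide-tsv"` (default) or `"edge-list"`.
#' @return An [interaction_matrix()].
#' @export
read_interaction_matrix <- function(path, format = c("wide-tsv", "edge-list")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  if (format == "wide-tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             row.names = NULL, check.names = FALSE,
                             colClasses = "character")
    if (nrow(tab) == 0 || ncol(tab) < 2) stop("empty or malformed matrix file: ", path)
    hosts <- tab[[1]]
    cells <- as.matrix(tab[, -1, drop = FALSE])
    suppressWarnings(storage.mode(cells) <- "numeric")
    interaction_matrix(cells, host_ids = hosts, phage_ids = colnames(tab)[-1])
  } else {
    edges <- utils::read.csv(path, header = TRUE, colClasses = "character")
    if (!all(c("host", "phage") %in% names(edges))) {
      stop("edge list must have a 'host,phage' header: ", path)
    }
    if (nrow(edges) == 0) stop("empty edge list: ", path)
    hosts <- unique(edges$host)
    phages <- unique(edges$phage)
    cells <- matrix(0L, length(hosts), length(phages),
                    dimnames = list(hosts, phages))
    cells[cbind(match(edges$host, hosts), match(edges$phage, phages))] <- 1L
    interaction_matrix(cells)
  }
}

#' Write an interaction matrix
#'
#' @param m an [interaction_matrix()].
#' @param path output file.
#' @param format `"wide-tsv"` or `"edge-list"` (only the 1-cells, first-appearance
#'   order by host then phage).
#' @return `path`, invisibly.
#' @export
write_interaction_matrix <- function(m, path, format = c("wide-tsv", "edge-list")) {
  format <- match.arg(format)
  if (format == "wide-tsv") {
    tab <- data.frame(host = rownames(m), unclass(m)[, , drop = FALSE],
                      check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(unclass(m) == 1L, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    edges <- data.frame(host = rownames(m)[idx[, 1]],
                        phage = colnames(m)[idx[, 2]])
    utils::write.csv(edges, path, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Summary properties of an interaction matrix
#'
#' Computes the standard descriptive properties of a binary bipartite killing
#' matrix: host count H, phage count P, species total S = H + P, interaction
#' count I, size M = H x P, connectance C = I/M, and the mean interactions per
#' host (L_H = I/H) and per phage (L_P = I/P). Values are kept at full
#' precision; [render_properties()] applies the conventional display rounding.
#'
#' @param m an [interaction_matrix()].
#' @return A list of class `matrix_properties` with fields `H`, `P`, `S`, `I`,
#'   `M`, `C`, `L_H`, `L_P`.
#' @seealso [properties_from_counts()] for computing the same quantities from
#'   published counts.
#' @export
matrix_properties <- function(m) {
  if (nrow(m) == 0 || ncol(m) == 0) stop("matrix must have >= 1 host and >= 1 phage")
  properties_from_counts(H = nrow(m), P = ncol(m), I = sum(m))
}

#' Matrix properties from published counts
#'
#' Same arithmetic as [matrix_properties()], starting from the host, phage and
#' interaction counts as printed in a summary table rather than from the matrix
#' itself.
#'
#' @param H host count. @param P phage count. @param I interaction count.
#' @return A `matrix_properties` list.
#' @export
properties_from_counts <- function(H, P, I) {
  if (H < 1 || P < 1) stop("matrix must have >= 1 host and >= 1 phage")
  if (I < 0 || I > H * P) stop("interaction count outside [0, H*P]")
  structure(list(H = H, P = P, S = H + P, I = I, M = H * P,
                 C = I / (H * P), L_H = I / H, L_P = I / P),
            class = "matrix_properties")
}

round_half_up <- function(x, digits) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Render matrix properties at conventional precision
#'
#' Connectance is displayed with 2 decimals and the mean-interaction counts
#' with 1 decimal (half-up rounding); counts are printed as integers. The
#' underlying values are never rounded.
#'
#' @param props a `matrix_properties` list.
#' @return Named character vector of rendered values.
#' @export
render_properties <- function(props) {
  c(H = format(props$H), P = format(props$P), S = format(props$S),
    I = format(props$I), M = format(props$M),
    C = sprintf("%.2f", round_half_up(props$C, 2)),
    L_H = sprintf("%.1f", round_half_up(props$L_H, 1)),
    L_P = sprintf("%.1f", round_half_up(props$L_P, 1)))
}

#' @export
print.matrix_properties <- function(x, ...) {
  r <- render_properties(x)
  cat(sprintf("H=%s P=%s S=%s I=%s M=%s C=%s L_H=%s L_P=%s\n",
              r["H"], r["P"], r["S"], r["I"], r["M"], r["C"], r["L_H"], r["L_P"]))
  invisible(x)
}

#' Drop hosts that no phage kills
#'
#' Restricts the matrix to hosts lysed by at least one phage (row sum >= 1),
#' the step that takes an assayed host panel down to the analysis host set.
#' The phage set and all orderings are unchanged.
#'
#' @param m an [interaction_matrix()].
#' @return An [interaction_matrix()] (possibly with zero hosts).
#' @export
filter_to_infected_hosts <- function(m) {
  keep <- rowSums(m) >= 1
  interaction_matrix(unclass(m)[keep, , drop = FALSE])
}

#' Exclusive one-to-one phage-host pairs
#'
#' Returns the pairs (host, phage) that interact exclusively with each other:
#' cell 1, host row sum 1 and phage column sum 1. These pairs form their own
#' singleton network modules under any sensible partition, so the count is
#' independent of the module-detection algorithm.
#'
#' @param m an [interaction_matrix()].
#' @return A data frame with columns `host` and `phage` (zero rows if none).
#' @export
singleton_pairs <- function(m) {
  rs <- rowSums(m)
  cs <- colSums(m)
  idx <- which(unclass(m) == 1L & outer(rs == 1, cs == 1, `&`), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(host = rownames(m)[idx[, 1]], phage = colnames(m)[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Read a phage annotation table
#'
#' Tab-separated with header
#' `phage_id, species_group, genus_group, morphotype, life_history`.
#' Species labels must nest in genus labels (each species maps to exactly one
#' genus).
#'
#' @param path annotation TSV.
#' @return A data frame with the five columns as character vectors.
#' @export
read_phage_annotations <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  validate_phage_annotations(ann)
}

validate_phage_annotations <- function(ann) {
  need <- c("phage_id", "species_group", "genus_group", "morphotype", "life_history")
  if (!all(need %in% names(ann))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(ann$phage_id)) stop("duplicate phage_id in annotations")
  genus_per_species <- tapply(ann$genus_group, ann$species_group,
                              function(g) length(unique(g)))
  if (any(genus_per_species > 1)) {
    stop("species mapping to multiple genera: ",
         paste(names(genus_per_species)[genus_per_species > 1], collapse = ", "))
  }
  ann
}
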