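#' NODF nestedness
#'
#' Nestedness by Overlap and Decreasing Fill. For every ordered pair of rows
#' (i, j) with strictly decreasing degree k_i > k_j > 0 the paired score is the
#' fraction of row j's interactions that also occur in row i,
#' `|N_i intersect N_j| / k_j`; pairs with tied degrees or an empty inner row
#' score 0. Columns are scored the same way. NODF is the sum of all paired
#' scores divided by the total number of row pairs plus column pairs, reported
#' on \[0, 1\].
#'
#' @param m an [interaction_matrix()] with at least 2 hosts and 2 phages.
#' @return A list of class `nestedness_result` with `nodf`, `row_component`
#'   (mean paired score over host pairs) and `col_component` (over phage
#'   pairs).
#' @export
nodf <- function(m) {
  if (nrow(m) < 2 || ncol(m) < 2) stop("NODF needs >= 2 hosts and >= 2 phages")
  A <- unclass(m)
  row_scores <- nodf_axis_scores(A)
  col_scores <- nodf_axis_scores(t(A))
  n_row_pairs <- choose(nrow(A), 2)
  n_col_pairs <- choose(ncol(A), 2)
  structure(list(nodf = (sum(row_scores) + sum(col_scores)) /
                   (n_row_pairs + n_col_pairs),
                 row_component = sum(row_scores) / n_row_pairs,
                 col_component = sum(col_scores) / n_col_pairs),
            class = "nestedness_result")
}

# paired overlap scores over all unordered row pairs of A (one value per pair)
nodf_axis_scores <- function(A) {
  deg <- rowSums(A)
  overlap <- tcrossprod(A)        # |N_i intersect N_j|
  lo <- outer(deg, deg, pmin)
  tied <- outer(deg, deg, `==`)
  score <- ifelse(!tied & lo > 0, overlap / pmax(lo, 1), 0)
  score[upper.tri(score)]
}

#' @export
print.nestedness_result <- function(x, ...) {
  cat(sprintf("NODF = %.4f (rows %.4f, cols %.4f)\n",
              x$nodf, x$row_component, x$col_component))
  invisible(x)
}
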