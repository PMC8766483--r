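#' Draw one equiprobable null matrix
#'
#' Places exactly I ones uniformly at random without replacement among the
#' H x P cells, so every replicate preserves the observed connectance exactly
#' while every cell is equally likely to be filled.
#'
#' @param H hosts. @param P phages. @param I interactions to place.
#' @return An [interaction_matrix()] with `I` ones.
#' @export
equiprobable_matrix <- function(H, P, I) {
  if (I > H * P) stop("cannot place more interactions than cells")
  cells <- integer(H * P)
  cells[sample.int(H * P, I)] <- 1L
  interaction_matrix(matrix(cells, H, P))
}

null_statistics <- list(
  qb_max = function(m, kl_tuning = TRUE) {
    leading_eigenvector_modules(m, kl_tuning = kl_tuning)$Qb
  },
  nodf = function(m, ...) nodf(m)$nodf
)

#' Equiprobable null-model significance test
#'
#' Tests an observed network statistic against an ensemble of random matrices
#' with the same dimensions and exactly the same number of interactions
#' (connectance preserved per replicate), each cell equally likely. Supported
#' statistics: `"qb_max"` (Barber modularity of the partition found by
#' [leading_eigenvector_modules()]) and `"nodf"`.
#'
#' @param m an [interaction_matrix()].
#' @param statistic `"qb_max"` or `"nodf"`.
#' @param n_replicates number of null matrices (>= 2).
#' @param seed integer seed; results are fully reproducible from it.
#' @param kl_tuning passed through to module detection for `"qb_max"`.
#' @return A list of class `null_model_result` with `statistic_name`,
#'   `observed`, `null_mean`, `null_std`, `z_score` (NA with `z_defined =
#'   FALSE` when the null ensemble is degenerate), `percentile` (percent of
#'   replicates <= observed), `n_replicates`, `seed`, and the replicate values
#'   in `null_values`.
#' @export
equiprobable_null <- function(m, statistic = c("qb_max", "nodf"),
                              n_replicates = 1000, seed = 1L,
                              kl_tuning = TRUE) {
  statistic <- match.arg(statistic)
  if (n_replicates < 2) stop("need >= 2 null replicates")
  stat_fun <- null_statistics[[statistic]]
  observed <- stat_fun(m, kl_tuning = kl_tuning)
  H <- nrow(m); P <- ncol(m); I <- sum(m)
  null_values <- withr::with_seed(seed, {
    vapply(seq_len(n_replicates), function(r) {
      stat_fun(equiprobable_matrix(H, P, I), kl_tuning = kl_tuning)
    }, numeric(1))
  })
  null_mean <- mean(null_values)
  null_std <- stats::sd(null_values)
  z_defined <- null_std > 0
  structure(list(statistic_name = statistic,
                 observed = observed,
                 null_mean = null_mean,
                 null_std = null_std,
                 z_score = if (z_defined) (observed - null_mean) / null_std else NA_real_,
                 z_defined = z_defined,
                 percentile = 100 * mean(null_values <= observed),
                 n_replicates = n_replicates,
                 seed = seed,
                 null_values = null_values),
            class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf("%s: observed %.4f, null mean %.4f (sd %.4f), z = %s, percentile %.1f (%d reps)\n",
              x$statistic_name, x$observed, x$null_mean, x$null_std,
              if (x$z_defined) sprintf("%.2f", x$z_score) else "undefined",
              x$percentile, x$n_replicates))
  invisible(x)
}
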