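#' Per-feature Welch two-sample t-test
#'
#' Vectorised Welch (unequal-variance) t statistics and two-sided
#' p-values comparing the two groups, one test per feature column.
#' Features with zero variance in both groups are uninformative; their
#' p-value is set to 1 so they rank last.
#'
#' @param table A feature table with 0/1 `group` labels, each group of
#'   size at least 2.
#'
#' @return Tibble with `feature`, `index`, `statistic`, `df`, `p_value`.
#' @export
welch_t_table <- function(table) {
  validate_feature_table(table)
  X <- feature_matrix(table)
  y <- as.integer(table$group)
  if (min(table(y)) < 2) abort("Each group needs at least 2 subjects.")
  X0 <- X[y == 0L, , drop = FALSE]
  X1 <- X[y == 1L, , drop = FALSE]
  n0 <- nrow(X0); n1 <- nrow(X1)
  m0 <- colMeans(X0); m1 <- colMeans(X1)
  v0 <- apply(X0, 2, var); v1 <- apply(X1, 2, var)
  se2 <- v0 / n0 + v1 / n1
  t_stat <- (m0 - m1) / sqrt(se2)
  df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  p <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  degenerate <- se2 == 0 | !is.finite(t_stat)
  t_stat[degenerate] <- 0
  df[degenerate] <- NA_real_
  p[degenerate] <- 1
  tibble::tibble(feature = colnames(X), index = seq_along(p),
                 statistic = unname(t_stat), df = unname(df),
                 p_value = unname(p))
}
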