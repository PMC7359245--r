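#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a randomization-test result
#'
#' One row per null draw, with the observed statistic alongside.
#'
#' @param x A `perm_test` object.
#' @param ... Unused.
#' @return A tibble with columns `draw`, `null_value`, `observed`.
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(
    draw = seq_along(x$null_values),
    null_value = x$null_values,
    observed = x$observed
  )
}

#' One-row summary of a randomization-test result
#'
#' @param x A `perm_test` object.
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `observed`, `p_value`,
#'   `p_smoothed`, `p_positive` (where applicable), `n_permutations`.
#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    observed = x$observed,
    p_value = x$p_value,
    p_smoothed = x$p_smoothed,
    p_positive = x$p_positive %||% NA_real_,
    n_permutations = x$n_permutations
  )
}

#' Tidy a signal-clustering result into pairwise correlations
#'
#' @param x A `signal_clust` object from [correlate_signals()].
#' @param ... Unused.
#' @return A tibble with columns `signal_a`, `signal_b`, `rho`.
#' @method tidy signal_clust
#' @export
tidy.signal_clust <- function(x, ...) {
  nm <- colnames(x$rho)
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble::tibble(
    signal_a = nm[idx[, 1]],
    signal_b = nm[idx[, 2]],
    rho = x$rho[idx]
  )
}
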