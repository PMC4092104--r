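#' Tidy a paired comparison
#'
#' @param x A `paired_comparison` from [paired_t()].
#' @param ... Unused.
#' @return A one-row tibble: `n_pairs`, `mean_pre`, `mean_post`,
#'   `mean_difference`, `t_statistic`, `df`, `p_value`.
#' @export
tidy.paired_comparison <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n_pairs, mean_pre = x$mean_pre, mean_post = x$mean_post,
    mean_difference = x$mean_difference, t_statistic = x$t_statistic,
    df = x$df, p_value = x$p_value
  )
}

#' @rdname tidy.paired_comparison
#' @export
glance.paired_comparison <- function(x, ...) tidy.paired_comparison(x)

#' Tidy a manual-vs-automated validation report
#'
#' @param x A `validation_report` from [validate_against_manual()].
#' @param ... Unused.
#' @return A one-row tibble: `n`, `r`, `p_value`.
#' @export
tidy.validation_report <- function(x, ...) {
  tibble::tibble(n = x$n, r = x$r, p_value = x$p_value)
}

#' @rdname tidy.validation_report
#' @export
glance.validation_report <- function(x, ...) tidy.validation_report(x)
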