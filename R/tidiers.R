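#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a comparison report
#'
#' One row per compared ion: predicted and measured relative
#' intensities, the base-10 log relative error, and the absolute linear
#' discrepancy.
#'
#' @param x A `comparison_report` from [log_error()].
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.comparison_report <- function(x, ...) {
  tibble::as_tibble(x$per_ion)
}

#' One-row summary of a comparison report
#'
#' @param x A `comparison_report` from [log_error()].
#' @param ... Unused.
#' @return A one-row tibble with `n_ions`, `sum_abs_log_err`,
#'   `max_abs_discrepancy`, `order_match`, `kendall_tau`.
#' @exportS3Method generics::glance
glance.comparison_report <- function(x, ...) {
  tibble::tibble(
    n_ions = x$n_ions,
    sum_abs_log_err = x$sum_abs_log_err,
    max_abs_discrepancy = x$max_abs_discrepancy,
    order_match = x$order_match,
    kendall_tau = x$kendall_tau
  )
}
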