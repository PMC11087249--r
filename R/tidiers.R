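#' Tidy a cohort summary
#'
#' Broom-style one-row-per-term view of an `immunotopo_cohort`: one row per
#' immune class and compartment with the paired-test statistics and the
#' fraction of cases higher in K17-negative zones.
#'
#' @param x An `immunotopo_cohort` from [cohort_summary()].
#' @param ... Unused.
#' @return A tibble.
#' @importFrom generics tidy
#' @export
tidy.immunotopo_cohort <- function(x, ...) x$summary

#' Glance at a cohort summary
#'
#' @param x An `immunotopo_cohort`.
#' @param ... Unused.
#' @return One-row tibble: `n_cases`, `n_tests`, `min_p_value`,
#'   `max_fraction_higher_in_neg`.
#' @importFrom generics glance
#' @export
glance.immunotopo_cohort <- function(x, ...) {
  tibble(n_cases = x$n_cases,
         n_tests = nrow(x$summary),
         min_p_value = min(x$summary$p_value),
         max_fraction_higher_in_neg = max(x$summary$fraction_higher_in_neg))
}

#' @rdname tidy.immunotopo_cohort
#' @export
tidy.immunotopo_run <- function(x, ...) tidy(x$cohort)

#' @rdname glance.immunotopo_cohort
#' @export
glance.immunotopo_run <- function(x, ...) glance(x$cohort)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
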