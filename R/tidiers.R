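#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a group test result
#'
#' One row per pairwise comparison (Tukey HSD results), or per group for a
#' plain ANOVA.
#'
#' @param x A `group_test_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.group_test_result <- function(x, ...) {
  if (!is.null(x$pairwise)) x$pairwise else x$groups
}

#' @rdname tidy.group_test_result
#' @export
glance.group_test_result <- function(x, ...) {
  tibble::tibble(statistic = x$F, p.value = x$p,
                 df = x$df[["between"]], df.residual = x$df[["within"]],
                 n.groups = nrow(x$groups),
                 n.pairs = if (is.null(x$pairwise)) NA_integer_
                 else nrow(x$pairwise),
                 alpha = x$alpha, method = x$method)
}

#' Tidy an iterative Tukey result
#' @param x An `iterative_tukey_result`.
#' @param ... Unused.
#' @return A tibble of pairwise rejection frequencies and decisions.
#' @export
tidy.iterative_tukey_result <- function(x, ...) x$pairs

#' @rdname tidy.iterative_tukey_result
#' @export
glance.iterative_tukey_result <- function(x, ...) {
  tibble::tibble(n_iter = x$n_iter, n_sample = x$n_sample, alpha = x$alpha,
                 freq_rule = x$freq_rule,
                 n_significant = sum(x$pairs$significant),
                 n_pairs = nrow(x$pairs))
}

#' Tidy an agreement report
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return Per-stratum agreement tibble.
#' @export
tidy.agreement_report <- function(x, ...) x$per_stratum

#' @rdname tidy.agreement_report
#' @export
glance.agreement_report <- function(x, ...) {
  tibble::tibble(overall = x$overall, n_strata = nrow(x$per_stratum))
}
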