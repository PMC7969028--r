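#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Student's t test result
#'
#' @param x An `epi_ttest`.
#' @param ... Unused.
#' @return One-row tibble with `estimate`, `statistic`, `df`, `p.value`,
#'   `method`, `n_x`, `n_y`.
#' @export
tidy.epi_ttest <- function(x, ...) {
  tibble(
    estimate = x$estimate, statistic = x$statistic, df = x$df,
    p.value = x$p_value,
    method = sprintf("Two-tailed %s Student's t test", x$flavor),
    n_x = x$n_x, n_y = x$n_y
  )
}

#' @rdname tidy.epi_ttest
#' @export
glance.epi_ttest <- function(x, ...) tidy.epi_ttest(x)

#' Tidy a methylome clustering result
#'
#' @param x An `epi_meth_clust`.
#' @param ... Unused.
#' @return Tibble `sample`, `cluster` (k = 2 cut labels).
#' @export
tidy.epi_meth_clust <- function(x, ...) {
  tibble(sample = names(x$k2), cluster = unname(x$k2))
}

#' @rdname tidy.epi_meth_clust
#' @export
glance.epi_meth_clust <- function(x, ...) {
  tibble(n_samples = length(x$k2), n_shared_sites = x$n_shared_sites,
         height = max(x$hclust$height))
}

#' Tidy a TSS-anchored enrichment profile
#'
#' @param x An `epi_profile`.
#' @param ... Unused.
#' @return The aggregate profile as a tibble `offset`, `mean`, plus sample
#'   metadata columns.
#' @export
tidy.epi_profile <- function(x, ...) {
  x$aggregate %>%
    mutate(sample_id = x$sample_id %||% NA_character_,
           mark = x$mark %||% NA_character_,
           genotype = x$genotype %||% NA_character_)
}
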