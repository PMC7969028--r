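#' Plot a TSS-anchored enrichment profile
#'
#' @param profile An `epi_profile`, or a tibble of several tidied profiles
#'   (columns `offset`, `mean` and optionally `sample_id`).
#' @return A ggplot object.
#' @export
plot_profile <- function(profile) {
  df <- if (inherits(profile, "epi_profile")) tidy(profile) else as_tibble(profile)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$mean))
  if ("sample_id" %in% names(df) && length(unique(df$sample_id)) > 1) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$sample_id))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "distance from anchor (bp)", y = "mean signal (RPKM)") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.epi_profile <- function(object, ...) plot_profile(object)

#' Boxplot of expression by promoter chromatin state
#'
#' Draws the per-state FPKM distribution on a log scale, box hinges at the
#' quartiles and whiskers by the 1.5 x IQR rule.
#'
#' @param states Output of [classify_promoter_states()].
#' @param expression Tibble with `gene_id` and FPKM columns.
#' @param sample FPKM column to plot.
#' @param pseudo Pseudo-FPKM added before the log transform.
#' @return A ggplot object.
#' @export
plot_expression_by_state <- function(states, expression, sample = "WT", pseudo = 0.1) {
  df <- states %>%
    inner_join(expression, by = "gene_id") %>%
    mutate(state = factor(.data$state, levels = promoter_state_names()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state,
                                   y = .data[[sample]] + pseudo)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "promoter state", y = sprintf("%s FPKM (+%g)", sample, pseudo)) +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Violin plot of methylation levels by cytosine context
#'
#' @param site_tables Named list of site tables (see [site_levels()]).
#' @return A ggplot object.
#' @export
plot_context_levels <- function(site_tables) {
  df <- purrr::imap_dfr(site_tables, function(s, nm) {
    as_tibble(s) %>% mutate(sample = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$context, y = .data$level,
                                   fill = .data$sample)) +
    ggplot2::geom_violin(scale = "width", adjust = 2) +
    ggplot2::labs(x = "cytosine context", y = "methylation level") +
    ggplot2::theme_classic()
}

#' Bar chart of bin change-class counts
#'
#' @param bin_changes Output of [classify_bin_changes()].
#' @param drop_unchanged Whether to omit the unchanged class (default TRUE,
#'   it usually dwarfs the rest).
#' @return A ggplot object.
#' @export
plot_bin_class_counts <- function(bin_changes, drop_unchanged = TRUE) {
  lv <- c(bin_class_names(), "mixed", "unchanged")
  df <- bin_changes %>% count(.data$class)
  if (drop_unchanged) df <- df %>% filter(.data$class != "unchanged")
  df <- df %>% mutate(class = factor(.data$class, levels = lv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "bin change class", y = "bins") +
    ggplot2::theme_classic()
}
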