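#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_vline
#'   geom_boxplot geom_jitter labs theme_minimal scale_colour_manual
NULL

#' @export
ggplot2::autoplot

#' Volcano plot of a DEG table
#'
#' log2 fold change against -log10 adjusted p for one comparison, DEGs
#' highlighted; the dashed lines mark the fold-change and significance gates.
#'
#' @param object A `deg_table`.
#' @param comparison Which comparison to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot deg_table
#' @export
autoplot.deg_table <- function(object, comparison = "CD_vs_control", ...) {
  df <- filter(as_tibble(object), .data$comparison == !!comparison,
               !is.na(.data$p_adjusted))
  fc <- attr(object, "fc_threshold") %||% 1
  alpha <- attr(object, "alpha") %||% 0.05
  ggplot(df, aes(x = .data$log2_fc, y = -log10(.data$p_adjusted),
                 colour = .data$is_deg)) +
    geom_point(alpha = 0.7) +
    geom_vline(xintercept = c(-fc, fc), linetype = "dashed", colour = "grey40") +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed", colour = "grey40") +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                        name = "DEG") +
    labs(title = comparison, x = "log2 fold change", y = "-log10 adjusted p") +
    theme_minimal()
}

#' Pathway-score plot for a QPA profile
#'
#' Per-sample pathway scores by group: the one-dimensional projection that
#' the permutation test compares between CD and UC.
#'
#' @param object A `qpa_profile`.
#' @param metadata Sample metadata supplying the groups.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qpa_profile
#' @export
autoplot.qpa_profile <- function(object, metadata, ...) {
  df <- tidy.qpa_profile(object) |>
    left_join(metadata, by = "sample_id")
  ggplot(df, aes(x = .data$group, y = .data$score)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.6) +
    labs(title = object$pathway_id, x = NULL, y = "pathway score") +
    theme_minimal()
}

#' Causal-screen overview plot
#'
#' CEV against -log10 permutation p per screened gene; the dashed line marks
#' the significance gate.
#'
#' @param object A `causal_result`.
#' @param alpha Significance gate to mark (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot causal_result
#' @export
autoplot.causal_result <- function(object, alpha = 0.05, ...) {
  ggplot(as_tibble(object), aes(x = .data$cev, y = -log10(.data$p_value))) +
    geom_point() +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed", colour = "grey40") +
    labs(x = "causal estimate value (CEV)", y = "-log10 permutation p") +
    theme_minimal()
}
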