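#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a dispersion model
#'
#' @param x A `dispersion_model` from [estimate_dispersion()].
#' @param ... Unused.
#' @return Tibble `gene_id`, `raw`, `shrunken`.
#' @export
tidy.dispersion_model <- function(x, ...) x$dispersions

#' One-row summary of a dispersion model
#'
#' @param x A `dispersion_model`.
#' @param ... Unused.
#' @return Tibble with `n_genes`, `common`, `delta`, `median_raw`,
#'   `median_shrunken`.
#' @export
glance.dispersion_model <- function(x, ...) {
  tibble(n_genes = nrow(x$dispersions), common = x$common, delta = x$delta,
         median_raw = median(x$dispersions$raw),
         median_shrunken = median(x$dispersions$shrunken))
}

#' One-row summary of a differential-expression table
#'
#' @param x A `de_result` from [nb_test()].
#' @param ... Unused.
#' @return Tibble with tested/untestable counts and significant up/down
#'   counts at the call thresholds.
#' @export
glance.de_result <- function(x, ...) {
  tibble(n_genes = nrow(x), n_untestable = sum(x$untestable),
         n_significant = sum(x$significant),
         n_up = sum(x$significant & x$log2_fc > 0),
         n_down = sum(x$significant & x$log2_fc < 0),
         contrast = x$contrast[1])
}

#' Tidy a gene network into a node table
#'
#' @param x A `gene_network`.
#' @param ... Unused.
#' @return The node tibble joined with centrality metrics.
#' @export
tidy.gene_network <- function(x, ...) {
  left_join(x$nodes, compute_metrics(x), by = c("gene_id", "biotype"))
}

#' Volcano plot of a differential-expression table
#'
#' @param object A `de_result` from [nb_test()].
#' @param ... Unused.
#' @return A ggplot object: log2 fold-change against -log10 FDR, calls
#'   highlighted.
#' @export
autoplot.de_result <- function(object, ...) {
  df <- as_tibble(object) |> filter(!.data$untestable)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log2_fc, y = -log10(pmax(.data$fdr, 1e-300)),
    colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold-change", y = "-log10 FDR",
                  colour = "called") +
    ggplot2::theme_minimal()
}

#' Heatmap of binned zonation profiles
#'
#' @param profiles Matrix from [zone_profile_matrix()].
#' @param ... Unused.
#' @return A ggplot tile plot, genes ordered by profile argmax.
#' @export
plot_zone_profiles <- function(profiles, ...) {
  ord <- order(apply(profiles, 1, which.max))
  df <- as_tibble(profiles[ord, , drop = FALSE], rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "bin", values_to = "z") |>
    mutate(bin = as.integer(sub("bin", "", .data$bin)),
           gene_id = factor(.data$gene_id, levels = rownames(profiles)[ord]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$gene_id,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = "lobule position bin (periportal -> pericentral)",
                  y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Paired bar chart of relative pathway information flow
#'
#' @param comparison Output of [compare_conditions()].
#' @param ... Unused.
#' @return A ggplot bar chart of relative flows per pathway and condition.
#' @export
plot_information_flow <- function(comparison, ...) {
  df <- comparison |>
    select("pathway", "relative_flow_a", "relative_flow_b") |>
    tidyr::pivot_longer(-"pathway", names_to = "condition",
                        values_to = "relative_flow") |>
    mutate(condition = ifelse(.data$condition == "relative_flow_a",
                              attr(comparison, "condition_a") %||% "A",
                              attr(comparison, "condition_b") %||% "B"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$relative_flow,
                                   y = .data$pathway,
                                   fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "relative information flow", y = NULL) +
    ggplot2::theme_minimal()
}
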