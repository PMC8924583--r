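# ggplot2 displays for the main result types

#' Manhattan plot of a genome scan
#'
#' @param object A `cherry_scan` tibble from [blink_scan()].
#' @param map Marker map supplying linkage group and cM position.
#' @param ... Unused.
#' @return A ggplot object: -log10 p by cumulative genetic position, one
#'   panel colour per linkage group, cofactor SNPs highlighted, with the
#'   Bonferroni line.
#' @export
autoplot.cherry_scan <- function(object, map, ...) {
  thr <- attr(object, "bonferroni_threshold")
  d <- inner_join(as_tibble(object), map, by = "snp_id") |>
    arrange(.data$linkage_group, .data$genetic_pos)
  offsets <- d |>
    group_by(.data$linkage_group) |>
    summarise(len = max(.data$genetic_pos), .groups = "drop") |>
    mutate(offset = cumsum(dplyr::lag(.data$len + 10, default = 0)))
  d <- left_join(d, offsets, by = "linkage_group") |>
    mutate(x = .data$genetic_pos + .data$offset)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$minus_log10_p,
                                  colour = factor(.data$linkage_group %% 2))) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_point(data = filter(d, .data$cofactor), colour = "red", size = 1.6) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed",
                        colour = "darkgreen") +
    ggplot2::scale_colour_manual(values = c("grey35", "steelblue")) +
    ggplot2::labs(x = "genetic position (cM, linkage groups concatenated)",
                  y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' Haplotype effect plot
#'
#' Bar chart of haplotype effects (carrier mean minus population mean) with
#' functional classes mapped to fill.
#'
#' @param effects Tibble from [estimate_effects()], optionally joined with
#'   the `class` column of [assign_functional_classes()].
#' @param trait_label Axis label (e.g. `"firmness (g/mm)"`).
#' @return A ggplot object.
#' @export
plot_haplotype_effects <- function(effects, trait_label = "trait units") {
  if (!"class" %in% names(effects)) effects$class <- "none"
  ggplot2::ggplot(effects,
                  ggplot2::aes(x = stats::reorder(.data$label, -.data$effect),
                               y = .data$effect, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::scale_fill_manual(values = c(high = "#d73027", moderate = "#fee090",
                                          low = "#4575b4", none = "grey70")) +
    ggplot2::labs(x = "SNP haplotype", y = paste0("effect (", trait_label, ")"),
                  fill = "class") +
    ggplot2::theme_minimal()
}

#' @rdname tidy.multiyear_blup
#' @param object A `multiyear_blup` fit (for `autoplot`).
#' @importFrom ggplot2 autoplot
#' @export
autoplot.multiyear_blup <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$deviation)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = paste0("multi-year deviation (", object$trait, ")"),
                  y = "seedlings") +
    ggplot2::theme_minimal()
}
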