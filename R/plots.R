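#' Plot a zone map
#'
#' Raster view of the influence-zone partition with a categorical legend.
#'
#' @param object A zone map from [assign_zones()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zone_map <- function(object, ...) {
  zl <- zone_labels()
  df <- tibble(
    row = rep(seq_len(nrow(object)), times = ncol(object)),
    col = rep(seq_len(ncol(object)), each = nrow(object)),
    zone = factor(names(zl)[match(as.vector(object), zl)], levels = names(zl))
  )
  pal <- c(TUMOR_POS = "#8c510a", TUMOR_NEG = "#01665e", CONTACT_POS = "#d8b365",
           CONTACT_NEG = "#5ab4ac", PERI_POS = "#f6e8c3", PERI_NEG = "#c7eae5",
           OUTSIDE_BAND = "grey90", EXCLUDED = "grey40")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$zone)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "zone",
                  title = sprintf("Influence zones (depth %g um)", attr(object, "depth_um"))) +
    ggplot2::theme_minimal()
}

#' Plot a label mask
#'
#' @param object A [label_mask()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.label_mask <- function(object, ...) {
  tab <- mask_class_table(object)
  roles <- c(tab$role, "EXCLUDED")
  codes <- c(tab$code, excluded_code())
  df <- tibble(
    row = rep(seq_len(nrow(object)), times = ncol(object)),
    col = rep(seq_len(ncol(object)), each = nrow(object)),
    role = factor(roles[match(as.vector(object), codes)], levels = roles)
  )
  pal <- c(STROMA = "grey95", TUMOR_K17POS = "#8c510a", TUMOR_K17NEG = "#01665e",
           CD4 = "#e41a1c", CD8 = "#984ea3", CD16 = "#ffd92f", CD163 = "#4daf4a",
           EXCLUDED = "grey40")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$role)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "class") +
    ggplot2::theme_minimal()
}

#' Ranked ratio bar plot
#'
#' Cases ranked by their K17-negative / K17-positive score ratio for one
#' immune class and compartment, on a log scale — the standard presentation
#' of cohort-wide zone-score asymmetry. Undefined ratios are dropped.
#'
#' @param ratios Tibble from [normalized_ratios()].
#' @param class Immune class to show.
#' @param compartment `"peri"` or `"intra"`.
#' @return A ggplot object.
#' @export
plot_ratio_ranks <- function(ratios, class = "CD8", compartment = "peri") {
  df <- ratios %>%
    filter(.data$class == !!class, .data$compartment == !!compartment,
           .data$status == "valid", .data$ratio > 0) %>%
    arrange(.data$ratio) %>%
    mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$ratio)) +
    ggplot2::geom_col(fill = "#984ea3") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "case rank",
                  y = "ZS(K17-) / ZS(K17+)",
                  title = sprintf("%s, %stumoral", class,
                                  ifelse(compartment == "peri", "peri", "intra"))) +
    ggplot2::theme_minimal()
}

#' Plot a depth-sweep profile
#'
#' Peritumoral immune density versus band depth, per class and marker side.
#'
#' @param profile Tibble from [depth_sweep()].
#' @return A ggplot object.
#' @export
plot_depth_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$depth_um, y = .data$density_per_mm2,
                               colour = .data$marker)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~class, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c("K17+" = "#8c510a", "K17-" = "#01665e")) +
    ggplot2::labs(x = "band depth (um)", y = "density (cells/mm²)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
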