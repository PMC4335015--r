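class_palette <- c(derived = "grey10", ancestral = "goldenrod2",
                   melanistic = "grey10", non_melanistic = "goldenrod2")

#' Plot a windowed diversity profile
#'
#' Bar chart of per-window nucleotide diversity (as a percentage) per
#' class, with SEM error bars — the standard way to display diversity of
#' derived vs ancestral chromosomes across a capture target.
#'
#' @param object A [diversity_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot diversity_profile
#' @export
autoplot.diversity_profile <- function(object, ...) {
  df <- as_tibble(object)
  df$window <- factor(df$window, levels = unique(df$window))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window, y = .data$pi_percent,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$pi_percent - 100 * .data$sem,
                   ymax = .data$pi_percent + 100 * .data$sem),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::scale_fill_manual(values = class_palette) +
    ggplot2::labs(x = "window", y = "nucleotide diversity (%)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot EHH curves
#'
#' EHH of the derived and ancestral classes against genomic position, with
#' the core variant marked; points are joined linearly (EHH is evaluated
#' at observed sites only).
#'
#' @param object An [ehh_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ehh_curves
#' @export
autoplot.ehh_curves <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            c("ehh_derived", "ehh_ancestral"),
                            names_to = "class", values_to = "ehh",
                            names_prefix = "ehh_")
  core_pos <- df$pos[df$distance_bp == 0][1]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$ehh,
                                   colour = .data$class)) +
    ggplot2::geom_vline(xintercept = core_pos, colour = "red",
                        linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = class_palette) +
    ggplot2::labs(x = "position (bp)", y = "EHH", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a haplotype bifurcation tree
#'
#' Branches fan out from the core variant; line thickness is proportional
#' to the number of chromosomes sharing the extended haplotype.
#'
#' @param object A [bifurcation_tree()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bifurcation_tree
#' @export
autoplot.bifurcation_tree <- function(object, ...) {
  tree <- as_tibble(object)
  sign <- if (attr(object, "direction") == "upstream") -1 else 1
  # leaf y-positions spread evenly, internal nodes at the mean of children
  y <- setNames(rep(NA_real_, nrow(tree)), tree$node_id)
  depths <- sort(unique(tree$depth), decreasing = TRUE)
  leaves <- tree$node_id[!tree$node_id %in% tree$parent_id]
  y[as.character(leaves)] <- seq_along(leaves)
  for (d in depths) {
    for (id in tree$node_id[tree$depth == d]) {
      kids <- tree$node_id[!is.na(tree$parent_id) & tree$parent_id == id]
      if (length(kids) > 0) {
        y[as.character(id)] <- mean(y[as.character(kids)])
      }
    }
  }
  tree$y <- y[as.character(tree$node_id)]
  tree$x <- sign * tree$depth
  seg <- dplyr::inner_join(
    tree, tree[, c("node_id", "x", "y")],
    by = c(parent_id = "node_id"), suffix = c("", "_parent"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x_parent, y = .data$y_parent,
                   xend = .data$x, yend = .data$y,
                   linewidth = .data$count)) +
    ggplot2::scale_linewidth(range = c(0.3, 3)) +
    ggplot2::labs(x = sprintf("sites %s of core", attr(object, "direction")),
                  y = NULL,
                  title = sprintf("%s class (n = %d)",
                                  attr(object, "allele_class"),
                                  attr(object, "class_size"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   legend.position = "none")
}
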