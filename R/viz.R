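#' Kernel PCA sample plot
#'
#' Scatter of the training samples on two kernel principal components, with
#' the explained-variance fraction of each axis in its label and optional
#' group coloring.
#'
#' @param model a fitted [kpca_fit()] model.
#' @param components length-2 integer vector of component indices (both
#'   `<= q`).
#' @param labels optional vector of group labels (length `n`).
#' @return A ggplot object.
#' @export
sample_plot <- function(model, components = c(1, 2), labels = NULL) {
  components <- check_components(model, components)
  ev <- explained_variance(model)
  df <- data.frame(x = model$scores[, components[1]],
                   y = model$scores[, components[2]])
  p <- if (is.null(labels)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_point()
  } else {
    df$group <- factor(labels)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$group)) +
      ggplot2::geom_point()
  }
  p + ggplot2::labs(
        x = sprintf("KPC%d (%.1f%%)", components[1], 100 * ev[components[1]]),
        y = sprintf("KPC%d (%.1f%%)", components[2], 100 * ev[components[2]])) +
    ggplot2::theme_minimal()
}

check_components <- function(model, components) {
  components <- as.integer(components)
  if (length(components) != 2L || any(components < 1L) ||
      any(components > model$q))
    stop(sprintf("'components' must be two indices in 1..%d", model$q),
         call. = FALSE)
  components
}

#' Arrow-field display of one feature on the kernel PCA plot
#'
#' Overlays, at every sample point, an arrow in the direction of steepest
#' growth of the chosen feature: the rows of the projected gradient field
#' restricted to the two displayed components. Arrows show where in the
#' embedding the feature increases; parallel arrows of equal length indicate a
#' (locally) linear effect, converging/diverging arrows a nonlinear one.
#' Zero-direction rows (e.g. a constant feature) are not drawn.
#'
#' @inheritParams sample_plot
#' @param feature feature name or index.
#' @param arrow_scale multiplier applied to the direction vectors; the default
#'   `NULL` normalizes the longest arrow to 10\% of the larger axis range.
#' @param subsample optionally draw arrows at only this many (evenly spaced,
#'   by sample order) anchor points.
#' @return A ggplot object; the unscaled direction matrix is attached as
#'   attribute `"field"`.
#' @export
variable_arrow_field <- function(model, feature, components = c(1, 2),
                                 arrow_scale = NULL, labels = NULL,
                                 subsample = NULL) {
  components <- check_components(model, components)
  field <- gradient_projection(model, feature)
  dirs <- field$W[, components, drop = FALSE]
  anchors <- model$scores[, components, drop = FALSE]
  if (is.null(arrow_scale)) {
    longest <- max(sqrt(rowSums(dirs^2)))
    span <- max(apply(anchors, 2, function(v) diff(range(v))))
    arrow_scale <- if (longest > 0) 0.1 * span / longest else 1
  }
  df <- data.frame(x = anchors[, 1], y = anchors[, 2],
                   dx = dirs[, 1] * arrow_scale, dy = dirs[, 2] * arrow_scale)
  if (!is.null(subsample) && subsample < nrow(df)) {
    keep <- unique(round(seq(1, nrow(df), length.out = subsample)))
    df <- df[keep, , drop = FALSE]
  }
  df <- df[df$dx != 0 | df$dy != 0, , drop = FALSE]
  p <- sample_plot(model, components, labels)
  if (nrow(df) > 0) {
    p <- p + ggplot2::geom_segment(
      data = df,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x + .data$dx, yend = .data$y + .data$dy),
      arrow = grid::arrow(length = grid::unit(0.12, "cm")),
      colour = "grey30", inherit.aes = FALSE)
  }
  p <- p + ggplot2::ggtitle(field$feature)
  attr(p, "field") <- field$W[, components, drop = FALSE]
  p
}

#' Score-distribution plot of a feature ranking
#'
#' Importance scores against rank (descending), with the extremes annotated;
#' a long flat tail indicates many uninformative features.
#'
#' @param ranking a `feature_ranking`.
#' @return A ggplot object.
#' @export
score_distribution_plot <- function(ranking) {
  if (!inherits(ranking, "feature_ranking") || nrow(ranking) == 0)
    stop("'ranking' must be a nonempty feature_ranking", call. = FALSE)
  df <- data.frame(rank = ranking$rank, score = ranking$score)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::annotate("text", x = c(1, nrow(df)), y = range(df$score)[c(2, 1)],
                      label = sprintf("%.3g", c(max(df$score), min(df$score))),
                      hjust = c(0, 1), vjust = c(0, 1), size = 3) +
    ggplot2::labs(x = "rank", y = "score") +
    ggplot2::theme_minimal()
}

#' Save a figure to disk
#'
#' Thin wrapper over [ggplot2::ggsave()]; the device is chosen from the file
#' extension (pdf, png, or svg where the cairo device is available).
#'
#' @param plot a ggplot object.
#' @param path output path ending in `.pdf`, `.png` or `.svg`.
#' @param width,height size in inches.
#' @export
save_figure <- function(plot, path, width = 6, height = 5) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("pdf", "png", "svg"))
    stop("unsupported figure format: ", ext, call. = FALSE)
  if (ext == "svg" && !isTRUE(capabilities("cairo")))
    stop("svg output requires cairo support; use pdf or png", call. = FALSE)
  suppressMessages(ggplot2::ggsave(path, plot, width = width, height = height))
  invisible(path)
}
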