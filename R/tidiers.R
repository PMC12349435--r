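# broom-style tidiers and ggplot2 displays.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a prompt set
#'
#' One row per prompt point, with the per-tree axis metadata joined in.
#'
#' @param x a `prompt_set`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy prompt_set
#' @export
tidy.prompt_set <- function(x, ...) {
  pts <- as_tibble(unclass(x)[c("tree", "point", "x", "y")])
  meta <- attr(x, "meta")
  if (!is.null(meta) && nrow(meta)) dplyr::left_join(pts, meta, by = "tree")
  else pts
}

#' @rdname tidy.prompt_set
#' @method glance prompt_set
#' @export
glance.prompt_set <- function(x, ...) {
  meta <- attr(x, "meta")
  tibble(n_trees = if (is.null(meta)) length(unique(x$tree)) else nrow(meta),
         n_points = nrow(x),
         n_summit_failures = if (is.null(meta) || !nrow(meta)) 0L
                             else sum(!meta$summit_ok))
}

#' Tidy an evaluation report
#'
#' `tidy()` returns the per-tree table; `glance()` the one-row dataset
#' summary.
#'
#' @param x an `eval_report`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$per_tree

#' @rdname tidy.eval_report
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) x$summary

#' Plot a prompt set
#'
#' The five diamond points per tree, optionally over the image.
#'
#' @param object a `prompt_set`.
#' @param image optional H x W x 3 array drawn behind the points.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot prompt_set
#' @export
autoplot.prompt_set <- function(object, image = NULL, ...) {
  d <- as_tibble(unclass(object)[c("tree", "point", "x", "y")])
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(image)) {
    h <- dim(image)[1]; w <- dim(image)[2]
    p <- p + ggplot2::annotation_raster(grDevices::as.raster(image),
                                        xmin = -0.5, xmax = w - 0.5,
                                        ymin = -(h - 0.5), ymax = 0.5) +
      ggplot2::coord_fixed(xlim = c(-0.5, w - 0.5), ylim = c(h - 0.5, -0.5))
  }
  p + ggplot2::geom_path(ggplot2::aes(group = .data$tree),
                         data = d[d$point %in% c("B", "C", "T"), ],
                         linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$tree),
                                     shape = .data$point), size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "tree",
                  shape = "point") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' Per-image mean Dice against signed mean error; a quick view of where
#' the pipeline over- or under-segments.
#'
#' @param object an `eval_report`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$per_image,
                  ggplot2::aes(x = .data$me, y = .data$mean_dice)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "mean error (signed, + = over-segmentation)",
                  y = "per-image mean Dice") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
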