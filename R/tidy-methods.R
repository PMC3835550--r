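#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a count result into its detection table
#'
#' @param x A `count_result`.
#' @param ... Unused.
#' @return Tibble with one row per counted cell: `id`, centroid `row` and
#'   `col` (1-based pixels), `size` in pixels.
#' @exportS3Method generics::tidy
tidy.count_result <- function(x, ...) {
  x$positions
}

#' One-row summary of a count result
#'
#' @param x A `count_result`.
#' @param ... Unused.
#' @return One-row tibble: `count`, `n_components`, `n_discarded`,
#'   `mode`, `threshold`, and the calibration parameters `m`, `c`, `f`.
#' @exportS3Method generics::glance
glance.count_result <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    count = x$count,
    n_components = x$n_components,
    n_discarded = x$n_components - x$count,
    mode = x$mode %||% NA_character_,
    threshold = x$threshold %||% NA_real_,
    m = if (is.null(p)) NA_integer_ else p$m,
    c = if (is.null(p)) NA_real_ else p$c,
    f = x$f
  )
}

# long-format tibble for raster plotting
image_to_df <- function(img) {
  tibble::tibble(
    row = rep(seq_len(nrow(img)), times = ncol(img)),
    col = rep(seq_len(ncol(img)), each = nrow(img)),
    intensity = as.vector(img)
  )
}

#' Plot a grayscale image
#'
#' @param img Numeric matrix in \eqn{[0, 1]}.
#' @param title Optional plot title.
#' @return A ggplot; row 1 is drawn at the top, as images are viewed.
#' @export
plot_gray_image <- function(img, title = NULL) {
  validate_gray_image(img)
  ggplot2::ggplot(image_to_df(img),
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = "column", y = "row",
                  fill = "intensity") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_gray_image Image with counted centroids overlaid in
#'   red (a plotted analogue of [save_overlay()]).
#' @param object A `count_result` from [run_pipeline()].
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.count_result <- function(object, ...) {
  if (is.null(object$image))
    stop("this count_result carries no source image to plot")
  plot_gray_image(object$image,
                  title = paste0("counted cells: ", object$count,
                                 " (mode ", object$mode %||% "?", ")")) +
    ggplot2::geom_point(
      data = object$positions,
      ggplot2::aes(x = .data$col, y = .data$row),
      inherit.aes = FALSE, colour = "red", size = 1.2, shape = 3
    )
}

#' @describeIn plot_gray_image Phantom with ground-truth spot centers
#'   circled.
#' @exportS3Method ggplot2::autoplot
autoplot.phantom <- function(object, ...) {
  plot_gray_image(object$image,
                  title = paste0("phantom (", nrow(object$truth),
                                 " true spots, seed ",
                                 object$spec$seed, ")")) +
    ggplot2::geom_point(
      data = object$truth,
      ggplot2::aes(x = .data$center_col, y = .data$center_row),
      inherit.aes = FALSE, colour = "#00c000", size = 2, shape = 1
    )
}
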