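#' Square median filter with mirror padding
#'
#' Filters an image with an \eqn{m \times m} median window. The image is
#' padded by edge-inclusive mirror reflection, so the output has the same
#' size as the input. For even `m` the window spans offsets
#' \eqn{[-m/2, m/2 - 1]} in each axis relative to the output pixel, and the
#' median of the (even) number of window values is the mean of the two
#' middle order statistics.
#'
#' @param img Numeric matrix in \eqn{[0, 1]}.
#' @param m Integer window side length in pixels, \eqn{m \ge 1}.
#' @return Numeric matrix, same size as `img`.
#' @export
#' @examples
#' median_filter(matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3), m = 3)
median_filter <- function(img, m) {
  validate_gray_image(img)
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 1L) stop("m must be an integer >= 1")
  if (m > 2L * nrow(img) || m > 2L * ncol(img))
    stop("window size m = ", m, " exceeds twice the image extent (",
         nrow(img), "x", ncol(img), "); mirror padding is undefined")
  out <- median_filter_cpp(img, m)
  dimnames(out) <- dimnames(img)
  out
}

#' Background homogenization by median subtraction
#'
#' Step 1 of the counting pipeline. Subtracts the median-filtered image
#' \eqn{\tilde I} from the original \eqn{I^{(0)}}, removing background
#' brightness fluctuations slower than the window scale, and maps the
#' difference \eqn{d = I^{(0)} - \tilde I \in [-1, 1]} back to \eqn{[0, 1]}
#' by the fixed affine map \eqn{(d + 1)/2}. The result \eqn{I^{(1)}} has a
#' neutral background near 0.5 with dark (labeled) structures below 0.5.
#'
#' The affine map is data-independent on purpose: a per-image min-max
#' stretch would silently rescale the meaning of the TV regularization
#' weight and the threshold multiplier across a batch.
#'
#' @inheritParams median_filter
#' @return Numeric matrix in \eqn{[0, 1]}, the denoising input
#'   \eqn{I^{(1)}}.
#' @export
#' @examples
#' subtract_background(matrix(0.3, 4, 4), m = 2)  # constant -> all 0.5
subtract_background <- function(img, m) {
  d <- img - median_filter(img, m)
  (d + 1) / 2
}
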