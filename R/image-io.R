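#' Read a grayscale micrograph and normalize it to [0, 1]
#'
#' Reads a single-channel TIFF or PNG raster and rescales the raw integer
#' sample values to intensities on \eqn{[0, 1]} by dividing by
#' \eqn{2^{b} - 1}, where \eqn{b} is the sample bit depth. Micrographs from
#' scientific cameras are frequently 10- or 12-bit data stored in 16-bit
#' containers; passing `bit_depth` overrides the container's declared depth
#' so that full scale means full scale of the sensor, keeping the threshold
#' and regularization parameters comparable across sources.
#'
#' @param path Path to a single-channel TIFF or PNG file.
#' @param bit_depth Optional integer, one of 8, 10, 12, 16: the true sample
#'   depth. When `NULL`, the container's declared depth is used; if the
#'   container does not declare one, the smallest of {8, 10, 12, 16} whose
#'   full scale covers the observed maximum is used (and noted in a message).
#' @param as_gray If `TRUE`, a multi-channel image is converted to luminance
#'   (mean of channels); otherwise multi-channel input is an error.
#'
#' @return A numeric matrix of intensities in \eqn{[0, 1]} (rows = image
#'   rows), with attribute `bit_depth` recording the depth used.
#' @export
#' @examples
#' f <- tempfile(fileext = ".png")
#' save_gray_image(matrix(runif(12), 3, 4), f)
#' img <- load_gray_image(f)
#' range(img)
load_gray_image <- function(path, bit_depth = NULL, as_gray = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.null(bit_depth)) {
    bit_depth <- as.integer(bit_depth)
    if (!bit_depth %in% c(8L, 10L, 12L, 16L))
      stop("bit_depth must be one of 8, 10, 12, 16")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    container_depth <- attr(raw, "bits.per.sample")
  } else if (ext == "png") {
    dat <- png::readPNG(path, info = TRUE)
    info <- attr(dat, "info")
    container_depth <- if (!is.null(info)) info$bit.depth else NULL
    raw <- round(dat * (2^container_depth - 1))
  } else {
    stop("unsupported image format: '", ext, "' (use TIFF or PNG)")
  }
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] == 1L) {
      raw <- raw[, , 1L]
    } else if (as_gray) {
      raw <- apply(raw, c(1L, 2L), mean)
    } else {
      stop("multi-channel image (", dim(raw)[3],
           " channels); pass as_gray = TRUE to convert to luminance")
    }
  }
  raw <- unclass(as.matrix(raw))
  obs_max <- max(raw)
  depth <- bit_depth
  if (is.null(depth)) {
    if (!is.null(container_depth) && length(container_depth) == 1L &&
        is.finite(container_depth)) {
      depth <- as.integer(container_depth)
    } else {
      candidates <- c(8L, 10L, 12L, 16L)
      depth <- candidates[which(2^candidates - 1 >= obs_max)[1]]
      if (is.na(depth))
        stop("observed maximum ", obs_max, " exceeds 16-bit full scale")
      message("no declared sample depth; assuming ", depth,
              "-bit from observed maximum ", obs_max)
    }
  }
  full <- 2^depth - 1
  if (obs_max > full)
    stop("observed maximum ", obs_max, " exceeds declared ", depth,
         "-bit full scale (", full, ")")
  out <- raw / full
  attr(out, "bit_depth") <- depth
  out
}

#' Write a [0, 1] intensity matrix as an 8- or 16-bit grayscale image
#'
#' @param img Numeric matrix with values in \eqn{[0, 1]}.
#' @param path Output path; format follows the extension (.png, .tif/.tiff).
#' @param bit_depth 8 or 16: container sample depth.
#' @return Invisibly, `path`.
#' @export
save_gray_image <- function(img, path, bit_depth = 8) {
  validate_gray_image(img)
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16 for output")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bit_depth != 8)
      stop("PNG output is written 8-bit; use TIFF for 16-bit")
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = bit_depth)
  } else {
    stop("unsupported output format: '", ext, "'")
  }
  invisible(path)
}

#' Write a red-overlay image of the counted components
#'
#' Replicates the grayscale image over three channels and paints every pixel
#' of a counted (surviving) component pure red, mirroring the tool's visual
#' report of counted features.
#'
#' @param img Numeric matrix in \eqn{[0, 1]}, the image to annotate.
#' @param result A `count_result` from [run_pipeline()] or [count_cells()]
#'   whose label grid matches `img` in size.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
save_overlay <- function(img, result, path) {
  validate_gray_image(img)
  stopifnot(inherits(result, "count_result"))
  lab <- result$label_grid
  if (!all(dim(lab) == dim(img)))
    stop("label grid (", paste(dim(lab), collapse = "x"),
         ") does not match image (", paste(dim(img), collapse = "x"), ")")
  counted <- matrix(lab %in% result$kept_ids, nrow(lab), ncol(lab))
  rgb <- array(img, dim = c(dim(img), 3L))
  rgb[, , 1][counted] <- 1
  rgb[, , 2][counted] <- 0
  rgb[, , 3][counted] <- 0
  png::writePNG(rgb, path)
  invisible(path)
}

#' @keywords internal
validate_gray_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(arg, " must be a numeric matrix")
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop(arg, " must have at least one row and one column")
  if (anyNA(img) || any(!is.finite(img)))
    stop(arg, " contains non-finite values")
  if (min(img) < 0 || max(img) > 1)
    stop(arg, " has values outside [0, 1] (range ",
         signif(min(img), 4), "..", signif(max(img), 4), ")")
  invisible(img)
}
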