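#' Specification of a synthetic retinal-mosaic phantom
#'
#' Describes a ground-truthed phantom micrograph: dark, soft-edged disk
#' "somata" scattered with a minimum separation on a bright field, with
#' optional smooth background blotches (low-pass-filtered noise emulating
#' uneven staining/illumination), per-pixel sensor noise, sub-threshold
#' debris specks, and one dark curvilinear vessel band. Defaults encode
#' the reference study conditions used throughout the package's
#' validation: a 512 x 512 field with 100 spots of radius 4 px and
#' contrast 0.4 on a 0.75 background with blotch amplitude 0.15
#' (correlation length 60 px) and pixel noise sd 0.02.
#'
#' @param height,width Image size in pixels.
#' @param n_spots Number of cells to place.
#' @param spot_radius_range Length-2 numeric, min/max spot radius in px
#'   (radii drawn uniformly; equal values give a fixed radius).
#' @param spot_contrast Depth of a spot below the local background, in
#'   intensity units on (0, 1].
#' @param min_separation Minimum pairwise center distance in px.
#' @param background_level Flat field intensity in (0, 1).
#' @param blotch_amplitude Standard deviation of the smooth background
#'   fluctuation field (0 disables).
#' @param blotch_scale Correlation length of the blotches in px (Gaussian
#'   smoothing sigma).
#' @param pixel_noise_sd Standard deviation of i.i.d. per-pixel noise.
#' @param n_debris Number of small dark specks (area below the default
#'   minimum feature size) to scatter.
#' @param vessel If `TRUE`, draw one dark curvilinear band across the
#'   image.
#' @param seed Integer RNG seed; identical specs generate identical
#'   phantoms.
#' @return A `phantom_spec` list.
#' @export
#' @examples
#' phantom_spec(n_spots = 20, seed = 7)
phantom_spec <- function(height = 512, width = 512, n_spots = 100,
                         spot_radius_range = c(4, 4), spot_contrast = 0.4,
                         min_separation = 16, background_level = 0.75,
                         blotch_amplitude = 0.15, blotch_scale = 60,
                         pixel_noise_sd = 0.02, n_debris = 0,
                         vessel = FALSE, seed = 1) {
  spec <- structure(
    list(height = as.integer(height), width = as.integer(width),
         n_spots = as.integer(n_spots),
         spot_radius_range = as.numeric(spot_radius_range),
         spot_contrast = as.numeric(spot_contrast),
         min_separation = as.numeric(min_separation),
         background_level = as.numeric(background_level),
         blotch_amplitude = as.numeric(blotch_amplitude),
         blotch_scale = as.numeric(blotch_scale),
         pixel_noise_sd = as.numeric(pixel_noise_sd),
         n_debris = as.integer(n_debris),
         vessel = isTRUE(vessel),
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
  stopifnot(spec$height >= 8L, spec$width >= 8L, spec$n_spots >= 0L,
            length(spec$spot_radius_range) == 2L,
            all(spec$spot_radius_range > 0),
            diff(spec$spot_radius_range) >= 0,
            spec$spot_contrast > 0, spec$spot_contrast <= 1,
            spec$min_separation >= 0,
            spec$background_level > 0, spec$background_level < 1,
            spec$blotch_amplitude >= 0, spec$blotch_scale > 0,
            spec$pixel_noise_sd >= 0, spec$n_debris >= 0L)
  spec
}

# Gaussian low-pass of a matrix by periodic FFT convolution.
gaussian_lowpass <- function(z, sigma) {
  n <- nrow(z); r <- ncol(z)
  kr <- stats::dnorm(pmin(0:(n - 1), n - (0:(n - 1))), sd = sigma)
  kc <- stats::dnorm(pmin(0:(r - 1), r - (0:(r - 1))), sd = sigma)
  k <- outer(kr, kc)
  k <- k / sum(k)
  Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (n * r)
}

# Subtract a soft-edged disk (1-px linear edge ramp) of the given depth.
stamp_disk <- function(img, row, col, radius, depth) {
  n <- nrow(img); r <- ncol(img)
  i0 <- max(1L, floor(row - radius - 1)); i1 <- min(n, ceiling(row + radius + 1))
  j0 <- max(1L, floor(col - radius - 1)); j1 <- min(r, ceiling(col + radius + 1))
  ii <- i0:i1; jj <- j0:j1
  d <- sqrt(outer((ii - row)^2, (jj - col)^2, "+"))
  fac <- pmin(1, pmax(0, radius + 0.5 - d))
  img[ii, jj] <- img[ii, jj] - depth * fac
  img
}

#' Generate a ground-truthed phantom micrograph
#'
#' Builds the image described by a [phantom_spec()]: flat background, plus
#' the smoothed-noise blotch field, minus soft-edged dark disks at
#' rejection-sampled centers (pairwise separation at least
#' `min_separation`), minus optional vessel band and debris specks, plus
#' per-pixel Gaussian noise; finally clipped to \eqn{[0, 1]} (the number
#' of clipped pixels is recorded). The same spec (including seed) always
#' produces the identical image.
#'
#' @param spec A [phantom_spec()].
#' @param max_attempts_per_spot Rejection-sampling budget; placement
#'   failing within `n_spots * max_attempts_per_spot` draws is an error.
#' @return List of class `phantom` with `image` (numeric matrix in
#'   \eqn{[0, 1]}), `truth` (tibble: spot, center_row, center_col, radius;
#'   1-based pixel coordinates), `n_clipped`, and the `spec`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(height = 96, width = 96,
#'   n_spots = 4, seed = 3))
#' nrow(ph$truth)
generate_phantom <- function(spec, max_attempts_per_spot = 1000) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    img <- matrix(spec$background_level, h, w)
    if (spec$blotch_amplitude > 0) {
      fld <- gaussian_lowpass(matrix(stats::rnorm(h * w), h, w),
                              spec$blotch_scale)
      fld <- fld - mean(fld)   # zero-mean fluctuation about the background
      img <- img + fld / stats::sd(fld) * spec$blotch_amplitude
    }
    # spot placement: uniform rejection sampling with a margin so disks
    # stay inside the frame
    rmax <- spec$spot_radius_range[2]
    margin <- rmax + 2
    if (h - 2 * margin < 1 || w - 2 * margin < 1)
      stop("image too small for the requested spot radius")
    centers <- matrix(numeric(0), 0, 2)
    attempts <- 0L
    budget <- spec$n_spots * max_attempts_per_spot
    while (nrow(centers) < spec$n_spots) {
      if (attempts >= budget)
        stop("could not place ", spec$n_spots, " spots with min_separation ",
             spec$min_separation, " within ", budget, " attempts")
      attempts <- attempts + 1L
      cand <- c(stats::runif(1, margin, h - margin),
                stats::runif(1, margin, w - margin))
      if (nrow(centers) == 0 ||
          min(sqrt((centers[, 1] - cand[1])^2 +
                   (centers[, 2] - cand[2])^2)) >= spec$min_separation)
        centers <- rbind(centers, cand)
    }
    radii <- stats::runif(spec$n_spots, spec$spot_radius_range[1],
                          spec$spot_radius_range[2])
    for (s in seq_len(spec$n_spots))
      img <- stamp_disk(img, centers[s, 1], centers[s, 2], radii[s],
                        spec$spot_contrast)
    if (spec$vessel) {
      # one dark sinuous band crossing the full width
      base_row <- stats::runif(1, 0.25 * h, 0.75 * h)
      amp <- stats::runif(1, 0.05 * h, 0.15 * h)
      per <- stats::runif(1, 0.5 * w, 1.5 * w)
      phase <- stats::runif(1, 0, 2 * pi)
      for (t in seq(1, w, by = 1)) {
        rr <- base_row + amp * sin(2 * pi * t / per + phase)
        img <- stamp_disk(img, rr, t, 2.5, 0.6 * spec$spot_contrast)
      }
    }
    if (spec$n_debris > 0) {
      for (s in seq_len(spec$n_debris)) {
        img <- stamp_disk(img,
                          stats::runif(1, 2, h - 2),
                          stats::runif(1, 2, w - 2),
                          stats::runif(1, 0.5, 0.9),
                          spec$spot_contrast)
      }
    }
    if (spec$pixel_noise_sd > 0)
      img <- img + matrix(stats::rnorm(h * w, 0, spec$pixel_noise_sd), h, w)
    n_clipped <- sum(img < 0 | img > 1)
    img[img < 0] <- 0
    img[img > 1] <- 1
    structure(
      list(image = img,
           truth = tibble::tibble(spot = seq_len(spec$n_spots),
                                  center_row = centers[, 1],
                                  center_col = centers[, 2],
                                  radius = radii),
           n_clipped = n_clipped,
           spec = spec),
      class = "phantom"
    )
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom>", nrow(x$image), "x", ncol(x$image), "px,",
      nrow(x$truth), "spots, seed", x$spec$seed,
      if (x$n_clipped > 0) paste0("(", x$n_clipped, " px clipped)") else "",
      "\n")
  invisible(x)
}

#' Score detections against phantom ground truth
#'
#' Greedy one-to-one matching of detected centroids to true spot centers:
#' all detection-truth pairs are sorted by distance and accepted in order
#' while both members are unmatched and the distance is at most
#' `match_radius`. Reported metrics mirror the standard counting
#' validation: the correctly-recognized fraction of true cells (recall),
#' the fraction of detections not matching any true cell (artifacts), and
#' the relative count error against the manual count.
#'
#' @param result A `count_result` (or a tibble/data.frame of detected
#'   positions with columns `row` and `col`).
#' @param truth Phantom truth tibble with `center_row`, `center_col` (as
#'   produced by [generate_phantom()]).
#' @param match_radius Maximum center distance in px for a detection to
#'   claim a true cell; defaults to the mean true spot radius.
#' @param manual_count Reference count for the relative error; defaults
#'   to the number of true spots.
#' @return One-row tibble of class `detection_metrics`: `n_true`,
#'   `n_detected`, `n_matched`, `recall_percent`, `artifact_percent`,
#'   `relative_error` (percent).
#' @export
evaluate_detection <- function(result, truth,
                               match_radius = NULL, manual_count = NULL) {
  det <- if (inherits(result, "count_result")) result$positions else result
  stopifnot(is.data.frame(det), all(c("row", "col") %in% names(det)),
            is.data.frame(truth),
            all(c("center_row", "center_col") %in% names(truth)))
  if (is.null(match_radius)) {
    if (!"radius" %in% names(truth) || nrow(truth) == 0)
      stop("match_radius must be given when truth has no radii")
    match_radius <- mean(truth$radius)
  }
  stopifnot(match_radius > 0)
  n_true <- nrow(truth); n_det <- nrow(det)
  if (n_true == 0 && n_det > 0)
    stop("empty truth with non-empty detections: recall undefined")
  manual_count <- manual_count %||% n_true
  n_matched <- 0L
  if (n_true > 0 && n_det > 0) {
    dmat <- sqrt(outer(det$row, truth$center_row, "-")^2 +
                 outer(det$col, truth$center_col, "-")^2)
    ord <- order(dmat)
    ok <- ord[dmat[ord] <= match_radius]
    used_det <- logical(n_det); used_true <- logical(n_true)
    for (idx in ok) {
      i <- ((idx - 1L) %% n_det) + 1L
      j <- ((idx - 1L) %/% n_det) + 1L
      if (!used_det[i] && !used_true[j]) {
        used_det[i] <- TRUE; used_true[j] <- TRUE
        n_matched <- n_matched + 1L
      }
    }
  }
  out <- tibble::tibble(
    n_true = n_true,
    n_detected = n_det,
    n_matched = n_matched,
    recall_percent = if (n_true > 0) 100 * n_matched / n_true else NA_real_,
    artifact_percent = if (n_det > 0) 100 * (n_det - n_matched) / n_det
                       else 0,
    relative_error = if (manual_count > 0)
        100 * abs(n_det - manual_count) / manual_count
      else NA_real_
  )
  class(out) <- c("detection_metrics", class(out))
  out
}
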