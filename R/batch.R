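#' Process a list of images with one parameter set
#'
#' The batch workflow: calibrate `m`, `c`, `f` on one representative
#' image, then run the whole file list unattended with identical
#' parameters. Per-file failures (unreadable files, decode errors) are
#' recorded in the report and do not abort the remaining files.
#'
#' @param file_list Character vector of image paths (TIFF/PNG), processed
#'   in order.
#' @param params A [pipeline_params()] object.
#' @param bit_depth Optional sample depth forwarded to
#'   [load_gray_image()] for every file.
#' @return A tibble of class `batch_report`, one row per file: `path`,
#'   `count`, `density_per_mm2` (only non-`NA` when `pixel_pitch_um` is
#'   set), `n_rows`, `n_cols`, `error` (NA on success) and a `positions`
#'   list-column of centroid tibbles. The parameter echo and a timestamp
#'   are attached as attributes `params` and `generated_at`.
#' @export
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' ph <- generate_phantom(phantom_spec(height = 128, width = 128,
#'   n_spots = 8, seed = 2))
#' save_gray_image(ph$image, file.path(dir, "a.png"))
#' run_batch(file.path(dir, "a.png"), pipeline_params(n_iter = 20))
run_batch <- function(file_list, params = pipeline_params(),
                      bit_depth = NULL) {
  if (length(file_list) == 0) stop("empty file list")
  params <- validate_pipeline_params(params)
  rows <- purrr::map(file_list, function(path) {
    res <- tryCatch({
      img <- load_gray_image(path, bit_depth = bit_depth)
      r <- run_pipeline(img, params)
      tibble::tibble(
        path = path,
        count = r$count,
        density_per_mm2 = density_per_mm2(r$count, nrow(img), ncol(img),
                                          params$pixel_pitch_um),
        n_rows = nrow(img), n_cols = ncol(img),
        error = NA_character_,
        positions = list(r$positions)
      )
    }, error = function(e) {
      tibble::tibble(path = path, count = NA_integer_,
                     density_per_mm2 = NA_real_,
                     n_rows = NA_integer_, n_cols = NA_integer_,
                     error = conditionMessage(e),
                     positions = list(tibble::tibble()))
    })
    res
  })
  report <- dplyr::bind_rows(rows)
  attr(report, "params") <- params
  attr(report, "generated_at") <- format(Sys.time(), tz = "UTC",
                                         usetz = TRUE)
  class(report) <- c("batch_report", class(report))
  report
}

# Mean density in cells per mm^2: count / (n_rows * n_cols * pitch_mm^2).
density_per_mm2 <- function(count, n_rows, n_cols, pixel_pitch_um) {
  if (is.null(pixel_pitch_um)) return(NA_real_)
  pitch_mm <- pixel_pitch_um / 1000
  count / (n_rows * n_cols * pitch_mm^2)
}

#' Write a batch report to CSV
#'
#' Writes one row per file (path, count, density, size, error) to `path`,
#' preceded by commented header lines echoing the full parameter set, and
#' optionally the per-file detection positions to a companion
#' `*_positions.csv`.
#'
#' @param report A `batch_report` from [run_batch()].
#' @param path Output CSV path.
#' @param positions If `TRUE` (default), also write
#'   `<path>_positions.csv` with columns file, id, row, col, size.
#' @return Invisibly, `path`.
#' @export
write_batch_report <- function(report, path, positions = TRUE) {
  stopifnot(inherits(report, "batch_report"))
  p <- attr(report, "params")
  hdr <- c(
    "# tvcount batch report",
    paste0("# generated_at: ", attr(report, "generated_at")),
    paste0("# params: m=", p$m, " c=", p$c, " f=", p$f,
           " alpha=", p$alpha, " n_iter=", p$n_iter,
           " tau_p=", signif(p$tau_p, 10), " tau_d=", signif(p$tau_d, 10),
           " mode=", p$mode, " connectivity=", p$connectivity,
           " spread=", p$spread,
           " pixel_pitch_um=", p$pixel_pitch_um %||% "NA"),
    "# threshold rule: mean - c * spread of the segmented image"
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  flat <- report[, setdiff(names(report), "positions")]
  utils::write.csv(as.data.frame(flat), con, row.names = FALSE)
  if (positions) {
    pos <- purrr::map2(report$path, report$positions, function(f, tb) {
      if (nrow(tb) == 0) return(NULL)
      tibble::tibble(file = f, tb)
    })
    pos <- dplyr::bind_rows(pos)
    ppath <- sub("(\\.csv)?$", "_positions.csv",
                 path, ignore.case = TRUE)
    utils::write.csv(as.data.frame(pos), ppath, row.names = FALSE)
  }
  invisible(path)
}
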