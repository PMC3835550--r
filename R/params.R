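#' Pipeline parameter set
#'
#' Bundles the tunable parameters of the counting pipeline. Only three of
#' them normally need manual calibration on a sample image: the median
#' window `m`, the contrast multiplier `c`, and the minimum feature size
#' `f`; the remaining settings control the TV solver and are rarely
#' touched.
#'
#' @param m Integer median window side length in pixels (default 30).
#' @param c Contrast multiplier: threshold is mean minus `c` standard
#'   deviations (default 2.5).
#' @param f Integer minimum feature size in pixels (default 5).
#' @param alpha TV regularization weight (default 0.05); larger values
#'   flatten the image more aggressively.
#' @param n_iter Number of primal-dual iterations (default 50).
#' @param tau_p,tau_d Primal/dual step sizes, product at most 0.125; both
#'   default to `sqrt(0.125)`.
#' @param mode `"tv"` (full pipeline), `"direct"` (threshold the raw
#'   image) or `"median_direct"` (median subtraction, no TV).
#' @param connectivity 4 or 8 (default 8).
#' @param spread `"sd"` or `"var"`; see [threshold_mask()].
#' @param pixel_pitch_um Optional micrometres per pixel; when given, batch
#'   reports include cell densities per mm^2.
#' @return A `pipeline_params` list.
#' @export
#' @examples
#' pipeline_params()            # the default calibration
#' pipeline_params(c = 3, f = 40)
pipeline_params <- function(m = 30, c = 2.5, f = 5, alpha = 0.05,
                            n_iter = 50, tau_p = sqrt(0.125),
                            tau_d = sqrt(0.125), mode = "tv",
                            connectivity = 8, spread = "sd",
                            pixel_pitch_um = NULL) {
  p <- structure(
    list(m = as.integer(m), c = as.numeric(c), f = as.integer(f),
         alpha = as.numeric(alpha), n_iter = as.integer(n_iter),
         tau_p = as.numeric(tau_p), tau_d = as.numeric(tau_d),
         mode = mode, connectivity = as.integer(connectivity),
         spread = spread,
         pixel_pitch_um = if (is.null(pixel_pitch_um)) NULL
                          else as.numeric(pixel_pitch_um)),
    class = "pipeline_params"
  )
  validate_pipeline_params(p)
}

#' @keywords internal
validate_pipeline_params <- function(p) {
  if (!inherits(p, "pipeline_params"))
    stop("params must be built with pipeline_params()")
  if (is.na(p$m) || p$m < 1L) stop("m must be an integer >= 1")
  if (!is.finite(p$c) || p$c < 0) stop("c must be >= 0")
  if (is.na(p$f) || p$f < 1L) stop("f must be an integer >= 1")
  if (!is.finite(p$alpha) || p$alpha < 0) stop("alpha must be >= 0")
  if (is.na(p$n_iter) || p$n_iter < 1L) stop("n_iter must be >= 1")
  if (!is.finite(p$tau_p) || p$tau_p <= 0 ||
      !is.finite(p$tau_d) || p$tau_d <= 0)
    stop("tau_p and tau_d must be positive")
  if (p$tau_p * p$tau_d > 0.125 + 1e-12)
    stop("tau_p * tau_d must be <= 0.125 (got ",
         signif(p$tau_p * p$tau_d, 6), ")")
  if (!p$mode %in% c("tv", "direct", "median_direct"))
    stop("mode must be one of 'tv', 'direct', 'median_direct'")
  if (!p$connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (!p$spread %in% c("sd", "var")) stop("spread must be 'sd' or 'var'")
  if (!is.null(p$pixel_pitch_um) &&
      (!is.finite(p$pixel_pitch_um) || p$pixel_pitch_um <= 0))
    stop("pixel_pitch_um must be a positive number")
  p
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("<pipeline_params> m =", x$m, "| c =", x$c, "| f =", x$f,
      "| alpha =", x$alpha, "| N =", x$n_iter, "| mode =", x$mode, "\n")
  invisible(x)
}

#' Save / load a pipeline configuration
#'
#' Writes the parameter set and an optional image file list to a
#' human-readable YAML file, and reads it back. `load_config(save_config(
#' params, files, path))` round-trips exactly. Missing `tau_p`/`tau_d`
#' entries in a config are filled with their defaults (with a message);
#' unknown or malformed fields raise an error naming the field.
#'
#' @param params A [pipeline_params()] object.
#' @param file_list Character vector of image paths (may be empty).
#' @param path Config file path.
#' @return `save_config()` returns `path` invisibly; `load_config()`
#'   returns a list with `params` and `file_list`.
#' @export
save_config <- function(params, file_list = character(0), path) {
  params <- validate_pipeline_params(params)
  cfg <- list(
    tool = "tvcount",
    config_version = 1L,
    params = params[!vapply(params, is.null, logical(1))],
    files = as.list(as.character(file_list))
  )
  attributes(cfg$params) <- list(names = names(cfg$params))
  # precision 17 so doubles (e.g. tau = sqrt(0.125)) round-trip exactly
  yaml::write_yaml(cfg, path, precision = 17L)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(cfg$params))
    stop("malformed config: missing field 'params'")
  if (!identical(cfg$config_version, 1L) &&
      !identical(cfg$config_version, 1))
    stop("malformed config: unsupported 'config_version' (",
         cfg$config_version %||% "absent", ")")
  p <- cfg$params
  required <- c("m", "c", "f", "alpha", "n_iter", "mode",
                "connectivity", "spread")
  for (fld in required)
    if (is.null(p[[fld]])) stop("malformed config: missing field '", fld, "'")
  for (fld in c("tau_p", "tau_d"))
    if (is.null(p[[fld]])) {
      p[[fld]] <- sqrt(0.125)
      message("config has no '", fld, "'; using default sqrt(0.125)")
    }
  params <- pipeline_params(
    m = p$m, c = p$c, f = p$f, alpha = p$alpha, n_iter = p$n_iter,
    tau_p = p$tau_p, tau_d = p$tau_d, mode = p$mode,
    connectivity = p$connectivity, spread = p$spread,
    pixel_pitch_um = p$pixel_pitch_um
  )
  list(params = params,
       file_list = as.character(unlist(cfg$files %||% character(0))))
}
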