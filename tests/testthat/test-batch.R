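make_phantom_files <- function(dir, n_spots_list, size = 160, sep = 18,
                               seed0 = 100) {
  vapply(seq_along(n_spots_list), function(k) {
    ph <- generate_phantom(phantom_spec(
      height = size, width = size, n_spots = n_spots_list[[k]],
      min_separation = sep, blotch_amplitude = 0.05,
      pixel_noise_sd = 0.01, seed = seed0 + k))
    f <- file.path(dir, sprintf("ph%02d.png", k))
    save_gray_image(ph$image, f)
    f
  }, character(1))
}

test_that("a batch reports the known counts of its phantoms in order", {
  d <- withr::local_tempdir()
  files <- make_phantom_files(d, c(5, 10, 15))
  params <- pipeline_params(n_iter = 30)
  rep <- run_batch(files, params)
  expect_s3_class(rep, "batch_report")
  expect_equal(rep$path, files)
  expect_equal(rep$count, c(5L, 10L, 15L))
  expect_true(all(is.na(rep$density_per_mm2)))
  expect_true(all(is.na(rep$error)))
  # per-file results equal single-file runs, independent of list order
  rev_rep <- run_batch(rev(files), params)
  expect_equal(rev_rep$count, rev(rep$count))
  expect_equal(rev_rep$positions[[3]], rep$positions[[1]])
})

test_that("density follows count / (area * pitch^2) exactly", {
  d <- withr::local_tempdir()
  files <- make_phantom_files(d, 8)
  rep <- run_batch(files, pipeline_params(n_iter = 30, pixel_pitch_um = 2))
  # 160x160 px at 2 um/px -> (160*0.002)^2 mm^2
  expect_equal(rep$density_per_mm2,
               rep$count / (160 * 160 * (2 / 1000)^2))
})

test_that("unreadable files are recorded without aborting the batch", {
  d <- withr::local_tempdir()
  files <- make_phantom_files(d, c(5, 7))
  bad <- file.path(d, "missing.png")
  rep <- run_batch(c(files[1], bad, files[2]), pipeline_params(n_iter = 20))
  expect_equal(nrow(rep), 3)
  expect_true(is.na(rep$count[2]))
  expect_match(rep$error[2], "not found")
  expect_equal(rep$count[c(1, 3)], c(5L, 7L))
  expect_error(run_batch(character(0)), "empty file list")
})

test_that("batch reports serialize with parameter echo and positions", {
  d <- withr::local_tempdir()
  files <- make_phantom_files(d, 6)
  rep <- run_batch(files, pipeline_params(n_iter = 20, pixel_pitch_um = 1))
  out <- file.path(d, "report.csv")
  write_batch_report(rep, out)
  lines <- readLines(out)
  expect_true(any(grepl("^# params: m=30 c=2.5 f=5 alpha=0.05", lines)))
  body <- utils::read.csv(out, comment.char = "#")
  expect_equal(body$count, 6L)
  pos <- utils::read.csv(file.path(d, "report_positions.csv"))
  expect_equal(nrow(pos), 6)
  expect_true(all(c("file", "id", "row", "col", "size") %in% names(pos)))
})

test_that("configs round-trip exactly and repair missing step sizes", {
  d <- withr::local_tempdir()
  p <- pipeline_params(m = 20, c = 3.5, f = 40, alpha = 0.07, n_iter = 75,
                       mode = "median_direct", connectivity = 4,
                       pixel_pitch_um = 1.5)
  cfg <- file.path(d, "cfg.yaml")
  save_config(p, c("a.png", "b.tif"), cfg)
  got <- load_config(cfg)
  expect_identical(got$params, p)
  expect_identical(got$file_list, c("a.png", "b.tif"))
  # saved defaults carry the documented values
  save_config(pipeline_params(), character(0), cfg)
  y <- yaml::read_yaml(cfg)
  expect_equal(y$params$m, 30)
  expect_equal(y$params$c, 2.5)
  expect_equal(y$params$f, 5)
  expect_equal(y$params$alpha, 0.05)
  expect_equal(y$params$n_iter, 50)
  # missing tau fields are defaulted with a message
  y$params$tau_p <- NULL; y$params$tau_d <- NULL
  yaml::write_yaml(y, cfg, precision = 17L)
  expect_message(got2 <- load_config(cfg), "tau_p")
  expect_equal(got2$params$tau_p, sqrt(0.125))
  # malformed configs name the offending field
  y$params$m <- NULL
  yaml::write_yaml(y, cfg, precision = 17L)
  expect_error(suppressMessages(load_config(cfg)), "'m'")
  expect_error(load_config(file.path(d, "nope.yaml")), "not found")
})

test_that("tidy, glance and autoplot expose the result object", {
  ph <- generate_phantom(phantom_spec(height = 128, width = 128,
                                      n_spots = 7, min_separation = 20,
                                      seed = 9))
  res <- run_pipeline(ph$image, pipeline_params(n_iter = 20))
  td <- generics::tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), res$count)
  expect_true(all(c("id", "row", "col", "size") %in% names(td)))
  gl <- generics::glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$count, res$count)
  expect_equal(gl$mode, "tv")
  plt <- ggplot2::autoplot(res)
  expect_s3_class(plt, "ggplot")
  expect_s3_class(ggplot2::autoplot(ph), "ggplot")
  expect_s3_class(plot_gray_image(ph$image), "ggplot")
})
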