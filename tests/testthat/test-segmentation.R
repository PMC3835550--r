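test_that("threshold rule reproduces the hand-computed example", {
  # ten pixels {0, 1 x9}: mean 0.9, sample var 0.1, t = 0.9 - sqrt(0.1)
  x <- matrix(c(0, rep(1, 9)), 2, 5)
  mk <- threshold_mask(x, c = 1)
  expect_equal(attr(mk, "threshold"), 0.9 - sqrt(0.1))
  expect_equal(sum(mk), 1)
  expect_true(mk[1, 1])
  # constant image: zero variance, no pixel strictly below the mean
  expect_equal(sum(threshold_mask(matrix(0.5, 4, 4), c = 2.5)), 0)
  # single pixel: sample variance undefined
  expect_error(threshold_mask(matrix(0.5, 1, 1), c = 1), "single-pixel")
  # raw-variance variant thresholds at mean - c * var
  mv <- threshold_mask(x, c = 1, spread = "var")
  expect_equal(attr(mv, "threshold"), 0.9 - 0.1)
})

test_that("the mask is invariant under positive affine intensity maps", {
  set.seed(21)
  strip <- function(m) { attributes(m) <- list(dim = dim(m)); m }
  for (rep in 1:25) {
    x <- random_image(12, 12)
    a <- runif(1, 0.1, 3); b <- runif(1, -1, 1)
    cc <- runif(1, 0, 3)
    expect_identical(strip(threshold_mask(a * x + b, cc)),
                     strip(threshold_mask(x, cc)),
                     label = sprintf("rep %d", rep))
  }
})

test_that("component labelling matches connectivity semantics", {
  m <- matrix(FALSE, 3, 3); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(length(label_components(m, 8)$sizes), 1)
  expect_equal(length(label_components(m, 4)$sizes), 2)
  # plus-shaped cross: one 5-pixel component centered at its middle
  p <- matrix(FALSE, 5, 5)
  p[3, 2:4] <- TRUE; p[2:4, 3] <- TRUE
  cs <- label_components(p, 4)
  expect_equal(cs$sizes, 5L)
  expect_equal(cs$centroids$row, 3)
  expect_equal(cs$centroids$col, 3)
  # empty mask
  e <- label_components(matrix(FALSE, 4, 4))
  expect_equal(length(e$sizes), 0)
  expect_equal(nrow(e$centroids), 0)
  # labels ordered by first pixel in row-major scan
  q <- matrix(FALSE, 3, 5); q[1, 4] <- TRUE; q[2, 1] <- TRUE
  lab <- label_components(q, 8)$label_grid
  expect_equal(lab[1, 4], 1L)
  expect_equal(lab[2, 1], 2L)
})

test_that("labelling agrees with the flood-fill oracle on random masks", {
  set.seed(22)
  for (rep in 1:30) {
    m <- random_mask(sample(8:24, 1), sample(8:24, 1),
                     p = runif(1, 0.2, 0.6))
    for (conn in c(4, 8)) {
      got <- label_components(m, conn)
      ref <- canonical_labels(label_oracle(m, conn))
      expect_identical(canonical_labels(got$label_grid), ref)
      expect_equal(sum(got$sizes), sum(m))
    }
  }
})

test_that("size filtering keeps exactly the components of at least f pixels", {
  m <- matrix(FALSE, 8, 8)
  m[1:2, 1:2] <- TRUE        # size 4
  m[5:7, 5:6] <- TRUE        # size 6
  cs <- label_components(m, 8)
  expect_equal(sort(cs$sizes), c(4L, 6L))
  r5 <- count_cells(cs, f = 5)
  expect_equal(r5$count, 1)
  expect_equal(cs$centroids$size[r5$kept_ids], 6L)
  expect_equal(count_cells(cs, f = 1)$count, 2)
  expect_equal(count_cells(label_components(matrix(FALSE, 3, 3)), 1)$count, 0)
  # partition: kept + discarded = total
  expect_equal(r5$count + (r5$n_components - r5$count), length(cs$sizes))
})

test_that("counts are monotone in f and masks shrink with c", {
  set.seed(23)
  x <- random_image(40, 40)
  cs <- label_components(threshold_mask(x, 1), 8)
  counts <- vapply(1:20, function(f) count_cells(cs, f)$count, integer(1))
  expect_true(all(diff(counts) <= 0))
  prev <- threshold_mask(x, 0)
  for (cc in seq(0.5, 4, by = 0.5)) {
    cur <- threshold_mask(x, cc)
    expect_true(all(!cur | prev))  # cur subset of prev
    prev <- cur
  }
})

test_that("the full pipeline counts well-separated disks and is affine-stable", {
  ph <- generate_phantom(phantom_spec(
    height = 256, width = 256, n_spots = 20, spot_radius_range = c(4, 4),
    min_separation = 24, blotch_amplitude = 0, pixel_noise_sd = 0,
    seed = 31))
  res <- run_pipeline(ph$image, pipeline_params())
  expect_equal(res$count, 20)
  # constant image: empty mask in every mode
  for (md in c("tv", "direct", "median_direct")) {
    expect_equal(run_pipeline(matrix(0.6, 32, 32),
                              pipeline_params(mode = md, n_iter = 5))$count, 0)
  }
  # direct mode is unchanged under positive affine remapping
  x <- ph$image * 0.5 + 0.2
  r1 <- run_pipeline(ph$image, pipeline_params(mode = "direct"))
  r2 <- run_pipeline(x, pipeline_params(mode = "direct"))
  expect_equal(r1$count, r2$count)
  expect_equal(r1$positions$row, r2$positions$row)
})

test_that("labelling cross-checks against EBImage where conventions overlap", {
  skip_if_not_installed("EBImage")
  set.seed(24)
  m <- random_mask(30, 30, 0.4)
  ours <- label_components(m, 4)
  ref <- EBImage::bwlabel(matrix(as.numeric(m), 30, 30))
  expect_equal(length(ours$sizes), max(ref))
  expect_identical(canonical_labels(ours$label_grid),
                   canonical_labels(matrix(as.integer(ref), 30, 30)))
})
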