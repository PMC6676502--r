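test_that("8-bit RGB TIFFs round-trip pixel-identically", {
  stack <- constant_stack(4, 4, c(10, 20, 30))
  path <- withr::local_tempfile(fileext = ".tif")
  write_rgb_stack(stack, path)
  back <- read_rgb_stack(path)
  expect_equal(back$n_slices, 1L)
  expect_identical(back$planes[[1]], stack$planes[[1]])

  # random content, written by the generator, re-read identically
  syn <- generate_image(synth_spec(image_size = c(32, 32), n_nuclei = 3,
                                   radius_range = c(3, 4), noise_sd = 7,
                                   seed = 11))
  write_rgb_stack(syn$stack, path)
  again <- read_rgb_stack(path)
  expect_identical(again$planes[[1]], syn$stack$planes[[1]])
})

test_that("multi-slice stacks keep shape and slice count", {
  stack <- constant_stack(6, 5, c(1, 2, 3), n_slices = 3)
  path <- withr::local_tempfile(fileext = ".tif")
  write_rgb_stack(stack, path)
  back <- read_rgb_stack(path)
  expect_equal(back$n_slices, 3L)
  expect_equal(back$height, 6L)
  expect_equal(back$width, 5L)
  expect_true(all(vapply(back$planes,
                         function(p) all(dim(p) == c(6, 5, 3)), logical(1))))
})

test_that("16-bit input is linearly rescaled to the 8-bit contract", {
  path <- withr::local_tempfile(fileext = ".tif")
  vals16 <- c(2570, 25700, 65535)  # /257 -> 10, 100, 255
  a <- array(rep(vals16 / 65535, each = 16), c(4, 4, 3))
  tiff::writeTIFF(a, path, bits.per.sample = 16L)
  expect_message(stack <- read_rgb_stack(path), "16-bit")
  expect_equal(unique(as.vector(stack$planes[[1]][, , 1])), 10L)
  expect_equal(unique(as.vector(stack$planes[[1]][, , 2])), 100L)
  expect_equal(unique(as.vector(stack$planes[[1]][, , 3])), 255L)
})

test_that("missing files and non-RGB TIFFs are rejected with clear errors", {
  expect_error(read_rgb_stack("no/such/file.tif"), "file not found")
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(16), 4, 4), path)  # grayscale, 1 sample
  expect_error(read_rgb_stack(path), "3 colour samples.*found 1")
})

test_that("split_channels separates constant channels and max-projects", {
  stack <- constant_stack(4, 4, c(10, 20, 30))
  ch <- split_channels(stack)
  expect_true(all(ch$red == 10L))
  expect_true(all(ch$green == 20L))
  expect_true(all(ch$blue == 30L))

  # two slices differing in red at one pixel: projection takes the max
  planes <- list(constant_stack(4, 4, c(5, 0, 0))$planes[[1]],
                 constant_stack(4, 4, c(5, 0, 0))$planes[[1]])
  planes[[2]][2, 3, 1] <- 9L
  stack2 <- fluorquant:::new_rgb_stack(planes)
  ch2 <- split_channels(stack2, "max")
  expect_equal(ch2$red[2, 3], 9L)
  expect_equal(ch2$red[1, 1], 5L)

  expect_error(split_channels(stack2, "single", slice = 3), "out of range")
})

test_that("max projection equals the per-pixel loop oracle on random stacks", {
  set.seed(31)
  planes <- lapply(1:3, function(s) {
    array(sample(0:255, 6 * 7 * 3, replace = TRUE), c(6, 7, 3))
  })
  stack <- fluorquant:::new_rgb_stack(planes)
  ch <- split_channels(stack, "max")
  for (k in 1:3) {
    want <- matrix(0L, 6, 7)
    for (r in 1:6) for (c in 1:7) {
      want[r, c] <- max(planes[[1]][r, c, k], planes[[2]][r, c, k],
                        planes[[3]][r, c, k])
    }
    expect_equal(unclass(ch[[k]]), want, ignore_attr = TRUE)
  }
})

test_that("split channels recombine into the source slice", {
  syn <- generate_image(synth_spec(image_size = c(24, 24), n_nuclei = 2,
                                   radius_range = c(2, 3), noise_sd = 4,
                                   seed = 5))
  ch <- split_channels(syn$stack, "single", slice = 1)
  rec <- array(0L, c(24, 24, 3))
  rec[, , 1] <- unclass(ch$red); rec[, , 2] <- unclass(ch$green)
  rec[, , 3] <- unclass(ch$blue)
  expect_identical(rec, syn$stack$planes[[1]])
})

test_that("results CSV has the fixed header, per-ROI rows and a summary row", {
  syn <- generate_image(synth_spec(n_nuclei = 3, seed = 7))
  ch <- split_channels(syn$stack)
  res <- quantify_image(ch$red, ch$green, image_id = "img1")
  dir <- withr::local_tempdir()
  path <- write_results_csv(res, dir)
  lines <- readLines(path)
  expect_equal(lines[1],
    "image,roi_id,area_px,mean_raw,mean_bg,mean_corrected,centroid_x,centroid_y")
  expect_length(lines, 1 + 3 + 1)  # header + 3 ROIs + summary
  parsed <- readr::read_csv(path, show_col_types = FALSE)
  smry <- parsed[parsed$roi_id == "summary", ]
  expect_equal(smry$area_px, 3)  # ROI count travels in area_px
  # round trip of the numeric ROI rows
  rois <- parsed[parsed$roi_id != "summary", ]
  expect_equal(as.numeric(rois$mean_corrected), res$mean_corrected,
               tolerance = 1e-6)
  expect_equal(as.numeric(rois$mean_raw), res$mean_raw, tolerance = 1e-6)
})

test_that("an empty ROI table writes header plus a zero-count summary row", {
  syn <- generate_image(synth_spec(n_nuclei = 0, seed = 1))
  ch <- split_channels(syn$stack)
  res <- quantify_image(ch$red, ch$green,
                        threshold = threshold_spec(100, 255),
                        image_id = "empty")
  dir <- withr::local_tempdir()
  path <- write_results_csv(res, dir)
  parsed <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(parsed), 1)
  expect_equal(parsed$roi_id, "summary")
  expect_equal(parsed$area_px, 0)
  expect_error(write_results_csv(res, file.path(dir, "nope")),
               "directory does not exist")
})
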