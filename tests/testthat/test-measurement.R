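quant_fixture <- function(n_nuclei = 6, noise_sd = 0, seed = 3, ...) {
  syn <- generate_image(synth_spec(n_nuclei = n_nuclei, noise_sd = noise_sd,
                                   seed = seed, ...))
  ch <- split_channels(syn$stack)
  list(syn = syn, marker = ch$red, query = ch$green)
}

test_that("mask pair partitions the selection exactly", {
  fx <- quant_fixture()
  mask <- apply_threshold(fx$marker, threshold_spec(110, 255))
  parts <- analyze_particles(mask, particle_filter(min_area = 1, min_circ = 0))
  sel <- selection_region(rbind(c(5, 5), c(120, 5), c(120, 120), c(5, 120)))
  masks <- build_masks(parts, sel, dim(fx$marker))
  selm <- selection_mask(sel, dim(fx$marker))
  expect_false(any(masks$measurement_mask & masks$background_mask))
  expect_identical(masks$measurement_mask | masks$background_mask, selm)
  expect_equal(sum(masks$measurement_mask) + sum(masks$background_mask),
               sum(selm))
})

test_that("degenerate mask pairs behave as documented", {
  fx <- quant_fixture(n_nuclei = 0)
  empty <- analyze_particles(matrix(FALSE, 128, 128))
  masks <- build_masks(empty, whole_image(), c(128, 128))
  expect_false(any(masks$measurement_mask))
  expect_true(all(masks$background_mask))
  # particles tiling the whole selection leave no background
  full <- analyze_particles(matrix(TRUE, 16, 16),
                            particle_filter(min_area = 1, min_circ = 0))
  masks2 <- build_masks(full, whole_image(), c(16, 16))
  expect_false(any(masks2$background_mask))
  expect_error(measure_background(channel_image(matrix(7L, 16, 16)), masks2),
               "background mask is empty")
})

test_that("partition invariant holds across random particle/selection draws", {
  set.seed(202)
  for (rep in 1:15) {
    m <- random_blob_mask(48, 48, sample(2:8, 1))
    parts <- analyze_particles(m, particle_filter(min_area = 1, min_circ = 0))
    cx <- runif(1, 14, 34); cy <- runif(1, 14, 34)
    ang <- sort(runif(sample(3:7, 1), 0, 2 * pi))
    sel <- selection_region(cbind(cx + runif(length(ang), 6, 13) * cos(ang),
                                  cy + runif(length(ang), 6, 13) * sin(ang)))
    masks <- build_masks(parts, sel, c(48, 48))
    selm <- selection_mask(sel, c(48, 48))
    expect_equal(sum(masks$measurement_mask) + sum(masks$background_mask),
                 sum(selm), label = sprintf("replicate %d", rep))
    expect_false(any(masks$measurement_mask & masks$background_mask))
  }
})

test_that("ROI means are exact arithmetic means of query pixels", {
  q <- channel_image(matrix(80L, 20, 20))
  m <- matrix(FALSE, 20, 20); m[5:8, 5:8] <- TRUE
  parts <- analyze_particles(m, particle_filter(min_area = 1, min_circ = 0))
  expect_equal(measure_rois(q, parts)$mean_raw, 80)

  # two-pixel particle with values 10 and 30 averages to 20
  q2 <- matrix(0L, 6, 6); q2[3, 3] <- 10L; q2[3, 4] <- 30L
  m2 <- matrix(FALSE, 6, 6); m2[3, 3:4] <- TRUE
  parts2 <- analyze_particles(m2, particle_filter(min_area = 1, min_circ = 0))
  expect_equal(measure_rois(channel_image(q2), parts2)$mean_raw, 20)

  # random image: explicit-loop summation oracle
  set.seed(6)
  qv <- matrix(as.integer(sample(0:255, 400, TRUE)), 20, 20)
  m3 <- random_blob_mask(20, 20, 3)
  parts3 <- analyze_particles(m3, particle_filter(min_area = 1, min_circ = 0))
  got <- measure_rois(channel_image(qv), parts3)
  for (i in seq_len(nrow(parts3))) {
    acc <- 0
    for (px in parts3$pixels[[i]]) acc <- acc + qv[px]
    expect_equal(got$mean_raw[i], acc / parts3$area[i], tolerance = 1e-9)
  }
  expect_error(measure_rois(channel_image(matrix(0L, 5, 5)), parts3),
               "do not match")
})

test_that("background is the mean over the background mask", {
  q <- matrix(10L, 10, 10); q[, 6:10] <- 30L
  masks <- build_masks(analyze_particles(matrix(FALSE, 10, 10)),
                       whole_image(), c(10, 10))
  expect_equal(measure_background(channel_image(q), masks), 20)
  set.seed(8)
  qv <- matrix(as.integer(sample(0:255, 100, TRUE)), 10, 10)
  expect_equal(measure_background(channel_image(qv), masks), mean(qv))
  expect_equal(measure_background(channel_image(qv), masks, stat = "median"),
               median(as.numeric(qv)))
})

test_that("noiseless nuclei are recovered exactly, background subtracted", {
  truth_means <- seq(60, 240, by = 20)
  fx <- quant_fixture(n_nuclei = 10, query_means = truth_means)
  res <- quantify_image(fx$marker, fx$query, image_id = "exact")
  expect_equal(nrow(res), 10)
  expect_setequal(res$mean_corrected, truth_means - 20)
  expect_equal(unique(res$mean_bg), 20)
  smry <- glance(res)
  expect_equal(smry$n_rois, 10)
  expect_equal(smry$mean_corrected_mean, mean(truth_means - 20))
})

test_that("query = marker yields marker in-ROI means; no nuclei yields none", {
  fx <- quant_fixture(n_nuclei = 5)
  res <- quantify_image(fx$marker, fx$marker, image_id = "self")
  expect_true(all(res$mean_raw == 200))  # marker disks are at level 200
  fx0 <- quant_fixture(n_nuclei = 0)
  res0 <- quantify_image(fx0$marker, fx0$query,
                         threshold = threshold_spec(110, 255), image_id = "none")
  expect_equal(nrow(res0), 0)
  expect_equal(glance(res0)$n_rois, 0)
})

test_that("adding a constant to the query leaves corrected means unchanged", {
  fx <- quant_fixture(n_nuclei = 8, query_mean = c(mu = 120, sd = 25), seed = 9)
  base <- quantify_image(fx$marker, fx$query, image_id = "base")
  for (c_shift in c(5, 25, 50)) {
    shifted <- channel_image(unclass(fx$query) + as.integer(c_shift))
    res <- quantify_image(fx$marker, shifted, image_id = "shifted")
    expect_equal(res$mean_corrected, base$mean_corrected, tolerance = 1e-12)
  }
})

test_that("ROI geometry depends only on the marker channel", {
  fx <- quant_fixture(n_nuclei = 6, seed = 13)
  a <- quantify_image(fx$marker, fx$query, image_id = "a")
  set.seed(99)
  permuted <- channel_image(matrix(sample(unclass(fx$query)), 128, 128))
  # permuted query pushes some ROIs below background: flagged, not dropped
  expect_warning(b <- quantify_image(fx$marker, permuted, image_id = "b"),
                 "negative corrected")
  expect_equal(b$roi_id, a$roi_id)
  expect_equal(b$area_px, a$area_px)
  expect_equal(b$centroid_x, a$centroid_x)
  expect_equal(b$centroid_y, a$centroid_y)
})

test_that("scaling query intensities scales corrected means proportionally", {
  truth <- c(40, 60, 80, 100)
  fx <- quant_fixture(n_nuclei = 4, query_means = truth, background_level = 0)
  base <- quantify_image(fx$marker, fx$query, image_id = "k1")
  doubled <- channel_image(unclass(fx$query) * 2L)
  res <- quantify_image(fx$marker, doubled, image_id = "k2")
  expect_equal(res$mean_corrected, 2 * base$mean_corrected, tolerance = 1e-9)
})

test_that("negative corrected means are flagged but not clipped", {
  marker <- matrix(20L, 32, 32)
  marker[10:16, 10:16] <- 200L
  query <- matrix(50L, 32, 32)
  query[10:16, 10:16] <- 5L  # dim nucleus on bright background
  expect_warning(
    res <- quantify_image(channel_image(marker), channel_image(query),
                          threshold = threshold_spec(110, 255),
                          filter = particle_filter(min_area = 1, min_circ = 0),
                          image_id = "neg"),
    "negative corrected mean")
  expect_lt(res$mean_corrected, 0)
})

test_that("stage failures carry the stage name", {
  expect_error(
    quantify_image(channel_image(matrix(100L, 8, 8)),
                   channel_image(matrix(0L, 8, 8))),
    "\\[stage auto_threshold\\]")
})
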