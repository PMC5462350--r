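color_pixel <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))

gray_image_for_test <- function(m, mask = NULL) {
  structure(list(pixels = m, mask = mask), class = "gray_image")
}

render_leaf_for_test <- function(dim) {
  img <- make_class(leaf_shape_params("ellipse", 1.6, margin_serration = 0.05),
                    n = 1, noise = noise_preset("none"), seed = 3,
                    dim = dim)[[1]]
  to_grayscale(img)$pixels
}

test_that("grayscale conversion uses the standard luma weights, unrounded", {
  expect_equal(to_grayscale(color_pixel(255, 0, 0))$pixels[1, 1], 76.2195)
  expect_equal(to_grayscale(color_pixel(0, 0, 0))$pixels[1, 1], 0)
  expect_equal(to_grayscale(color_pixel(255, 255, 255))$pixels[1, 1], 254.9745)
  arr <- array(runif(6 * 4 * 3, 0, 255), c(6, 4, 3))
  g <- to_grayscale(arr)
  expect_equal(dim(g$pixels), c(6, 4))
  expect_true(all(g$pixels >= 0 & g$pixels <= 254.9745))
  # linear in each channel
  arr2 <- arr; arr2[, , 2] <- arr2[, , 2] / 2
  expect_equal(g$pixels - to_grayscale(arr2)$pixels, 0.587 * arr[, , 2] / 2)
  expect_error(to_grayscale(array(0, c(0, 4, 3))), "empty")
})

test_that("background segmentation thresholds at >= and flags degenerate images", {
  m <- matrix(c(10, 40, 29, 30), 2, 2, byrow = TRUE)  # [[10,40],[29,30]]
  g <- segment_background(gray_image_for_test(m), 30)
  expect_identical(g$mask, matrix(c(0L, 1L, 0L, 1L), 2, 2, byrow = TRUE) * 1L)
  expect_error(segment_background(gray_image_for_test(matrix(0, 3, 3)), 30),
               "degenerate")
  expect_true(all(segment_background(
    gray_image_for_test(matrix(255, 3, 3)), 30)$mask == 1))
})

test_that("segmentation keeps only the largest connected component", {
  m <- matrix(5, 20, 20)
  m[5:15, 5:10] <- 100       # leaf blob
  m[1, 19] <- 100            # isolated speck
  g <- segment_background(gray_image_for_test(m), 30)
  expect_equal(g$mask[1, 19], 0L)
  expect_equal(sum(g$mask), 11 * 6)
})

test_that("long-axis alignment verticalizes the principal axis", {
  mask <- ellipse_mask(80, 80, a = 12, b = 30, angle = 0)  # horizontal
  g <- gray_image_for_test(mask * 150)
  g <- segment_background(g, 30)
  expect_gt(abs(mask_axis_angle(g$mask)), pi / 4)
  al <- align_long_axis(g)
  expect_lt(abs(mask_axis_angle(al$mask)), 1 * pi / 180)
  # already vertical: rotation angle about zero
  maskv <- ellipse_mask(80, 80, a = 30, b = 12, angle = 0)
  alv <- align_long_axis(segment_background(gray_image_for_test(maskv * 150), 30))
  expect_lt(abs(attr(alv, "angle")), 1 * pi / 180)
})

test_that("alignment warns and passes through isotropic foregrounds", {
  disk <- ellipse_mask(60, 60, a = 20, b = 20)
  g <- segment_background(gray_image_for_test(disk * 150), 30)
  expect_warning(al <- align_long_axis(g), "isotropic")
  expect_identical(al$pixels, g$pixels)
})

test_that("alignment is idempotent up to resampling noise", {
  mask <- ellipse_mask(90, 90, a = 14, b = 32, angle = 0.6)
  g <- segment_background(gray_image_for_test(mask * 150), 30)
  a1 <- align_long_axis(g)
  a2 <- suppressWarnings(align_long_axis(a1))
  expect_lt(abs(mask_axis_angle(a2$mask) - mask_axis_angle(a1$mask)),
            1 * pi / 180)
})

test_that("size normalization meets the shape contract and preserves constants", {
  mask <- ellipse_mask(64, 32, a = 25, b = 12)
  g <- gray_image_for_test(mask * 120)
  g <- segment_background(g, 30)
  out <- normalize_size(g, c(32L, 16L))
  expect_equal(dim(out$pixels), c(32, 16))
  expect_equal(dim(out$mask), c(32, 16))
  # constant foreground on constant background stays within the constants
  expect_true(all(out$pixels >= 0 & out$pixels <= 120 + 1e-9))
  expect_true(max(abs(out$pixels[out$mask == 1] - 120)) < 1e-6 ||
                all(out$pixels[out$mask == 1] <= 120))
  g2 <- gray_image_for_test(matrix(77, 40, 20),
                            mask = matrix(1L, 40, 20))
  out2 <- normalize_size(g2, c(32L, 16L))
  expect_true(all(abs(out2$pixels - 77) < 1e-9))
})

test_that("downsample/upsample round trip keeps the silhouette (IoU > 0.8)", {
  big <- render_leaf_for_test(c(320L, 160L))
  g <- segment_background(gray_image_for_test(big), 30)
  small <- normalize_size(g, c(32L, 16L))
  back <- (leafjdsr:::resize_matrix(small$mask, 320, 160) >= 0.5) * 1L
  # compare against the cropped original mask, resampled to the same frame
  idx <- which(g$mask == 1, arr.ind = TRUE)
  rr <- range(idx[, 1]); cr <- range(idx[, 2])
  ref <- (leafjdsr:::resize_matrix(
    g$mask[rr[1]:rr[2], cr[1]:cr[2]], 320, 160) >= 0.5) * 1L
  iou <- sum(back & ref) / sum(back | ref)
  expect_gt(iou, 0.8)
})

test_that("edge extraction: uniform input, step edge localization, binary output", {
  cfg <- preprocess_config()
  uni <- gray_image_for_test(matrix(100, 32, 16))
  expect_true(all(extract_orientation(uni, cfg) == 0))
  # vertical step edge at column 8: edge pixels confined to columns 7..9
  step <- matrix(40, 32, 16); step[, 8:16] <- 200
  e <- extract_orientation(gray_image_for_test(step), cfg)
  expect_true(all(e %in% c(0L, 1L)))
  expect_gt(sum(e), 0)
  expect_true(all(which(colSums(e) > 0) %in% 7:9))
  # fourstep variant also returns a binary map with edges near the step
  cfg4 <- preprocess_config(extractor_mode = "fourstep")
  e4 <- extract_orientation(gray_image_for_test(step), cfg4)
  expect_true(all(e4 %in% c(0L, 1L)))
  expect_gt(sum(e4), 0)
})

test_that("edge-pixel count is non-increasing in the sensitivity threshold", {
  leaf <- render_leaf_for_test(c(96L, 64L))
  g <- segment_background(gray_image_for_test(leaf), 30)
  g <- normalize_size(g, c(32L, 16L))
  counts <- vapply(c(0.01, 0.05, 0.12, 0.3, 0.5), function(r) {
    sum(extract_orientation(g, preprocess_config(sensitivity_threshold = r)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gte(counts[1], counts[length(counts)])
})

test_that("vectorize flattens row-major to length 512 and errors on bad shapes", {
  img <- matrix(0L, 32, 16)
  expect_length(vectorize(img), 512)
  expect_identical(vectorize(matrix(1L, 32, 16)), rep(1L, 512))
  img[1, 6] <- 1L           # row 0, col 5 in 0-based indexing
  expect_equal(which(vectorize(img) == 1), 6)
  expect_error(vectorize(matrix(0L, 16, 32)), "32x16")
  # vectorize then reshape is the identity
  set.seed(5)
  b <- matrix(rbinom(512, 1, 0.3), 32, 16)
  expect_identical(matrix(vectorize(b), 32, 16, byrow = TRUE), b + 0L)
})

test_that("full preprocessing is deterministic", {
  leaf <- make_class(leaf_shape_params("lobed", 1.5, 4, 0.4),
                     n = 1, noise = noise_preset("low"), seed = 9)[[1]]
  cfg <- preprocess_config()
  expect_identical(preprocess_image(leaf, cfg), preprocess_image(leaf, cfg))
})
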