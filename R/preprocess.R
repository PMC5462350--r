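#' Preprocessing configuration
#'
#' Bundles the parameters of the leaf preprocessing chain: background
#' segmentation, long-axis alignment, size normalization and binary edge
#' (orientation) extraction.
#'
#' @param sensitivity_threshold Canny binarization threshold on the
#'   max-normalized gradient magnitude, in (0, 1).  Lower values keep more
#'   edge pixels.  Default 0.12.
#' @param background_threshold gray level below which a pixel is background,
#'   in \[0, 255\].  Default 30, matching photographs of leaves on a dark,
#'   uniform background.
#' @param target_shape integer `(rows, cols)` of the normalized image.
#'   Default `c(32, 16)`, giving feature vectors of length 512.
#' @param gaussian_sigma standard deviation (pixels) of the Gaussian
#'   smoothing applied before gradient computation.  Default 1.
#' @param low_ratio hysteresis low threshold as a fraction of the high one
#'   (`low = sensitivity_threshold / low_ratio`).  Default 2.5.
#' @param do_hist_equalize apply histogram equalization after size
#'   normalization.  Default `TRUE`.
#' @param do_align rotate so the foreground's principal axis is vertical.
#'   Default `TRUE`.
#' @param denoise_radius radius of the median filter applied to the
#'   grayscale image before segmentation (0 disables).  Removes
#'   salt-and-pepper sensor noise that would otherwise corrupt the
#'   foreground mask.  Default 1 (a 3x3 window).
#' @param extractor_mode `"canny"` (Gaussian + Sobel + non-maximum
#'   suppression + hysteresis) or `"fourstep"` (Gaussian + Roberts cross +
#'   3x3 dilation + non-maximum suppression + single-threshold
#'   binarization).
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(sensitivity_threshold = 0.12,
                              background_threshold = 30,
                              target_shape = c(32L, 16L),
                              gaussian_sigma = 1,
                              low_ratio = 2.5,
                              do_hist_equalize = TRUE,
                              do_align = TRUE,
                              denoise_radius = 1L,
                              extractor_mode = c("canny", "fourstep")) {
  extractor_mode <- match.arg(extractor_mode)
  stopifnot(sensitivity_threshold > 0, sensitivity_threshold < 1,
            background_threshold >= 0, background_threshold <= 255,
            gaussian_sigma > 0, low_ratio >= 1,
            length(target_shape) == 2, all(target_shape >= 2))
  structure(list(sensitivity_threshold = sensitivity_threshold,
                 background_threshold = background_threshold,
                 target_shape = as.integer(target_shape),
                 gaussian_sigma = gaussian_sigma,
                 low_ratio = low_ratio,
                 do_hist_equalize = isTRUE(do_hist_equalize),
                 do_align = isTRUE(do_align),
                 denoise_radius = as.integer(denoise_radius),
                 extractor_mode = extractor_mode),
            class = "preprocess_config")
}

#' Convert a color leaf image to grayscale
#'
#' Uses the standard luma weights `Gray = 0.2989 R + 0.5870 G + 0.1140 B`.
#' Values are kept real-valued (no rounding), on the \[0, 255\] scale.
#'
#' @param img an H x W x 3 numeric array with channel values in \[0, 255\]
#'   (an H x W matrix is accepted as already-grayscale).
#' @return a `gray_image`: list with `pixels` (H x W matrix) and `mask`
#'   (`NULL` until [segment_background()] is applied).
#' @export
to_grayscale <- function(img) {
  if (is.list(img) && !is.null(img$pixels)) return(img)
  if (is.matrix(img)) return(gray_image(img))
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] < 3L) {
    stop("expected an H x W x 3 color array")
  }
  if (dim(img)[1] < 1L || dim(img)[2] < 1L) stop("empty image")
  if (min(img) < 0 || max(img) > 255) stop("channel values must be in [0, 255]")
  g <- 0.2989 * img[, , 1] + 0.5870 * img[, , 2] + 0.1140 * img[, , 3]
  gray_image(matrix(g, dim(img)[1], dim(img)[2]))
}

gray_image <- function(pixels, mask = NULL) {
  structure(list(pixels = pixels, mask = mask), class = "gray_image")
}

#' Separate the leaf from a low-intensity background
#'
#' Pixels with gray value below the threshold are taken as background.  The
#' rule assumes photographs against a dark, near-uniform backdrop, so the
#' leaf (foreground) is the brighter region.  When the thresholded mask
#' falls apart into several connected components (isolated bright noise
#' specks away from the leaf), only the largest component is kept, so
#' stray pixels cannot distort the bounding box or the principal axis.
#'
#' @param img a `gray_image`.
#' @param background_threshold gray cut-off; pixels `>= threshold` are
#'   foreground.
#' @param largest_component keep only the largest 8-connected foreground
#'   component.  Default `TRUE`.
#' @return the `gray_image` with its `mask` field set (1 = leaf).
#' @export
segment_background <- function(img, background_threshold = 30,
                               largest_component = TRUE) {
  img <- to_grayscale(img)
  mask <- (img$pixels >= background_threshold) * 1L
  if (sum(mask) == 0L) {
    stop("degenerate image: no foreground pixel at or above gray level ",
         background_threshold)
  }
  if (largest_component) {
    lab <- from_ebi(EBImage::bwlabel(as_ebi(mask)))
    sizes <- tabulate(lab[lab > 0])
    mask <- (lab == which.max(sizes)) * 1L
  }
  gray_image(img$pixels, mask)
}

#' Rotate a leaf so its geometric long axis is vertical
#'
#' The principal axis of the foreground pixel coordinates (leading
#' eigenvector of their covariance) is rotated to the row direction, about
#' the foreground centroid, with bilinear resampling.  The remaining 180
#' degree ambiguity is resolved by placing the foreground-mass-heavier half
#' in the bottom half of the frame.  Near-isotropic foregrounds (no
#' distinct long axis) are returned unrotated with a warning.
#'
#' @param img a segmented `gray_image` (mask present).
#' @param isotropy_tol eigenvalue ratio below which the shape is treated as
#'   isotropic.
#' @return the rotated `gray_image`; the applied angle (radians) is stored
#'   in attribute `"angle"`.
#' @export
align_long_axis <- function(img, isotropy_tol = 1.02) {
  stopifnot(inherits(img, "gray_image"), !is.null(img$mask))
  idx <- which(img$mask == 1, arr.ind = TRUE)
  if (nrow(idx) < 3L) stop("degenerate image: foreground too small to align")
  cen <- colMeans(idx)
  cov2 <- stats::cov(idx)
  eg <- eigen(cov2, symmetric = TRUE)
  if (eg$values[2] <= 0 || eg$values[1] / eg$values[2] < isotropy_tol) {
    warning("foreground is nearly isotropic; skipping alignment")
    return(structure(img, angle = 0))
  }
  v <- eg$vectors[, 1]                       # (d_row, d_col) of long axis
  if (v[1] < 0) v <- -v                      # canonical sign: downward row
  theta <- atan2(v[2], v[1])                 # angle from the row axis
  out <- rotate_about(img$pixels, img$mask, cen, -theta)
  # 180-degree disambiguation: heavier half goes to the bottom
  idx2 <- which(out$mask == 1, arr.ind = TRUE)
  if (nrow(idx2) > 0L) {
    med <- mean(idx2[, 1])
    below <- sum(idx2[, 1] > med)
    if (below < nrow(idx2) - below) {
      out$pixels <- out$pixels[nrow(out$pixels):1, ncol(out$pixels):1]
      out$mask <- out$mask[nrow(out$mask):1, ncol(out$mask):1]
    }
  }
  structure(gray_image(out$pixels, out$mask), angle = -theta)
}

# Rotate image content by `phi` radians about `cen` (row, col), inverse
# mapping with bilinear sampling; out-of-frame samples are 0 (background).
rotate_about <- function(pixels, mask, cen, phi) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  dst <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  dr <- dst$r - cen[1]; dc <- dst$c - cen[2]
  sr <- cen[1] + cos(phi) * dr + sin(phi) * dc
  sc <- cen[2] - sin(phi) * dr + cos(phi) * dc
  px <- matrix(bilinear_sample(pixels, sr, sc), nr, nc)
  mk <- matrix(as.integer(bilinear_sample(mask, sr, sc) >= 0.5), nr, nc)
  list(pixels = px, mask = mk)
}

bilinear_sample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  at <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- numeric(length(ri))
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  at(r0, c0) * (1 - fr) * (1 - fc) + at(r0 + 1, c0) * fr * (1 - fc) +
    at(r0, c0 + 1) * (1 - fr) * fc + at(r0 + 1, c0 + 1) * fr * fc
}

#' Crop to the leaf bounding box and resample to a fixed size
#'
#' The foreground bounding box is cropped and bilinearly resampled to
#' `target_shape` (default 32 x 16), after which all leaves live in a
#' common coordinate frame for pixelwise comparison.  Histogram
#' equalization can be applied afterwards to spread the gray levels.
#'
#' @param img a segmented `gray_image`.
#' @param target_shape integer `(rows, cols)`.
#' @param equalize apply histogram equalization to the resampled gray
#'   values.
#' @return a `gray_image` of exactly `target_shape`.
#' @export
normalize_size <- function(img, target_shape = c(32L, 16L), equalize = FALSE) {
  stopifnot(inherits(img, "gray_image"), !is.null(img$mask))
  idx <- which(img$mask == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("degenerate image: empty foreground")
  rr <- range(idx[, 1]); cr <- range(idx[, 2])
  if (rr[1] == rr[2] || cr[1] == cr[2]) {
    stop("degenerate image: foreground bounding box has zero extent")
  }
  px <- img$pixels[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  mk <- img$mask[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  px2 <- resize_matrix(px, target_shape[1], target_shape[2])
  mk2 <- (resize_matrix(mk, target_shape[1], target_shape[2]) >= 0.5) * 1L
  if (equalize) {
    eq <- EBImage::equalize(as_ebi(px2 / 255), range = c(0, 1), levels = 256)
    px2 <- from_ebi(eq) * 255
  }
  gray_image(px2, mk2)
}

resize_matrix <- function(m, rows, cols) {
  if (nrow(m) == rows && ncol(m) == cols) return(m + 0)
  from_ebi(EBImage::resize(as_ebi(m), w = cols, h = rows,
                           filter = "bilinear"))
}

as_ebi <- function(m) EBImage::Image(t(m))
from_ebi <- function(img) t(EBImage::imageData(img))

#' Extract the binary edge-orientation image
#'
#' Reduces a normalized grayscale leaf to a binary edge map that encodes
#' its contour and vein structure.  Two extractors are available:
#'
#' * `"canny"`: Gaussian smoothing, Sobel gradients, non-maximum
#'   suppression along the gradient direction, then hysteresis
#'   thresholding with high threshold `sensitivity_threshold` (on the
#'   max-normalized gradient magnitude) and low threshold
#'   `high / low_ratio`.
#' * `"fourstep"`: Gaussian smoothing, Roberts-cross gradient magnitude,
#'   3x3 morphological dilation, non-maximum suppression, then a single
#'   threshold at `sensitivity_threshold`.
#'
#' An all-zero edge map is permitted here (a featureless input has no
#' edges); downstream Jaccard computations guard the degenerate case.
#'
#' @param img a `gray_image` (typically 32 x 16 after [normalize_size()]).
#' @param cfg a [preprocess_config()].
#' @return a binary matrix of the same shape (1 = edge).
#' @export
extract_orientation <- function(img, cfg = preprocess_config()) {
  img <- to_grayscale(img)
  g <- smooth_gaussian(img$pixels / 255, cfg$gaussian_sigma)
  if (cfg$extractor_mode == "canny") {
    gr <- sobel_gradient(g)
    mag <- nonmax_suppress(gr$mag, gr$gx, gr$gy)
    mx <- max(mag)
    if (mx < 1e-9) return(matrix(0L, nrow(g), ncol(g)))
    mag <- mag / mx
    hysteresis(mag, cfg$sensitivity_threshold,
               cfg$sensitivity_threshold / cfg$low_ratio)
  } else {
    gr <- roberts_gradient(g)
    mag <- from_ebi(EBImage::dilate(as_ebi(gr$mag), EBImage::makeBrush(3, "box")))
    mag <- nonmax_suppress(mag, gr$gx, gr$gy)
    mx <- max(mag)
    if (mx < 1e-9) return(matrix(0L, nrow(g), ncol(g)))
    (mag / mx >= cfg$sensitivity_threshold) * 1L
  }
}

# separable Gaussian with replicate (edge-clamped) boundary: a constant
# image stays exactly constant and image borders produce no phantom edges
smooth_gaussian <- function(m, sigma) {
  half <- ceiling(3 * sigma)
  w <- exp(-(-half:half)^2 / (2 * sigma^2)); w <- w / sum(w)
  conv1 <- function(x, w) {
    n <- length(x); half <- (length(w) - 1) / 2
    xi <- x[pmin(pmax(seq_len(n + 2 * half) - half, 1), n)]
    as.numeric(stats::filter(xi, w, sides = 2)[(half + 1):(half + n)])
  }
  m2 <- apply(m, 2, conv1, w = w)
  t(apply(m2, 1, conv1, w = w))
}

# shift with replicate boundary (out-of-frame samples clamp to the edge)
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1), nc)
  m[ri, ci, drop = FALSE]
}

sobel_gradient <- function(g) {
  # 3x3 Sobel via shifts; gx = d/d(col), gy = d/d(row)
  gx <- (shift_mat(g, 0, -1) - shift_mat(g, 0, 1)) * 2 +
    shift_mat(g, -1, -1) - shift_mat(g, -1, 1) +
    shift_mat(g, 1, -1) - shift_mat(g, 1, 1)
  gy <- (shift_mat(g, -1, 0) - shift_mat(g, 1, 0)) * 2 +
    shift_mat(g, -1, -1) - shift_mat(g, 1, -1) +
    shift_mat(g, -1, 1) - shift_mat(g, 1, 1)
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

roberts_gradient <- function(g) {
  d1 <- g - shift_mat(g, -1, -1)   # I(r,c) - I(r+1,c+1)
  d2 <- shift_mat(g, -1, 0) - shift_mat(g, 0, -1)  # I(r+1,c) - I(r,c+1)
  # Roberts responses are along the diagonals; rotate 45 degrees back to
  # the row/col frame so non-maximum suppression can use them
  gx <- (d1 - d2) / sqrt(2)
  gy <- (d1 + d2) / sqrt(2)
  list(gx = gx, gy = gy, mag = sqrt(d1^2 + d2^2))
}

nonmax_suppress <- function(mag, gx, gy) {
  ang <- atan2(gy, gx)                      # gradient direction
  sector <- floor(((ang / pi * 4) + 4.5)) %% 4  # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  n1 <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  for (s in 0:3) {
    d <- n1[[s + 1]]
    a <- shift_mat(mag, d[1], d[2])
    b <- shift_mat(mag, -d[1], -d[2])
    keep <- keep | (sector == s & mag >= a & mag >= b)
  }
  mag * keep
}

hysteresis <- function(mag, high, low) {
  strong <- mag >= high
  weak <- mag >= low
  if (!any(strong)) return(matrix(0L, nrow(mag), ncol(mag)))
  repeat {
    grown <- strong
    for (dr in -1:1) for (dc in -1:1) {
      if (dr || dc) grown <- grown | (shift_mat(strong, dr, dc) > 0)
    }
    grown <- grown & weak
    if (all(grown == strong)) break
    strong <- grown
  }
  strong * 1L
}

#' Flatten a binary orientation image to a feature vector
#'
#' Row-major flattening of the 32 x 16 binary edge map into a vector of
#' length 512.  The same fixed convention is used for training and test
#' images, so pixelwise comparisons remain aligned.
#'
#' @param img a binary matrix of shape `target_shape`.
#' @param target_shape expected `(rows, cols)`.
#' @return integer 0/1 vector of length `prod(target_shape)`.
#' @export
vectorize <- function(img, target_shape = c(32L, 16L)) {
  if (!is.matrix(img) || !all(dim(img) == target_shape)) {
    stop("expected a ", target_shape[1], "x", target_shape[2],
         " binary image")
  }
  v <- as.integer(t(img))
  if (!all(v %in% c(0L, 1L))) stop("orientation image must be binary")
  v
}

#' Full preprocessing chain: color photograph to binary orientation image
#'
#' Runs grayscale conversion, background segmentation, optional long-axis
#' alignment, bounding-box crop with resampling to the target shape
#' (optionally histogram-equalized), and binary edge extraction.
#'
#' @param img an H x W x 3 color array (\[0, 255\]) or a `gray_image`.
#' @param cfg a [preprocess_config()].
#' @return a binary orientation matrix of shape `cfg$target_shape`.
#' @export
preprocess_image <- function(img, cfg = preprocess_config()) {
  g <- to_grayscale(img)
  if (cfg$denoise_radius > 0) {
    px <- from_ebi(EBImage::medianFilter(as_ebi(g$pixels / 255),
                                         size = cfg$denoise_radius)) * 255
    g <- gray_image(px, g$mask)
  }
  g <- segment_background(g, cfg$background_threshold)
  if (cfg$do_align) {
    g <- suppressWarnings(align_long_axis(g))
  }
  g <- normalize_size(g, cfg$target_shape, equalize = cfg$do_hist_equalize)
  extract_orientation(g, cfg)
}
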