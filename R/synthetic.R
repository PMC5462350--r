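#' Parametric leaf shape
#'
#' A synthetic leaf is rendered from a radial polar profile: a base
#' outline (ellipse, slender "linear" blade, heart-shaped cordate, lobed,
#' or palmate) perturbed by sinusoidal lobes and margin serration, with a
#' midrib and lateral veins drawn darker than the blade.  The polar
#' parameterization gives an analytic handle on how far apart two classes
#' are, which the dataset generator exploits to control inter-class
#' separation.
#'
#' @param base one of `"ellipse"`, `"linear"`, `"cordate"`, `"lobed"`,
#'   `"palmate"`.
#' @param aspect_ratio length-to-width ratio of the blade, > 1 for an
#'   elongated leaf.
#' @param lobe_count number of marginal lobes (0 for entire margins).
#' @param lobe_depth relative lobe amplitude in \[0, 1).
#' @param margin_serration tooth amplitude of the fine margin serration
#'   (relative, >= 0).
#' @param vein_density relative density of lateral veins (0 = midrib
#'   only).
#' @return a list of class `leaf_shape_params`.
#' @export
leaf_shape_params <- function(base = "ellipse", aspect_ratio = 1.8,
                              lobe_count = 0L, lobe_depth = 0,
                              margin_serration = 0, vein_density = 1) {
  base <- match.arg(base, c("ellipse", "linear", "cordate", "lobed", "palmate"))
  if (aspect_ratio <= 0) stop("aspect_ratio must be positive")
  stopifnot(lobe_count >= 0, lobe_depth >= 0, lobe_depth < 1,
            margin_serration >= 0, vein_density >= 0)
  if (lobe_count == 0) lobe_depth <- 0
  structure(list(base = base, aspect_ratio = aspect_ratio,
                 lobe_count = as.integer(lobe_count), lobe_depth = lobe_depth,
                 margin_serration = margin_serration,
                 vein_density = vein_density),
            class = "leaf_shape_params")
}

#' Intra-class noise settings
#'
#' Emulates the variation seen across leaves of one species: each leaf is
#' photographed at a slightly different angle and distance (rotation and
#' scale jitter), under drifting illumination, occasionally damaged
#' (occlusion), and with sensor salt-and-pepper noise (pixel flips).
#' The `"medium"` preset is the generator default.
#'
#' @param rotation_jitter_deg half-range of the uniform rotation jitter,
#'   degrees.
#' @param scale_jitter half-range of the uniform relative scale jitter.
#' @param occlusion_prob probability that a leaf has a disk-shaped bite
#'   removed.
#' @param pixel_flip_prob per-pixel probability of flipping between
#'   foreground and background gray.
#' @param illumination_drift half-range of the uniform relative blade
#'   brightness drift.
#' @return a list of class `noise_params`.
#' @export
noise_params <- function(rotation_jitter_deg = 8, scale_jitter = 0.08,
                         occlusion_prob = 0, pixel_flip_prob = 0.002,
                         illumination_drift = 0.05) {
  stopifnot(rotation_jitter_deg >= 0, scale_jitter >= 0,
            occlusion_prob >= 0, occlusion_prob <= 1,
            pixel_flip_prob >= 0, pixel_flip_prob <= 1,
            illumination_drift >= 0)
  structure(list(rotation_jitter_deg = rotation_jitter_deg,
                 scale_jitter = scale_jitter,
                 occlusion_prob = occlusion_prob,
                 pixel_flip_prob = pixel_flip_prob,
                 illumination_drift = illumination_drift),
            class = "noise_params")
}

#' @rdname noise_params
#' @param preset `"none"`, `"low"`, `"medium"` or `"high"`.
#' @export
noise_preset <- function(preset = c("medium", "none", "low", "high")) {
  switch(match.arg(preset),
    none = noise_params(0, 0, 0, 0, 0),
    low = noise_params(3, 0.03, 0, 0.0005, 0.02),
    medium = noise_params(),
    high = noise_params(15, 0.15, 0.2, 0.01, 0.15))
}

# gray levels of the rendered scene; background stays strictly below the
# segmentation threshold of 30
.leaf_bg_gray <- 12
.leaf_blade_gray <- 140
.leaf_vein_frac <- 0.45
# channel multipliers (greenish) chosen so the luma recombination
# 0.2989 R + 0.5870 G + 0.1140 B returns the scene gray exactly
.leaf_rgb_mult <- c((1 - 1.4 * 0.5870) / (0.2989 + 0.1140), 1.4,
                    (1 - 1.4 * 0.5870) / (0.2989 + 0.1140))

#' Render synthetic leaves of one species
#'
#' @param params a [leaf_shape_params()].
#' @param n number of leaves to render.
#' @param noise a [noise_params()]; `noise_preset("none")` gives n
#'   byte-identical images.
#' @param seed RNG seed; the output is deterministic given
#'   (params, n, noise, seed).
#' @param dim image `(rows, cols)`.
#' @return list of `n` H x W x 3 color arrays with values in \[0, 255\].
#' @export
make_class <- function(params, n, noise = noise_params(), seed = 1,
                       dim = c(96L, 64L)) {
  stopifnot(inherits(params, "leaf_shape_params"), n >= 1)
  with_seed(seed, lapply(seq_len(n), function(i) {
    rot <- runif(1, -noise$rotation_jitter_deg, noise$rotation_jitter_deg)
    scl <- 1 + runif(1, -noise$scale_jitter, noise$scale_jitter)
    ill <- 1 + runif(1, -noise$illumination_drift, noise$illumination_drift)
    g <- render_leaf_gray(params, dim, rot_deg = rot, scale = scl,
                          illum = ill)
    if (noise$occlusion_prob > 0 && runif(1) < noise$occlusion_prob) {
      g <- apply_occlusion(g)
    }
    if (noise$pixel_flip_prob > 0) {
      flip <- matrix(runif(length(g)) < noise$pixel_flip_prob, nrow(g))
      g[flip] <- ifelse(g[flip] >= 30, .leaf_bg_gray, .leaf_blade_gray)
    }
    gray_to_color(g)
  }))
}

render_leaf_gray <- function(params, dim, rot_deg = 0, scale = 1,
                             illum = 1) {
  nr <- dim[1]; nc <- dim[2]
  cen <- c((nr + 1) / 2, (nc + 1) / 2)
  gr <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  dr <- gr$r - cen[1]; dc <- gr$c - cen[2]
  phi <- rot_deg * pi / 180
  # leaf-frame coordinates (axis vertical before rotation jitter)
  lr <- cos(phi) * dr + sin(phi) * dc
  lc <- -sin(phi) * dr + cos(phi) * dc
  rad <- sqrt(lr^2 + lc^2)
  theta <- atan2(lc, lr)
  rho <- radial_profile(params, theta)
  rmax <- 0.40 * nr * scale
  inside <- rad <= rmax * rho
  blade <- min(.leaf_blade_gray * illum, 180)
  g <- rep(.leaf_bg_gray, nr * nc)
  g[inside] <- blade
  # venation: midrib along the axis plus oblique lateral veins
  vein <- inside & abs(lc) < 0.9 & abs(lr) < rmax
  if (params$vein_density > 0) {
    spacing <- nr / (3 + 9 * params$vein_density)
    lat <- inside & ((lr + abs(lc) * 1.2) %% spacing) < 1.1 & rad > 2
    vein <- vein | lat
  }
  g[vein] <- blade * .leaf_vein_frac
  matrix(g, nr, nc)
}

radial_profile <- function(params, theta) {
  a <- params$aspect_ratio
  if (params$base == "linear") a <- a * 1.8
  rho <- 1 / sqrt(cos(theta)^2 + (a * sin(theta))^2)
  # natural tip/base taper: real leaves narrow toward the apex, which
  # gives every blade a well-defined orientation for long-axis alignment
  rho <- rho * (1 - 0.15 * cos(theta)) / 1.15
  if (params$base == "cordate") {
    rho <- rho * (1 - 0.4 * cos(theta)) / 1.4
  }
  k <- params$lobe_count; d <- params$lobe_depth
  if (params$base == "lobed" && k > 0) {
    rho <- rho * (1 + d * cos(k * theta)) / (1 + d)
  }
  if (params$base == "palmate" && k > 0) {
    rho <- rho * (1 + d * cos(k * theta + pi)) / (1 + d)
  }
  if (params$margin_serration > 0) {
    s <- params$margin_serration
    rho <- rho * (1 + s * cos(26 * theta)) / (1 + s)
  }
  pmax(rho, 1e-3)
}

apply_occlusion <- function(g) {
  nr <- nrow(g); nc <- ncol(g)
  idx <- which(g >= 30, arr.ind = TRUE)
  if (nrow(idx) == 0) return(g)
  p <- idx[sample.int(nrow(idx), 1), ]
  rad <- 0.08 * nr
  gr <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  hit <- (gr$r - p[1])^2 + (gr$c - p[2])^2 <= rad^2
  g[matrix(hit, nr, nc)] <- .leaf_bg_gray
  g
}

gray_to_color <- function(g) {
  arr <- array(0, c(nrow(g), ncol(g), 3))
  for (ch in 1:3) arr[, , ch] <- pmin(g * .leaf_rgb_mult[ch], 255)
  arr
}

#' Generate a labeled multi-species synthetic dataset
#'
#' Each class gets its own shape parameters.  At `separation = 1` the
#' classes sit at well-spread anchor shapes (distinct bases, aspect
#' ratios, lobe structure); at `separation = 0` every class collapses onto
#' one common parameter set, making the classes indistinguishable.
#' Intermediate values interpolate the numeric parameters linearly between
#' the common center and the class anchors.
#'
#' @param C number of classes (>= 2).
#' @param per_class images per class.
#' @param separation inter-class shape separation in \[0, 1\].
#' @param noise a [noise_params()] applied within every class.
#' @param seed RNG seed; the dataset is a deterministic function of all
#'   arguments.
#' @param dir if non-`NULL`, write the images as PNG under
#'   `dir/class_XX/leaf_YY.png` plus a `manifest.csv`, and return the
#'   manifest.
#' @param dim image `(rows, cols)`.
#' @return if `dir` is `NULL`, a list with `images` (list of color
#'   arrays), `labels` (character), `params` (per-class
#'   [leaf_shape_params()]); otherwise the manifest data.frame.
#' @export
make_dataset <- function(C, per_class, separation = 0.5,
                         noise = noise_params(), seed = 1, dir = NULL,
                         dim = c(96L, 64L)) {
  stopifnot(C >= 2, per_class >= 1, separation >= 0, separation <= 1)
  params <- lapply(seq_len(C), function(i) class_anchor(i, separation))
  labels <- sprintf("class_%02d", seq_len(C))
  images <- list()
  lab_out <- character(0)
  for (i in seq_len(C)) {
    imgs <- make_class(params[[i]], per_class, noise,
                       seed = (seed %% 2000000L) * 1000L + i, dim = dim)
    images <- c(images, imgs)
    lab_out <- c(lab_out, rep(labels[i], per_class))
  }
  if (is.null(dir)) {
    return(list(images = images, labels = lab_out, params = params))
  }
  manifest <- data.frame(sample_id = character(0), class = character(0),
                         path = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(images)) {
    cl <- lab_out[i]
    cdir <- file.path(dir, cl)
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    j <- sum(lab_out[seq_len(i)] == cl)
    path <- file.path(cdir, sprintf("leaf_%02d.png", j))
    write_color_png(images[[i]], path)
    manifest <- rbind(manifest, data.frame(
      sample_id = sprintf("%s/leaf_%02d", cl, j), class = cl, path = path,
      stringsAsFactors = FALSE))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

# anchor shapes: distinct margin/venation structure per class.  Because
# size normalization stretches every leaf to the same 32x16 frame, the
# aspect ratio carries little class information afterwards; anchors are
# therefore separated in the features that survive normalization — base
# outline, lobe count and depth, margin serration, vein density
class_anchor <- function(i, separation) {
  anchors <- list(
    list(base = "ellipse", aspect = 1.5, lobes = 0, depth = 0,    serr = 0.00, veins = 1.5),
    list(base = "lobed",   aspect = 1.4, lobes = 4, depth = 0.45, serr = 0.00, veins = 0.8),
    list(base = "cordate", aspect = 1.2, lobes = 0, depth = 0,    serr = 0.07, veins = 1.0),
    list(base = "linear",  aspect = 2.4, lobes = 0, depth = 0,    serr = 0.14, veins = 0.3),
    list(base = "palmate", aspect = 1.3, lobes = 5, depth = 0.60, serr = 0.00, veins = 1.2),
    list(base = "lobed",   aspect = 1.9, lobes = 6, depth = 0.30, serr = 0.00, veins = 2.0),
    list(base = "ellipse", aspect = 1.7, lobes = 0, depth = 0,    serr = 0.10, veins = 0.5),
    list(base = "cordate", aspect = 1.5, lobes = 0, depth = 0,    serr = 0.00, veins = 1.8)
  )
  center <- c(aspect = 1.6, lobes = 0, depth = 0, serr = 0.02, veins = 1.0)
  a0 <- anchors[[(i - 1) %% length(anchors) + 1]]
  a <- c(aspect = a0$aspect, lobes = a0$lobes, depth = a0$depth,
         serr = a0$serr, veins = a0$veins)
  # replicate anchors beyond the table by shifting the vein density
  a["veins"] <- a["veins"] + 0.4 * ((i - 1) %/% length(anchors))
  p <- center + separation * (a - center)
  base <- if (separation == 0) "ellipse" else a0$base
  lobes <- if (separation == 0) 0L else as.integer(a[["lobes"]])
  leaf_shape_params(base = base, aspect_ratio = p[["aspect"]],
                    lobe_count = lobes,
                    lobe_depth = if (lobes > 0) p[["depth"]] else 0,
                    margin_serration = max(p[["serr"]], 0),
                    vein_density = max(p[["veins"]], 0))
}

write_color_png <- function(arr, path) {
  img <- EBImage::Image(aperm(arr, c(2, 1, 3)) / 255, colormode = "Color")
  EBImage::writeImage(img, path, type = "png")
}

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}
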