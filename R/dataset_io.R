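#' Read a leaf photograph from disk
#'
#' Reads PNG/JPEG via EBImage and returns an H x W x 3 array with channel
#' values on the \[0, 255\] scale (grayscale files are replicated across
#' channels; alpha channels are dropped).
#'
#' @param path image file path.
#' @return an H x W x 3 numeric array.
#' @export
read_leaf_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2L) {
    g <- t(dat) * 255
    return(array(rep(g, 3), c(nrow(g), ncol(g), 3)))
  }
  nch <- dim(dat)[3]
  if (nch < 3L) {
    g <- t(dat[, , 1]) * 255
    return(array(rep(g, 3), c(nrow(g), ncol(g), 3)))
  }
  arr <- aperm(dat[, , 1:3, drop = FALSE], c(2, 1, 3)) * 255
  arr
}

#' Scan a directory-per-class image dataset
#'
#' Expects `root/<class_name>/<image>.png|jpg|jpeg`.  Classes and files
#' are ordered by a locale-independent (C-collation) sort so the manifest
#' is identical across platforms.  Non-image files are skipped with a
#' warning; empty class directories are skipped with a warning.
#'
#' @param root dataset root directory.
#' @return a data.frame of class `dataset_manifest` with columns
#'   `sample_id`, `path`, `class`, plus attributes `C` (class count) and
#'   `n_per_class` (named counts).
#' @export
scan_dataset <- function(root) {
  if (!dir.exists(root)) stop("no such dataset directory: ", root)
  dirs <- list.dirs(root, recursive = FALSE, full.names = TRUE)
  dirs <- dirs[c_sort_order(basename(dirs))]
  rows <- list()
  for (d in dirs) {
    files <- list.files(d, full.names = TRUE)
    is_img <- grepl("\\.(png|jpg|jpeg)$", files, ignore.case = TRUE)
    if (any(!is_img)) {
      warning("skipping ", sum(!is_img), " non-image file(s) in ",
              basename(d))
    }
    files <- files[is_img]
    if (length(files) == 0L) {
      warning("skipping empty class directory: ", basename(d))
      next
    }
    files <- files[c_sort_order(basename(files))]
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = paste0(basename(d), "/",
                         tools::file_path_sans_ext(basename(files))),
      path = files, class = basename(d), stringsAsFactors = FALSE)
  }
  if (length(rows) < 2L) stop("need at least 2 usable class directories")
  man <- do.call(rbind, rows)
  rownames(man) <- NULL
  attr(man, "C") <- length(rows)
  attr(man, "n_per_class") <- table(man$class)
  class(man) <- c("dataset_manifest", "data.frame")
  man
}

c_sort_order <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)))
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  order(x)
}

#' Hash of a preprocessing configuration
#'
#' Used to key the orientation-image cache: a cache entry is valid only
#' for the exact configuration that produced it.
#'
#' @param cfg a [preprocess_config()].
#' @return md5 hex string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Preprocess a whole dataset, with an on-disk orientation cache
#'
#' Runs [preprocess_image()] on every manifest entry.  When `cache_dir`
#' is given, each binary orientation image is stored as a 1-bit-content
#' PNG next to a JSON sidecar recording the configuration hash; a rerun
#' with the same configuration loads from the cache instead of
#' recomputing, and a changed configuration invalidates it wholesale.
#'
#' @param manifest a `dataset_manifest` from [scan_dataset()].
#' @param cfg a [preprocess_config()].
#' @param cache_dir optional cache directory.
#' @return list of class `orientation_cache`: `images` (named list of
#'   32x16 binary matrices, keyed by `sample_id`), `config_hash`,
#'   `recomputed` (count), `failures` (named character of per-sample
#'   error messages).
#' @export
preprocess_dataset <- function(manifest, cfg = preprocess_config(),
                               cache_dir = NULL) {
  h <- config_hash(cfg)
  images <- list()
  failures <- character(0)
  recomputed <- 0L
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    cpath <- if (!is.null(cache_dir)) {
      file.path(cache_dir, paste0(gsub("/", "__", sid), ".png"))
    }
    cached <- NULL
    if (!is.null(cpath) && file.exists(cpath) &&
        file.exists(paste0(cpath, ".json"))) {
      side <- jsonlite::fromJSON(paste0(cpath, ".json"))
      if (identical(side$config_hash, as.character(h))) {
        cached <- read_orientation_png(cpath)
      }
    }
    if (is.null(cached)) {
      res <- tryCatch(
        preprocess_image(read_leaf_image(manifest$path[i]), cfg),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[sid] <- conditionMessage(res)
        next
      }
      recomputed <- recomputed + 1L
      cached <- res
      if (!is.null(cpath)) {
        dir.create(dirname(cpath), recursive = TRUE, showWarnings = FALSE)
        EBImage::writeImage(as_ebi(cached), cpath, type = "png")
        writeLines(jsonlite::toJSON(list(config_hash = as.character(h),
                                         sample_id = sid),
                                    auto_unbox = TRUE),
                   paste0(cpath, ".json"))
      }
    }
    images[[sid]] <- cached
  }
  if (length(images) == 0L) {
    stop("preprocessing failed for every sample; first error: ",
         failures[1])
  }
  structure(list(images = images, config_hash = as.character(h),
                 recomputed = recomputed, failures = failures),
            class = "orientation_cache")
}

read_orientation_png <- function(path) {
  m <- from_ebi(EBImage::readImage(path))
  (m >= 0.5) * 1L
}

#' Feature matrix and labels from an orientation cache
#'
#' @param cache an `orientation_cache`.
#' @param manifest the `dataset_manifest` it was built from.
#' @return list with `x` (D x n binary matrix) and `labels`.
#' @export
cache_features <- function(cache, manifest) {
  sids <- names(cache$images)
  x <- vapply(sids, function(s) vectorize(cache$images[[s]],
                                          dim(cache$images[[s]])),
              integer(length(cache$images[[1]])))
  labels <- manifest$class[match(sids, manifest$sample_id)]
  list(x = x, labels = labels, sample_ids = sids)
}
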