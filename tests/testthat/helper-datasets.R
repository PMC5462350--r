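# Small synthetic datasets shared across test files, generated once per
# test run and cached in the session.

.dataset_cache <- new.env(parent = emptyenv())

cached_features <- function(C, per_class, separation, preset, seed) {
  key <- paste(C, per_class, separation, preset, seed, sep = "_")
  if (is.null(.dataset_cache[[key]])) {
    ds <- make_dataset(C, per_class, separation,
                       noise = noise_preset(preset), seed = seed)
    cfg <- preprocess_config()
    X <- vapply(ds$images,
                function(im) vectorize(preprocess_image(im, cfg)),
                integer(512))
    .dataset_cache[[key]] <- list(x = X, labels = ds$labels,
                                  params = ds$params, images = ds$images)
  }
  .dataset_cache[[key]]
}
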