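#' Full descriptor extraction for one fundus image
#'
#' Convenience chain: [preprocess_fundus()] -> [detect_keypoints()] ->
#' [describe_keypoints()].
#'
#' @param img a [fundus_image()] (or a path, read with [read_fundus()]).
#' @param config a [bow_config()].
#' @return descriptor matrix (rows = keypoints, 128 columns).
#' @export
fundus_descriptors <- function(img, config = bow_config()) {
  if (is.character(img)) img <- read_fundus(img)
  pp <- preprocess_fundus(img)
  kp <- detect_keypoints(pp$gray, pp$mask, config)
  describe_keypoints(pp$gray, kp, config)
}

#' Build a visual-word codebook by k-means over pooled descriptors
#'
#' Following standard bag-of-visual-words practice, descriptors are pooled
#' from a seeded random half (`ceiling(n/2)`) of the training images and
#' clustered with k-means; each centroid is one visual word. The default
#' vocabulary size is `k = 100`, which keeps the image view comparable in
#' dimension to the other modalities. A fixed seed gives a bit-identical
#' codebook.
#'
#' @param descriptor_sets named list of per-image descriptor matrices (as
#'   from [fundus_descriptors()]), or a list of [fundus_image()] objects /
#'   paths, in which case descriptors are extracted first.
#' @param k vocabulary size (default 100).
#' @param seed RNG seed governing the image half-split, any descriptor
#'   subsampling and the k-means initialization.
#' @param config a [bow_config()].
#' @return object of class `"codebook"`: `centroids` (k x 128), `k`,
#'   `build_seed`, `image_ids`.
#' @export
build_codebook <- function(descriptor_sets, k = 100, seed = 1,
                           config = bow_config()) {
  if (length(descriptor_sets) < 2L)
    pm_stop("need at least two training images", "too_few_images")
  if (!all(vapply(descriptor_sets, is.matrix, logical(1))))
    descriptor_sets <- lapply(descriptor_sets, fundus_descriptors, config = config)
  ids <- names(descriptor_sets) %||% as.character(seq_along(descriptor_sets))
  n <- length(descriptor_sets)
  with_seed(seed, {
    half <- sort(sample.int(n, ceiling(n / 2)))
    pool <- do.call(rbind, descriptor_sets[half])
    if (is.null(pool) || nrow(pool) < k)
      pm_stop(sprintf("only %d descriptors pooled for k = %d; use a smaller k",
                      if (is.null(pool)) 0L else nrow(pool), k), "too_few_descriptors")
    if (nrow(pool) > config$max_pool)
      pool <- pool[sort(sample.int(nrow(pool), config$max_pool)), , drop = FALSE]
    pool <- matrix(as.numeric(pool), nrow(pool), ncol(pool))
    centers <- unique(pool)
    if (nrow(centers) < k)
      pm_stop(sprintf("only %d distinct descriptors for k = %d; use a smaller k",
                      nrow(centers), k), "too_few_descriptors")
    init <- centers[sample.int(nrow(centers), k), , drop = FALSE]
    km <- suppressWarnings(stats::kmeans(pool, centers = init, iter.max = 100,
                                         algorithm = "Lloyd"))
    structure(list(centroids = km$centers, k = k, build_seed = seed,
                   image_ids = ids[half]),
              class = "codebook")
  })
}

#' @export
print.codebook <- function(x, ...) {
  cat("Visual codebook: k =", x$k, "words, built from", length(x$image_ids),
      "images (seed", x$build_seed, ")\n")
  invisible(x)
}

#' Encode descriptors as a bag-of-visual-words histogram
#'
#' Each descriptor is assigned to its nearest centroid (Euclidean distance,
#' ties to the lowest centroid index); the occurrence-count histogram is then
#' normalized (L2 by default, L1 by configuration). An image with zero
#' descriptors yields an all-zero vector with a warning rather than an error:
#' a screening pipeline must not abort on one structureless image.
#'
#' @param descriptors keypoint descriptor matrix (rows in \[0, 255\]).
#' @param codebook a [build_codebook()] result.
#' @param norm `"l2"` (default) or `"l1"`.
#' @return object of class `"bow_vector"`: `histogram` (length k, normalized),
#'   `counts` (raw integer counts), `raw_count` (total descriptors).
#' @export
encode_bow <- function(descriptors, codebook, norm = c("l2", "l1")) {
  norm <- match.arg(norm)
  k <- codebook$k
  if (is.null(descriptors) || nrow(descriptors) == 0L) {
    warning("image yielded zero descriptors; emitting an all-zero BOW vector")
    return(structure(list(histogram = numeric(k), counts = integer(k),
                          raw_count = 0L, norm = norm), class = "bow_vector"))
  }
  X <- matrix(as.numeric(descriptors), nrow(descriptors), ncol(descriptors))
  Cm <- codebook$centroids
  d2 <- outer(rowSums(X^2), rowSums(Cm^2), "+") - 2 * tcrossprod(X, Cm)
  assign <- max.col(-d2, ties.method = "first")
  counts <- tabulate(assign, nbins = k)
  h <- as.numeric(counts)
  denom <- if (norm == "l2") sqrt(sum(h^2)) else sum(h)
  if (denom > 0) h <- h / denom
  structure(list(histogram = h, counts = as.integer(counts),
                 raw_count = nrow(X), norm = norm), class = "bow_vector")
}

#' @export
print.bow_vector <- function(x, ...) {
  cat("BOW vector: k =", length(x$histogram), ",", x$raw_count,
      "descriptors,", x$norm, "normalized\n")
  invisible(x)
}

#' Extract the BOW feature matrix for a set of images
#'
#' @param images named list of [fundus_image()] objects or a character vector
#'   of paths.
#' @param codebook a [build_codebook()] result.
#' @param config a [bow_config()].
#' @return a [feature_view()] (`source_id = "I"`), one normalized histogram
#'   row per image; rownames are subject ids.
#' @export
extract_bow_features <- function(images, codebook, config = bow_config()) {
  if (is.character(images)) {
    paths <- images
    images <- lapply(paths, read_fundus)
    names(images) <- vapply(images, function(im) im$subject_id, "")
  }
  ids <- names(images) %||% as.character(seq_along(images))
  rows <- matrix(0, length(images), codebook$k, dimnames = list(ids, NULL))
  for (i in seq_along(images)) {
    d <- fundus_descriptors(images[[i]], config)
    bv <- if (nrow(d) == 0L)
      suppressWarnings(encode_bow(d, codebook, config$norm))
    else encode_bow(d, codebook, config$norm)
    rows[i, ] <- bv$histogram
  }
  feature_view(rows, source_id = "I")
}

#' Persist a codebook as a flat text matrix with a metadata header
#'
#' @param codebook a `"codebook"`.
#' @param path output path.
#' @export
write_codebook <- function(codebook, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# pmfuse codebook",
               paste0("# k: ", codebook$k),
               paste0("# seed: ", codebook$build_seed),
               paste0("# images: ", paste(codebook$image_ids, collapse = ","))), con)
  utils::write.table(format(codebook$centroids, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a codebook written by [write_codebook()]
#'
#' @param path codebook path.
#' @return a `"codebook"`.
#' @export
read_codebook <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get <- function(key) sub(paste0("^# ", key, ": "), "", hdr[grepl(paste0("^# ", key, ":"), hdr)])
  centroids <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  structure(list(centroids = centroids, k = as.integer(get("k")),
                 build_seed = as.integer(get("seed")),
                 image_ids = strsplit(get("images"), ",")[[1]]),
            class = "codebook")
}
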