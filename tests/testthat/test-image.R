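# Synthetic rasters with known geometry exercise the detector/descriptor
# stack without any stored image fixtures.

blank_fundus <- function(value = 0.5, h = 256, w = 256) {
  fundus_image(array(value, c(h, w, 3)))
}

test_that("preprocessing resizes to height 256, keeps aspect, extracts green, masks at 0.95 radius", {
  img <- fundus_image(array(runif(512 * 768 * 3), c(512, 768, 3)))
  pp <- preprocess_fundus(img)
  expect_equal(dim(pp$gray), c(256, 384))

  img2 <- blank_fundus()
  pp2 <- preprocess_fundus(img2)
  expect_equal(dim(pp2$gray), c(256, 256))
  expect_equal(pp2$radius, 121.6)
  # mask is the 0.95-radius disc
  expect_true(pp2$mask[128, 128])
  expect_false(pp2$mask[128, 252])
  expect_false(pp2$mask[3, 3])

  px <- array(0, c(64, 64, 3)); px[, , 1] <- 1  # red-only image
  pp3 <- preprocess_fundus(fundus_image(px))
  expect_true(all(pp3$gray == 0))
})

test_that("a structureless raster yields no keypoints and degenerate images do not error", {
  pp <- preprocess_fundus(blank_fundus(0.4))
  kp <- detect_keypoints(pp$gray, pp$mask)
  expect_equal(nrow(kp), 0)
  d <- describe_keypoints(pp$gray, kp)
  expect_equal(nrow(d), 0)
})

test_that("Harris-Laplace finds corners of a high-contrast square", {
  g <- matrix(0.1, 256, 256)
  g[97:161, 97:161] <- 0.9
  kp <- detect_keypoints(g, NULL)
  har <- kp[kp$detector == "HAR", ]
  expect_gt(nrow(har), 0)
  corners <- rbind(c(97, 97), c(97, 161), c(161, 97), c(161, 161))
  dist_to_corner <- vapply(seq_len(nrow(har)), function(i)
    min(sqrt((har$x[i] - corners[, 2])^2 + (har$y[i] - corners[, 1])^2)),
    numeric(1))
  expect_true(any(dist_to_corner <= 3))
})

test_that("Hessian-Laplace finds the centre of a Gaussian blob", {
  yy <- matrix(1:256, 256, 256); xx <- t(yy)
  g <- 0.1 + 0.8 * exp(-((xx - 140)^2 + (yy - 120)^2) / (2 * 6^2))
  kp <- detect_keypoints(g, NULL)
  hes <- kp[kp$detector == "HES", ]
  expect_gt(nrow(hes), 0)
  d <- sqrt((hes$x - 140)^2 + (hes$y - 120)^2)
  expect_true(any(d <= 3))
})

test_that("all emitted keypoints respect the circular mask", {
  set.seed(71)
  img <- render_fundus(1, contrast = 0.8)
  pp <- preprocess_fundus(img)
  kp <- detect_keypoints(pp$gray, pp$mask)
  expect_gt(nrow(kp), 0)
  expect_true(all(pp$mask[cbind(kp$y, kp$x)]))
  ctr <- pp$center
  r <- sqrt((kp$y - ctr["y"])^2 + (kp$x - ctr["x"])^2)
  expect_true(all(r <= pp$radius))
})

test_that("a typical rendered fundus yields a keypoint count in the designed band", {
  set.seed(72)
  img <- render_fundus(1, contrast = 0.8)
  pp <- preprocess_fundus(img)
  kp <- detect_keypoints(pp$gray, pp$mask)
  expect_gte(nrow(kp), 100)
  expect_lte(nrow(kp), 1000)
})

test_that("descriptors are 128-dimensional, bounded, deterministic and brightness invariant", {
  set.seed(73)
  img <- render_fundus(1, contrast = 0.8)
  pp <- preprocess_fundus(img)
  # keep intensities in [0, 0.8] so a +0.15 shift cannot clip
  g <- pp$gray * 0.8
  kp <- detect_keypoints(g, pp$mask)
  d1 <- suppressMessages(describe_keypoints(g, kp))
  expect_equal(ncol(d1), 128)
  expect_true(all(d1 >= 0 & d1 <= 255))
  d2 <- suppressMessages(describe_keypoints(g, kp))
  expect_identical(d1[, ], d2[, ])
  d3 <- suppressMessages(describe_keypoints(g + 0.15, kp))
  expect_identical(d1[, ], d3[, ])
})

test_that("descriptors are stable under a 90-degree rotation", {
  set.seed(74)
  img <- render_fundus(1, contrast = 0.8)
  pp <- preprocess_fundus(img)
  g <- pp$gray[1:256, 1:256]
  kp <- detect_keypoints(g, NULL)
  d1 <- suppressMessages(describe_keypoints(g, kp))
  k1 <- attr(d1, "keypoints")
  gr <- t(g)[256:1, ]                       # rotate raster by 90 degrees
  kp2 <- kp; kp2$x <- kp$y; kp2$y <- 256 + 1 - kp$x
  d2 <- suppressMessages(describe_keypoints(gr, kp2))
  k2 <- attr(d2, "keypoints")
  id1 <- paste(k1$x, k1$y, k1$scale, k1$detector)
  id2 <- paste(256 + 1 - k2$y, k2$x, k2$scale, k2$detector)
  common <- intersect(id1, id2)
  expect_gt(length(common), 20)
  i1 <- match(common, id1); i2 <- match(common, id2)
  rel <- sqrt(rowSums((d1[i1, , drop = FALSE] - d2[i2, , drop = FALSE])^2)) /
    pmax(sqrt(rowSums(d1[i1, , drop = FALSE]^2)), 1)
  expect_gt(mean(rel <= 0.15), 0.9)
})

test_that("codebook construction is seeded, deterministic and validates its inputs", {
  set.seed(75)
  # two tight descriptor clusters at known centres
  c1 <- matrix(rep(c(rep(200, 64), rep(10, 64)), 40), 40, 128, byrow = TRUE)
  c2 <- matrix(rep(c(rep(10, 64), rep(200, 64)), 40), 40, 128, byrow = TRUE)
  jitter1 <- c1 + matrix(rnorm(40 * 128, 0, 0.3), 40, 128)
  jitter2 <- c2 + matrix(rnorm(40 * 128, 0, 0.3), 40, 128)
  sets <- list(img1 = jitter1[1:20, ], img2 = jitter2[1:20, ],
               img3 = jitter1[21:40, ], img4 = jitter2[21:40, ])
  cb <- build_codebook(sets, k = 2, seed = 5)
  expect_equal(cb$k, 2)
  expect_equal(cb$build_seed, 5)
  dist_to_true <- function(centroid) min(
    sqrt(mean((centroid - c1[1, ])^2)), sqrt(mean((centroid - c2[1, ])^2)))
  expect_lt(dist_to_true(cb$centroids[1, ]), 1.0)
  expect_lt(dist_to_true(cb$centroids[2, ]), 1.0)
  cb2 <- build_codebook(sets, k = 2, seed = 5)
  expect_identical(cb$centroids, cb2$centroids)
  expect_error(build_codebook(sets, k = 1000, seed = 5),
               class = "pmfuse_error_too_few_descriptors")
})

test_that("BOW encoding conserves counts, breaks ties low, and matches brute-force NN", {
  set.seed(76)
  cb <- structure(list(centroids = matrix(runif(3 * 128, 0, 255), 3, 128),
                       k = 3, build_seed = 1, image_ids = "x"),
                  class = "codebook")
  desc <- matrix(sample(0:255, 7 * 128, replace = TRUE), 7, 128)
  bv <- encode_bow(desc, cb)
  expect_equal(sum(bv$counts), 7)
  expect_equal(bv$raw_count, 7)
  expect_equal(sqrt(sum(bv$histogram^2)), 1, tolerance = 1e-12)

  big <- matrix(sample(0:255, 20 * 128, replace = TRUE), 20, 128)
  bvb <- encode_bow(big, cb)
  brute <- apply(big, 1, function(r) {
    d <- apply(cb$centroids, 1, function(ct) sum((r - ct)^2))
    which(d == min(d))[1]                 # lowest index on ties
  })
  expect_equal(bvb$counts, tabulate(brute, 3))

  # exact tie between duplicated centroids -> lowest index wins
  cbt <- structure(list(centroids = rbind(cb$centroids[1, ], cb$centroids[1, ]),
                        k = 2, build_seed = 1, image_ids = "x"),
                   class = "codebook")
  bvt <- encode_bow(desc, cbt)
  expect_equal(bvt$counts[2], 0L)

  expect_warning(bv0 <- encode_bow(matrix(integer(0), 0, 128), cb), "zero")
  expect_equal(bv0$raw_count, 0L)
  expect_true(all(bv0$histogram == 0))
  l1 <- encode_bow(desc, cb, norm = "l1")
  expect_equal(sum(l1$histogram), 1, tolerance = 1e-12)
})

test_that("count conservation holds end to end on rendered images", {
  set.seed(77)
  for (lab in c(-1, 1)) {
    img <- render_fundus(lab, contrast = 0.8)
    d <- fundus_descriptors(img)
    cb <- structure(list(centroids = matrix(runif(5 * 128, 0, 255), 5, 128),
                         k = 5, build_seed = 1, image_ids = "x"),
                    class = "codebook")
    bv <- encode_bow(d, cb)
    expect_equal(sum(bv$counts), nrow(d))
  }
})

test_that("codebooks round-trip through the flat text format", {
  cb <- structure(list(centroids = matrix(round(runif(4 * 128, 0, 255), 6), 4, 128),
                       k = 4, build_seed = 9, image_ids = c("a", "b")),
                  class = "codebook")
  path <- withr::local_tempfile(fileext = ".txt")
  write_codebook(cb, path)
  cb2 <- read_codebook(path)
  expect_equal(cb2$k, 4)
  expect_equal(cb2$build_seed, 9)
  expect_equal(cb2$image_ids, c("a", "b"))
  expect_equal(cb2$centroids, cb$centroids, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("fundus images round-trip through PNG", {
  set.seed(78)
  img <- render_fundus(1, contrast = 0.5, size = 128)
  path <- withr::local_tempfile(fileext = ".png")
  write_fundus(img, path)
  back <- read_fundus(path)
  expect_equal(dim(back$pixels), c(128, 128, 3))
  expect_lt(max(abs(back$pixels - img$pixels)), 1 / 255)
  pp <- preprocess_fundus(back)
  expect_equal(nrow(pp$gray), 256)
})
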