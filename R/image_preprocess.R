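#' Preprocess a fundus image for local feature extraction
#'
#' Resizes the image to a height of 256 pixels keeping the aspect ratio
#' (bilinear interpolation), extracts the green channel -- the channel in
#' which retinal structure is best differentiated -- and builds the circular
#' analysis mask: the disc of radius `0.95 * min(height, width) / 2` centered
#' on the raster, which excludes the dark rim at the camera field-of-view
#' boundary. All-constant images are processed normally and simply yield no
#' keypoints downstream.
#'
#' @param img a [fundus_image()].
#' @param target_height output height in pixels (default 256).
#' @return list with `gray` (H x W matrix in \[0, 1\]), `mask` (logical
#'   matrix), `radius` and `center`.
#' @export
preprocess_fundus <- function(img, target_height = 256) {
  stopifnot(inherits(img, "fundus_image"))
  green <- img$pixels[, , 2]
  H0 <- nrow(green); W0 <- ncol(green)
  H <- as.integer(target_height)
  W <- as.integer(round(W0 * H / H0))
  gray <- resize_bilinear(green, H, W)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r <- 0.95 * min(H, W) / 2
  dy <- (seq_len(H) - cy)^2
  dx <- (seq_len(W) - cx)^2
  mask <- outer(dy, dx, "+") <= r^2
  list(gray = gray, mask = mask, radius = r, center = c(y = cy, x = cx))
}

# Bilinear resize of a single-channel matrix to H x W (pixel-center mapping).
resize_bilinear <- function(m, H, W) {
  H0 <- nrow(m); W0 <- ncol(m)
  if (H == H0 && W == W0) return(m)
  yi <- pmin(pmax((seq_len(H) - 0.5) * H0 / H + 0.5, 1), H0)
  xi <- pmin(pmax((seq_len(W) - 0.5) * W0 / W + 0.5, 1), W0)
  y0 <- pmin(floor(yi), H0 - 1L); fy <- yi - y0
  x0 <- pmin(floor(xi), W0 - 1L); fx <- xi - x0
  a <- m[y0, x0, drop = FALSE]; b <- m[y0 + 1, x0, drop = FALSE]
  c2 <- m[y0, x0 + 1, drop = FALSE]; d <- m[y0 + 1, x0 + 1, drop = FALSE]
  wy <- matrix(fy, H, W); wx <- matrix(fx, H, W, byrow = TRUE)
  (1 - wy) * (1 - wx) * a + wy * (1 - wx) * b + (1 - wy) * wx * c2 + wy * wx * d
}

# --- Gaussian filtering via banded convolution matrices -------------------

.blur_cache <- new.env(parent = emptyenv())

gaussian_band_matrix <- function(n, sigma) {
  key <- paste0(n, "_", format(sigma, digits = 10))
  got <- .blur_cache[[key]]
  if (!is.null(got)) return(got)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w <- w / sum(w)
  A <- matrix(0, n, n)
  idx <- seq_len(n)
  for (t in -r:r) {
    j <- idx + t
    j <- ifelse(j < 1, 2 - j, j)        # mirror boundary
    j <- ifelse(j > n, 2 * n - j, j)
    j <- pmin(pmax(j, 1L), n)
    # within one offset the (row, col) pairs are unique, so += is safe
    A[cbind(idx, j)] <- A[cbind(idx, j)] + w[t + r + 1]
  }
  .blur_cache[[key]] <- A
  A
}

# Separable Gaussian blur with mirrored boundaries; band matrices are cached
# per (dimension, sigma) since a whole cohort shares one raster geometry.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  Ar <- gaussian_band_matrix(nrow(m), sigma)
  Ac <- gaussian_band_matrix(ncol(m), sigma)
  Ar %*% m %*% t(Ac)
}

# Central-difference gradients; x runs along columns, y along rows.
image_gradients <- function(m) {
  H <- nrow(m); W <- ncol(m)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gx[, 2:(W - 1)] <- (m[, 3:W] - m[, 1:(W - 2)]) / 2
  gy[2:(H - 1), ] <- (m[3:H, ] - m[1:(H - 2), ]) / 2
  list(gx = gx, gy = gy)
}
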