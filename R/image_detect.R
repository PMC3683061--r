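#' Detector and bag-of-visual-words configuration
#'
#' Tunable parameters of the local-feature pipeline. Scale space is a
#' 5-level pyramid with sigma doubling from `sigma0`; the Harris corner
#' measure uses `harris_k = 0.04`; response thresholds were chosen so a
#' typical synthetic fundus rendering yields on the order of 100-1000
#' keypoints.
#'
#' @param sigma0 base scale of the pyramid (pixels).
#' @param n_levels number of pyramid levels (sigma doubles per level).
#' @param harris_k Harris corner-measure trace coefficient.
#' @param harris_thresh threshold on the scale-normalized Harris response.
#' @param hessian_thresh threshold on the scale-normalized determinant of
#'   Hessian.
#' @param deriv_ratio derivative scale as a fraction of the integration scale.
#' @param k codebook size (number of visual words).
#' @param norm BOW normalization, `"l2"` (default) or `"l1"`.
#' @param max_pool maximum number of descriptors pooled for codebook k-means
#'   (a seeded subsample is taken above this).
#' @return list of class `"bow_config"`.
#' @export
bow_config <- function(sigma0 = 1.6, n_levels = 5, harris_k = 0.04,
                       harris_thresh = 1e-7, hessian_thresh = 2e-5,
                       deriv_ratio = 0.7, k = 100, norm = c("l2", "l1"),
                       max_pool = 25000) {
  norm <- match.arg(norm)
  structure(list(sigma0 = sigma0, n_levels = n_levels, harris_k = harris_k,
                 harris_thresh = harris_thresh, hessian_thresh = hessian_thresh,
                 deriv_ratio = deriv_ratio, k = k, norm = norm,
                 max_pool = max_pool),
            class = "bow_config")
}

# 3x3 neighbourhood maximum (excluding the centre), -Inf at borders handled
# by padding with -Inf.
neighbour_max <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  out <- matrix(-Inf, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- pmax(out, pad[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)])
  }
  out
}

#' Detect Harris-Laplace and Hessian-Laplace keypoints
#'
#' Corner features come from the scale-adapted Harris measure
#' `det(M) - k tr(M)^2` of the second-moment matrix; blob features from the
#' scale-normalized determinant of the Hessian. Candidates are 3x3 spatial
#' maxima above threshold at each pyramid level; the characteristic scale is
#' confirmed by requiring the absolute scale-normalized Laplacian at the
#' point to peak across neighbouring levels. Detections outside the circular
#' mask are discarded. The procedure is a pure function of the raster.
#'
#' @param gray preprocessed single-channel raster in \[0, 1\].
#' @param mask logical matrix from [preprocess_fundus()] (`NULL` keeps all).
#' @param config a [bow_config()].
#' @return data.frame with `x`, `y` (pixel coordinates, x along columns),
#'   `scale`, `detector` (`"HAR"`/`"HES"`) and `response`; zero rows when the
#'   image has no structure.
#' @export
detect_keypoints <- function(gray, mask = NULL, config = bow_config()) {
  H <- nrow(gray); W <- ncol(gray)
  sigmas <- config$sigma0 * 2^(seq_len(config$n_levels) - 1)
  nl <- length(sigmas)
  har <- vector("list", nl); hes <- vector("list", nl); logs <- vector("list", nl)
  for (k in seq_len(nl)) {
    s <- sigmas[k]
    sd <- config$deriv_ratio * s
    L <- gaussian_blur(gray, sd)
    g <- image_gradients(L)
    gx <- g$gx * sd; gy <- g$gy * sd       # scale-normalized first derivatives
    A <- gaussian_blur(gx * gx, s)
    B <- gaussian_blur(gx * gy, s)
    C2 <- gaussian_blur(gy * gy, s)
    har[[k]] <- (A * C2 - B * B) - config$harris_k * (A + C2)^2
    Ls <- gaussian_blur(gray, s)
    Lx <- image_gradients(Ls)
    Lxx <- image_gradients(Lx$gx)$gx
    Lyy <- image_gradients(Lx$gy)$gy
    Lxy <- image_gradients(Lx$gx)$gy
    hes[[k]] <- s^4 * (Lxx * Lyy - Lxy * Lxy)
    logs[[k]] <- s^2 * (Lxx + Lyy)
  }
  collect <- function(resp, thresh, tag) {
    out <- list()
    for (k in seq_len(nl)) {
      R <- resp[[k]]
      cand <- which(R > thresh & R > neighbour_max(R), arr.ind = TRUE)
      if (!nrow(cand)) next
      keep <- rep(TRUE, nrow(cand))
      aL <- abs(logs[[k]][cand])
      if (k > 1)  keep <- keep & aL >= abs(logs[[k - 1]][cand])
      if (k < nl) keep <- keep & aL >= abs(logs[[k + 1]][cand])
      cand <- cand[keep, , drop = FALSE]
      if (!nrow(cand)) next
      out[[k]] <- data.frame(x = cand[, 2], y = cand[, 1],
                             scale = sigmas[k], detector = tag,
                             response = R[cand])
    }
    out
  }
  kp <- rbind(do.call(rbind, collect(har, config$harris_thresh, "HAR")),
              do.call(rbind, collect(hes, config$hessian_thresh, "HES")))
  if (is.null(kp) || !nrow(kp))
    return(data.frame(x = numeric(0), y = numeric(0), scale = numeric(0),
                      detector = character(0), response = numeric(0)))
  if (!is.null(mask)) kp <- kp[mask[cbind(kp$y, kp$x)], , drop = FALSE]
  rownames(kp) <- NULL
  kp
}
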