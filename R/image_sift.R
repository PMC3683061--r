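#' Compute 128-bin SIFT descriptors for detected keypoints
#'
#' For each keypoint, gradients of the Gaussian-smoothed raster at the
#' keypoint scale are sampled on a rotated 16x16 grid (spacing equal to the
#' keypoint scale), assigned a dominant orientation from a 36-bin
#' gradient-orientation histogram (making the descriptor invariant to image
#' rotation), accumulated into 4x4 spatial cells times 8 orientation bins
#' with bilinear spatial and linear orientation interpolation under a
#' Gaussian spatial weight, L2-normalized with the standard 0.2 clipping, and
#' quantized to integers in \[0, 255\]. Working on gradients makes the
#' descriptor invariant to additive brightness shifts, and the normalization
#' to contrast scaling. The per-pixel loops run in compiled code.
#'
#' Keypoints whose sampling window leaves the raster are dropped (their count
#' is reported via a message and the `"n_dropped"` attribute).
#'
#' @param gray preprocessed raster in \[0, 1\].
#' @param kps keypoint data.frame from [detect_keypoints()].
#' @param config a [bow_config()].
#' @return integer matrix with one 128-column row per surviving keypoint,
#'   entries in \[0, 255\]; attribute `"keypoints"` holds the surviving rows.
#' @export
describe_keypoints <- function(gray, kps, config = bow_config()) {
  empty <- matrix(integer(0), 0, 128)
  if (is.null(kps) || !nrow(kps)) return(structure(empty, keypoints = kps, n_dropped = 0L))
  desc <- list(); keep_rows <- list()
  n_dropped <- 0L
  for (s in sort(unique(kps$scale))) {
    rows <- kps[kps$scale == s, , drop = FALSE]
    L <- gaussian_blur(gray, s)
    g <- image_gradients(L)
    theta <- cpp_orientation(g$gx, g$gy, rows$x, rows$y, s)
    d <- cpp_descriptors(g$gx, g$gy, rows$x, rows$y, s, theta)
    ok <- d$ok
    n_dropped <- n_dropped + sum(!ok)
    if (any(ok)) {
      desc[[length(desc) + 1]] <- d$desc[ok, , drop = FALSE]
      keep_rows[[length(keep_rows) + 1]] <- rows[ok, , drop = FALSE]
    }
  }
  if (n_dropped > 0)
    message(sprintf("describe_keypoints: dropped %d keypoint(s) whose window left the raster",
                    n_dropped))
  if (!length(desc)) return(structure(empty, keypoints = kps[0, ], n_dropped = n_dropped))
  structure(do.call(rbind, desc),
            keypoints = do.call(rbind, keep_rows), n_dropped = n_dropped)
}
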