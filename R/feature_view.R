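#' Construct a per-modality feature view
#'
#' A feature view is a subject-by-feature numeric matrix for one data
#' modality (demographic, genotype or image bag-of-words), optionally carrying
#' the min-max scaling parameters that map each feature to \[0, 1\]. Scalers
#' are always fitted on training subjects and re-applied, with clipping, to
#' test subjects so that no test-set information leaks into the encoding.
#'
#' @param x numeric matrix, subjects in rows.
#' @param source_id modality tag (e.g. `"D"`, `"G"`, `"I"`).
#' @param scaler optional scaler from [fit_minmax()]; when supplied, `x` is
#'   transformed with it. When `NULL` the matrix is used as-is.
#' @return a matrix of class `"feature_view"` with attributes `source_id` and
#'   `scaler`.
#' @export
feature_view <- function(x, source_id = "view", scaler = NULL) {
  x <- as.matrix(x)
  if (!is_finite_matrix(x)) pm_stop("feature view contains non-finite entries", "nonfinite")
  if (!is.null(scaler)) x <- apply_minmax(x, scaler)
  structure(x, source_id = source_id, scaler = scaler,
            class = c("feature_view", class(x)))
}

#' Fit per-feature min-max scaling parameters
#'
#' @param x numeric matrix (training subjects only).
#' @return list with `min` and `range` per column; constant columns get
#'   `range = 0` and map to all zeros.
#' @export
fit_minmax <- function(x) {
  x <- as.matrix(x)
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  list(min = mins, range = maxs - mins)
}

#' Apply a fitted min-max scaler, clipping to \[0, 1\]
#'
#' @param x numeric matrix.
#' @param scaler output of [fit_minmax()].
#' @return scaled matrix with every entry in \[0, 1\].
#' @export
apply_minmax <- function(x, scaler) {
  x <- as.matrix(x)
  rng <- scaler$range
  rng_safe <- ifelse(rng > 0, rng, 1)
  out <- sweep(sweep(x, 2, scaler$min, "-"), 2, rng_safe, "/")
  out[, rng == 0] <- 0  # constant in training -> uninformative, zeroed
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

view_matrix <- function(v) {
  m <- unclass(v)
  attr(m, "source_id") <- NULL
  attr(m, "scaler") <- NULL
  as.matrix(m)
}

view_source <- function(v, default = "view") attr(v, "source_id") %||% default
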