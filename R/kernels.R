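#' Linear Gram matrix of a feature view
#'
#' Computes the kernel matrix `K[i, j] = <x_i, x_j>` over subjects. Linear
#' kernels are used throughout: one basis kernel per data modality, combined
#' convexly by the multiple kernel learner.
#'
#' @param view a [feature_view()] or numeric matrix, subjects in rows.
#' @return symmetric positive semi-definite matrix of class `"kernel_matrix"`
#'   with a `source_id` attribute.
#' @export
linear_gram <- function(view) {
  x <- if (inherits(view, "feature_view")) view_matrix(view) else as.matrix(view)
  if (nrow(x) < 1L) pm_stop("need at least one subject", "empty")
  if (!is_finite_matrix(x)) pm_stop("non-finite entries in feature view", "nonfinite")
  K <- tcrossprod(x)
  K <- (K + t(K)) / 2  # exact symmetry despite roundoff
  structure(K, source_id = view_source(view), class = c("kernel_matrix", class(K)))
}

#' Convex combination of basis kernels
#'
#' @param kernels list of kernel matrices of identical dimension.
#' @param weights nonnegative weights summing to 1 (the kernel simplex).
#' @return the weighted element-wise sum, a `"kernel_matrix"`.
#' @export
combine_kernels <- function(kernels, weights) {
  if (length(kernels) != length(weights))
    pm_stop("one weight per kernel required", "dim_mismatch")
  dims <- vapply(kernels, nrow, integer(1))
  if (length(unique(dims)) != 1L || any(dims != vapply(kernels, ncol, integer(1))))
    pm_stop("kernels must be square and of identical dimension", "dim_mismatch")
  if (any(weights < -1e-12) || abs(sum(weights) - 1) > 1e-8)
    pm_stop("weights must lie on the probability simplex", "bad_weights")
  K <- matrix(0, dims[1], dims[1])
  for (m in seq_along(kernels)) K <- K + weights[m] * unclass(kernels[[m]])
  structure(K, source_id = paste(vapply(kernels, view_source, "", default = "k"),
                                 collapse = "+"),
            class = c("kernel_matrix", class(K)))
}

# PSD / symmetry validation for a kernel matrix. Tolerance scales with the
# magnitude of the entries so large unscaled Grams are not rejected for
# harmless roundoff.
check_kernel <- function(K, tol = 1e-8) {
  K <- unclass(K)
  if (!is_finite_matrix(K)) pm_stop("kernel has non-finite entries", "nonfinite")
  if (max(abs(K - t(K))) > 1e-9 * max(1, max(abs(K))))
    pm_stop("kernel matrix is not symmetric", "not_symmetric")
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(K))))
    pm_stop(sprintf("kernel is not positive semi-definite (min eigenvalue %.3g)",
                    min(ev)), "not_psd")
  invisible(TRUE)
}
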