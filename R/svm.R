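#' Train a soft-margin SVM from a precomputed kernel
#'
#' Solves the dual of the C-SVM
#' \deqn{\min_{w,b,\xi} \tfrac12 \|w\|^2 + C \sum_i \xi_i
#'       \quad\text{s.t. } y_i (w^\top \phi(x_i) + b) \ge 1 - \xi_i,\ \xi_i \ge 0}
#' by SMO-style pairwise coordinate ascent with maximal-violating-pair working
#' set selection. The dual variables satisfy the box constraint
#' `0 <= alpha_i <= C` and the equality `sum(alpha * y) == 0`.
#'
#' @param K symmetric PSD kernel matrix over the training subjects.
#' @param y labels in `{+1, -1}`; both classes must be present.
#' @param C positive box penalty (default 1).
#' @param tol stopping threshold on the maximal KKT violation.
#' @param max_iter cap on pairwise updates.
#' @return an object of class `"svm_dual"`: `alpha`, `bias`, `C`, `y`,
#'   `support` (indices with `alpha > 0`), the dual and primal objectives and
#'   the final KKT violation.
#' @export
train_svm <- function(K, y, C = 1, tol = 1e-9, max_iter = NULL) {
  K <- unclass(as.matrix(K))
  n <- nrow(K)
  y <- as.numeric(y)
  if (length(y) != n || ncol(K) != n)
    pm_stop("kernel and label dimensions disagree", "dim_mismatch")
  if (!all(y %in% c(-1, 1))) pm_stop("labels must be +1/-1", "bad_labels")
  if (length(unique(y)) < 2L) pm_stop("training labels contain a single class", "single_class")
  if (!is.numeric(C) || length(C) != 1L || C <= 0) pm_stop("C must be a positive scalar", "bad_C")
  check_kernel(K)
  if (is.null(max_iter)) max_iter <- max(10000L, 500L * n)

  alpha <- numeric(n)
  G <- rep(-1, n)  # gradient of 0.5 a'Qa - e'a at a = 0
  iter <- 0L
  repeat {
    # I_up / I_low index sets for the equality-constrained box problem
    up  <- (alpha < C - 1e-12 & y > 0) | (alpha > 1e-12 & y < 0)
    low <- (alpha < C - 1e-12 & y < 0) | (alpha > 1e-12 & y > 0)
    mG <- -y * G
    m_up  <- suppressWarnings(max(mG[up]))
    m_low <- suppressWarnings(min(mG[low]))
    if (!any(up) || !any(low) || m_up - m_low < tol) break
    if (iter >= max_iter) {
      # only a practically meaningful residual violation merits a warning
      if (m_up - m_low > 1e-3)
        warning(sprintf("SMO stopped at the iteration cap with KKT violation %.2g",
                        m_up - m_low))
      break
    }
    i <- which(up)[which.max(mG[up])]
    j <- which(low)[which.min(mG[low])]

    quad <- K[i, i] + K[j, j] - 2 * K[i, j]
    d <- (m_up - m_low) / max(quad, 1e-12)
    # box limits along the feasible direction a_i += y_i d, a_j -= y_j d
    dmax <- if (y[i] > 0) C - alpha[i] else alpha[i]
    dmax <- min(dmax, if (y[j] > 0) alpha[j] else C - alpha[j])
    d <- min(d, dmax)
    alpha[i] <- alpha[i] + y[i] * d
    alpha[j] <- alpha[j] - y[j] * d
    G <- G + d * y * (K[, i] - K[, j])
    iter <- iter + 1L
  }
  alpha[alpha < 1e-12] <- 0
  alpha[alpha > C - 1e-12] <- C

  free <- alpha > 1e-8 * C & alpha < C * (1 - 1e-8)
  bias <- if (any(free)) mean((-y * G)[free]) else (m_up + m_low) / 2
  if (!is.finite(bias)) bias <- 0

  f <- as.numeric(K %*% (alpha * y)) + bias
  dual_obj <- sum(alpha) - 0.5 * sum((alpha * y) * (K %*% (alpha * y)))
  primal_obj <- 0.5 * sum((alpha * y) * (K %*% (alpha * y))) +
    C * sum(pmax(0, 1 - y * f))

  structure(list(alpha = alpha, bias = bias, C = C, y = y,
                 support = which(alpha > 0),
                 dual_objective = dual_obj, primal_objective = primal_obj,
                 duality_gap = primal_obj - dual_obj,
                 kkt_violation = max(0, m_up - m_low), iterations = iter),
            class = "svm_dual")
}

#' Decision scores of a dual SVM on new subjects
#'
#' @param model an `"svm_dual"` fit.
#' @param K_cross kernel between training subjects (rows) and new subjects
#'   (columns).
#' @return numeric scores; the predicted label is `+1` when the score is
#'   strictly positive and `-1` otherwise (a score of exactly 0 is called
#'   negative).
#' @export
svm_decision <- function(model, K_cross) {
  K_cross <- as.matrix(K_cross)
  if (nrow(K_cross) != length(model$alpha))
    pm_stop("cross-kernel rows must match training subjects", "dim_mismatch")
  as.numeric(crossprod(K_cross, model$alpha * model$y)) + model$bias
}

#' @export
print.svm_dual <- function(x, ...) {
  cat("Soft-margin SVM (dual), n =", length(x$alpha),
      "| support vectors:", length(x$support),
      "| C =", format(x$C), "\n")
  cat("  dual objective:", format(x$dual_objective, digits = 6),
      " duality gap:", format(x$duality_gap, digits = 3), "\n")
  invisible(x)
}

score_to_label <- function(score) ifelse(score > 0, 1, -1)
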