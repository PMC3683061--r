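#' Fit a multiple kernel learning SVM over modality views
#'
#' The central fitting function of the package. Each data modality (demographic
#' covariates `D`, panel genotypes `G`, image bag-of-visual-words `I`)
#' contributes one linear basis kernel; the classifier kernel is the convex
#' combination \eqn{K = \sum_m \beta_m K_m} with \eqn{\beta_m \ge 0},
#' \eqn{\sum_m \beta_m = 1}. Weights and the SVM dual are optimized by
#' alternating minimization: at fixed weights the combined-kernel SVM is solved
#' with [train_svm()]; at a fixed dual the weights get the closed-form L1-MKL
#' (group-lasso) update \eqn{\beta_m \propto \|w_m\|}, where
#' \eqn{\|w_m\|^2 = \beta_m^2\, \alpha^\top Y K_m Y \alpha}. Both half-steps
#' minimize the joint regularized primal exactly, so the tracked objective is
#' non-increasing.
#'
#' With a single view the fit degenerates to a plain single-kernel SVM with
#' weight 1.
#'
#' @param views a list of [feature_view()]s or numeric matrices (one per
#'   modality, same subjects in the same order), or a single matrix.
#' @param y labels in `{+1, -1}`, both classes present.
#' @param C positive SVM penalty (default 1).
#' @param tol relative decrease of the outer objective at which to stop.
#' @param max_iter maximum outer iterations.
#' @param weights optional initial simplex weights (default uniform `1/M`).
#' @return an object of class `"mkl_svm"` with components `kernel_weights`,
#'   `svm` (the final [train_svm()] fit), `source_ids`, `views` (training
#'   views, kept for prediction), `objective_trace`, `C`.
#' @seealso [predict.mkl_svm()], [decision_function()], [write_mkl_model()]
#' @export
mkl_svm <- function(views, y, C = 1, tol = 1e-5, max_iter = 100, weights = NULL) {
  if (is.matrix(views) || inherits(views, "feature_view")) views <- list(views)
  if (!is.list(views) || length(views) < 1L) pm_stop("need at least one view", "no_views")
  M <- length(views)
  mats <- lapply(views, function(v) if (inherits(v, "feature_view")) view_matrix(v) else as.matrix(v))
  ns <- vapply(mats, nrow, integer(1))
  if (length(unique(ns)) != 1L)
    pm_stop("views cover different numbers of subjects", "subject_mismatch")
  n <- ns[1]
  if (length(y) != n) pm_stop("labels do not match subject count", "dim_mismatch")
  source_ids <- names(views) %||% rep(NA_character_, M)
  if (is.null(names(views)))
    source_ids <- vapply(seq_len(M), function(m) view_source(views[[m]], paste0("view", m)), "")

  kernels <- lapply(mats, tcrossprod)
  kernels <- lapply(kernels, function(K) (K + t(K)) / 2)
  y <- as.numeric(y)

  beta <- weights %||% rep(1 / M, M)
  if (length(beta) != M || any(beta < 0) || abs(sum(beta) - 1) > 1e-9)
    pm_stop("initial weights must lie on the simplex", "bad_weights")

  trace <- numeric(0)
  fit <- NULL
  for (it in seq_len(max_iter)) {
    Kc <- matrix(0, n, n)
    for (m in seq_len(M)) Kc <- Kc + beta[m] * kernels[[m]]
    fit <- train_svm(Kc, y, C = C)  # tight default tolerance keeps the outer
                                    # objective monotone across iterations
    ay <- fit$alpha * y
    u <- vapply(kernels, function(Km) sum(ay * (Km %*% ay)), numeric(1))  # alpha' Y Km Y alpha
    u[u < 0] <- 0
    f <- as.numeric(Kc %*% ay) + fit$bias
    obj <- 0.5 * sum(beta * u) + C * sum(pmax(0, 1 - y * f))
    trace <- c(trace, obj)
    if (it > 1 && (trace[it - 1] - obj) < tol * max(1, abs(trace[it - 1]))) break
    wnorm <- beta * sqrt(u)  # ||w_m|| = beta_m * sqrt(u_m)
    if (sum(wnorm) > 0) beta <- wnorm / sum(wnorm)
  }
  beta <- pmax(beta, 0)
  beta <- beta / sum(beta)

  structure(list(kernel_weights = stats::setNames(beta, source_ids),
                 svm = fit, source_ids = source_ids, views = views,
                 objective_trace = trace, C = C, tol = tol,
                 n_subjects = n, call = match.call()),
            class = "mkl_svm")
}

#' Decision scores for new subjects under a fused model
#'
#' Computes \eqn{s_t = \sum_i \alpha_i y_i \sum_m \beta_m \langle x_i^m,
#' x_t^m\rangle + b}. Test views must be scaled with the training scalers and
#' supplied in the model's modality order; a score of exactly 0 is labelled
#' `-1`.
#'
#' @param model an `"mkl_svm"` fit.
#' @param test_views list of matrices/views matching the model's modalities
#'   (a single matrix is accepted for single-view models).
#' @return numeric decision scores.
#' @export
decision_function <- function(model, test_views) {
  if (is.matrix(test_views) || inherits(test_views, "feature_view"))
    test_views <- list(test_views)
  M <- length(model$source_ids)
  if (length(test_views) != M)
    pm_stop("test modality set does not match the trained model", "modality_mismatch")
  if (!is.null(names(test_views)) && !is.null(names(model$kernel_weights)) &&
      !identical(names(test_views), model$source_ids))
    pm_stop("test modality names/order differ from the trained model", "modality_mismatch")
  train_mats <- lapply(model$views, function(v)
    if (inherits(v, "feature_view")) view_matrix(v) else as.matrix(v))
  score <- NULL
  for (m in seq_len(M)) {
    xt <- test_views[[m]]
    # raw matrices are rescaled with the stored training scaler, if any
    sc <- attr(model$views[[m]], "scaler")
    xt <- if (inherits(xt, "feature_view")) view_matrix(xt) else {
      xt <- as.matrix(xt)
      if (!is.null(sc)) apply_minmax(xt, sc) else xt
    }
    if (ncol(xt) != ncol(train_mats[[m]]))
      pm_stop("test view has a different feature dimension", "modality_mismatch")
    Kx <- tcrossprod(train_mats[[m]], xt)  # train x test
    part <- model$kernel_weights[m] * as.numeric(crossprod(Kx, model$svm$alpha * model$svm$y))
    score <- if (is.null(score)) part else score + part
  }
  unname(score + model$svm$bias)
}

#' @rdname decision_function
#' @param object an `"mkl_svm"` fit.
#' @param newdata list of test views (see [decision_function()]).
#' @param type `"score"` for raw decision values, `"class"` for `+1/-1` labels.
#' @param ... ignored.
#' @export
predict.mkl_svm <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  s <- decision_function(object, newdata)
  if (type == "class") score_to_label(s) else s
}

#' @export
print.mkl_svm <- function(x, ...) {
  cat("Multiple kernel learning SVM (", length(x$source_ids), " basis kernel",
      if (length(x$source_ids) > 1) "s", ")\n", sep = "")
  cat("  n =", x$n_subjects, "| C =", format(x$C),
      "| outer iterations:", length(x$objective_trace), "\n")
  cat("  kernel weights:\n")
  print(round(x$kernel_weights, 4))
  invisible(x)
}

#' @export
summary.mkl_svm <- function(object, ...) {
  out <- list(kernel_weights = object$kernel_weights,
              n_subjects = object$n_subjects,
              n_support = length(object$svm$support),
              C = object$C,
              objective_trace = object$objective_trace,
              duality_gap = object$svm$duality_gap)
  class(out) <- "summary.mkl_svm"
  out
}

#' @export
print.summary.mkl_svm <- function(x, ...) {
  cat("MKL-SVM summary\n")
  cat("  subjects:", x$n_subjects, "  support vectors:", x$n_support,
      "  C:", format(x$C), "\n")
  cat("  kernel weights:\n"); print(round(x$kernel_weights, 4))
  cat("  outer objective trace:", paste(format(x$objective_trace, digits = 6),
                                        collapse = " -> "), "\n")
  cat("  final duality gap:", format(x$duality_gap, digits = 3), "\n")
  invisible(x)
}

#' @param x an `"mkl_svm"` fit.
#' @rdname mkl_svm
#' @export
plot.mkl_svm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::barplot(x$kernel_weights, ylab = "kernel weight", ylim = c(0, 1),
                    main = "Modality contributions", ...)
  graphics::plot(seq_along(x$objective_trace), x$objective_trace, type = "b",
                 xlab = "outer iteration", ylab = "regularized objective",
                 main = "MKL objective trace")
  invisible(x)
}

#' @export
coef.mkl_svm <- function(object, ...) {
  list(kernel_weights = object$kernel_weights,
       dual_coefficients = object$svm$alpha,
       bias = object$svm$bias)
}
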