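#' Serialize a fitted MKL-SVM to a single JSON document
#'
#' Stores everything needed to reproduce predictions: kernel weights, dual
#' coefficients, bias, C, the per-modality scaler parameters, modality
#' ordering, an optional codebook reference and the RNG seed used in
#' training. Training feature matrices are stored as well (the dual expansion
#' needs them); for large cohorts prefer keeping the training data externally
#' and re-fitting.
#'
#' @param model an `"mkl_svm"` fit.
#' @param path output JSON path.
#' @param codebook_ref optional path/identifier of the visual codebook used
#'   for the image view.
#' @param seed optional RNG seed recorded as provenance.
#' @export
write_mkl_model <- function(model, path, codebook_ref = NULL, seed = NULL) {
  stopifnot(inherits(model, "mkl_svm"))
  scalers <- lapply(model$views, function(v) {
    sc <- attr(v, "scaler")
    if (is.null(sc)) NULL else list(min = unname(sc$min), range = unname(sc$range))
  })
  doc <- list(
    format = "pmfuse-mkl-model",
    version = 1L,
    source_ids = model$source_ids,
    kernel_weights = unname(model$kernel_weights),
    dual_coefficients = model$svm$alpha,
    labels = model$svm$y,
    bias = model$svm$bias,
    C = model$C,
    scalers = scalers,
    training_views = lapply(model$views, function(v) {
      m <- if (inherits(v, "feature_view")) view_matrix(v) else as.matrix(v)
      unname(m)  # serialized as a row-major nested array
    }),
    codebook_ref = codebook_ref,
    seed = seed)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Restore a fitted MKL-SVM from JSON
#'
#' @param path JSON written by [write_mkl_model()].
#' @return an `"mkl_svm"` object equivalent for prediction.
#' @export
read_mkl_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "pmfuse-mkl-model"))
    pm_stop("not a pmfuse model file", "bad_model_file")
  M <- length(doc$source_ids)
  views <- vector("list", M)
  for (m in seq_len(M)) {
    tv <- doc$training_views[[m]]
    x <- if (is.list(tv)) do.call(rbind, tv) else as.matrix(tv)
    if (is.list(doc$scalers) && !is.null(doc$scalers[[m]])) {
      sc <- list(min = doc$scalers[[m]]$min, range = doc$scalers[[m]]$range)
      views[[m]] <- structure(x, source_id = doc$source_ids[m], scaler = sc,
                              class = c("feature_view", class(x)))
    } else views[[m]] <- feature_view(x, source_id = doc$source_ids[m])
  }
  names(views) <- doc$source_ids
  alpha <- as.numeric(doc$dual_coefficients)
  y <- as.numeric(doc$labels)
  svm <- structure(list(alpha = alpha, bias = doc$bias, C = doc$C, y = y,
                        support = which(alpha > 0),
                        dual_objective = NA_real_, primal_objective = NA_real_,
                        duality_gap = NA_real_, kkt_violation = NA_real_,
                        iterations = NA_integer_),
                   class = "svm_dual")
  structure(list(kernel_weights = stats::setNames(as.numeric(doc$kernel_weights),
                                                  doc$source_ids),
                 svm = svm, source_ids = doc$source_ids, views = views,
                 objective_trace = numeric(0), C = doc$C,
                 n_subjects = length(alpha),
                 codebook_ref = doc$codebook_ref, seed = doc$seed),
            class = "mkl_svm")
}
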