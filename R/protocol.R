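#' Match subjects across modality sources into a cohort bundle
#'
#' Takes any subset of the three modality sources, each keyed by subject id,
#' intersects the ids, and returns matched matrices in sorted-id order
#' together with the labels. Counts per source and after intersection are
#' reported via a message.
#'
#' @param demographics numeric matrix (rows named by subject id), a
#'   [feature_view()], or `NULL`.
#' @param genotypes numeric matrix / [feature_view()] (e.g. from
#'   [encode_additive()]) or `NULL`.
#' @param images numeric BOW matrix / [feature_view()] or `NULL`.
#' @param labels named vector of `{+1, -1}` labels covering the matched ids.
#' @return object of class `"cohort_bundle"`: `subject_ids`, `labels`,
#'   `views` (named list with any of `D`, `G`, `I`), `provenance`.
#' @export
match_subjects <- function(demographics = NULL, genotypes = NULL,
                           images = NULL, labels) {
  src <- list(D = demographics, G = genotypes, I = images)
  src <- src[!vapply(src, is.null, logical(1))]
  if (!length(src)) pm_stop("at least one modality source is required", "no_views")
  src <- lapply(src, function(v) {
    m <- if (inherits(v, "feature_view")) view_matrix(v) else as.matrix(v)
    if (is.null(rownames(m))) pm_stop("each source must be keyed by subject id rownames",
                                      "missing_ids")
    m
  })
  if (is.null(names(labels))) pm_stop("labels must be named by subject id", "missing_ids")
  ids <- Reduce(intersect, c(lapply(src, rownames), list(names(labels))))
  if (!length(ids)) pm_stop("no subject is present in every source", "empty_intersection")
  ids <- sort(ids)
  counts <- vapply(src, nrow, integer(1))
  message(sprintf("match_subjects: %s; %d labelled; %d matched",
                  paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
                  length(labels), length(ids)))
  y <- as.numeric(labels[ids])
  if (!all(y %in% c(-1, 1))) pm_stop("labels must be +1/-1", "bad_labels")
  if (sum(y > 0) == 0) pm_stop("cohort has no positive subjects", "single_class")
  views <- lapply(src, function(m) m[ids, , drop = FALSE])
  structure(list(subject_ids = ids, labels = stats::setNames(y, ids),
                 views = views,
                 provenance = list(n_per_source = counts, n_matched = length(ids))),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("Cohort bundle:", length(x$subject_ids), "subjects,",
      sum(x$labels > 0), "positive; views:",
      paste(names(x$views), collapse = ", "), "\n")
  invisible(x)
}

#' All seven modality combinations
#'
#' The non-empty subsets of \{D, G, I\} evaluated against each other:
#' three single sources, three pairs, and the full fusion.
#'
#' @param available modality tags present in the bundle.
#' @return character vector of method names such as `"D+G+I"`.
#' @export
method_specs <- function(available = c("D", "G", "I")) {
  subsets <- unlist(lapply(seq_along(available), function(m)
    utils::combn(available, m, paste, collapse = "+", simplify = FALSE)))
  unlist(subsets)
}

# Stratified half split: permute each class and deal into halves A/B; the
# extra subject of an odd class goes to half A. Deterministic given the RNG
# state.
stratified_half_split <- function(y) {
  idx_pos <- which(y > 0); idx_neg <- which(y < 0)
  pos <- sample(idx_pos); neg <- sample(idx_neg)
  nA_pos <- ceiling(length(pos) / 2); nA_neg <- ceiling(length(neg) / 2)
  A <- sort(c(pos[seq_len(nA_pos)], neg[seq_len(nA_neg)]))
  B <- sort(c(pos[-seq_len(nA_pos)], neg[-seq_len(nA_neg)]))
  list(A = A, B = B)
}

#' Run the balanced stratified cross-validation protocol
#'
#' The evaluation protocol for an imbalanced screening cohort: per test, all
#' subjects are randomly split into stratified halves A and B (class
#' proportions preserved, sizes differing by at most one). Round 1 trains on
#' all A-positives plus an equal-sized seeded random draw of A-negatives (a
#' balanced training set) and scores **all** of B; round 2 swaps the halves.
#' With `n_tests = 10` this yields 20 result groups per method. Every method
#' in a given (test, round) uses the identical split and negative draw, so
#' method comparisons are paired. Single-modality methods use the plain
#' linear-kernel SVM path; multi-modality methods the MKL path. Each view is
#' min-max scaled with parameters fitted on the training subjects of that
#' round.
#'
#' RNG streams per (test, round) are derived from the master seed by fixed
#' offsets, so adding methods never perturbs the splits.
#'
#' @param bundle a [match_subjects()] cohort bundle.
#' @param methods character vector of modality combinations (default: all
#'   non-empty subsets of the bundle's views).
#' @param n_tests number of independent tests (default 10).
#' @param seed master seed.
#' @param C SVM penalty (default 1).
#' @param setpoint specificity setpoint for the reported sensitivity
#'   (default 0.85).
#' @return object of class `"pm_eval"`: `results` data.frame (method, test,
#'   round, auc, sensitivity at the setpoint, confusion counts at threshold
#'   0), `roc` (list of ROC data.frames keyed `method|test|round`),
#'   `provenance`.
#' @export
run_protocol <- function(bundle, methods = NULL, n_tests = 10, seed = 1,
                         C = 1, setpoint = 0.85) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  methods <- methods %||% method_specs(names(bundle$views))
  need <- unique(unlist(strsplit(methods, "\\+")))
  if (!all(need %in% names(bundle$views)))
    pm_stop("a requested method needs a modality absent from the bundle",
            "modality_mismatch")
  y <- unname(bundle$labels)
  n <- length(y)
  results <- list()
  rocs <- list()
  for (t in seq_len(n_tests)) {
    halves <- with_seed(derive_seed(seed, t), stratified_half_split(y))
    if (sum(y[halves$A] > 0) < 1 || sum(y[halves$B] > 0) < 1)
      pm_stop("a half-split contains no positive subject", "too_few_positives")
    for (r in 1:2) {
      train_half <- if (r == 1) halves$A else halves$B
      test_idx <- if (r == 1) halves$B else halves$A
      pos <- train_half[y[train_half] > 0]
      negs <- train_half[y[train_half] < 0]
      if (length(pos) < 1) pm_stop("training half has no positives", "too_few_positives")
      neg_draw <- with_seed(derive_seed(seed, 1000L * t + r),
                            sort(sample(negs, length(pos))))
      train_idx <- sort(c(pos, neg_draw))
      y_tr <- y[train_idx]; y_te <- y[test_idx]
      for (meth in methods) {
        mods <- strsplit(meth, "\\+")[[1]]
        tr_views <- list(); te_views <- list()
        for (md in mods) {
          xm <- bundle$views[[md]]
          sc <- fit_minmax(xm[train_idx, , drop = FALSE])
          tr_views[[md]] <- feature_view(xm[train_idx, , drop = FALSE],
                                         source_id = md, scaler = sc)
          te_views[[md]] <- feature_view(xm[test_idx, , drop = FALSE],
                                         source_id = md, scaler = sc)
        }
        fit <- mkl_svm(tr_views, y_tr, C = C)
        scores <- decision_function(fit, te_views)
        ra <- roc_and_auc(scores, y_te)
        sens <- sensitivity_at_specificity(ra$roc, setpoint)
        pred <- score_to_label(scores)
        res <- data.frame(method = meth, test = t, round = r,
                          auc = ra$auc, sensitivity_at_setpoint = sens,
                          tp = sum(pred > 0 & y_te > 0), fp = sum(pred > 0 & y_te < 0),
                          tn = sum(pred < 0 & y_te < 0), fn = sum(pred < 0 & y_te > 0),
                          n_train = length(train_idx), n_test = length(test_idx))
        results[[length(results) + 1]] <- res
        rocs[[paste(meth, t, r, sep = "|")]] <- ra$roc
      }
    }
  }
  structure(list(results = do.call(rbind, results), roc = rocs,
                 provenance = list(seed = seed, n_tests = n_tests, C = C,
                                   setpoint = setpoint, methods = methods,
                                   n_subjects = n, n_positive = sum(y > 0))),
            class = "pm_eval")
}

#' @export
print.pm_eval <- function(x, ...) {
  cat("Protocol evaluation:", x$provenance$n_tests, "tests x 2 rounds,",
      length(x$provenance$methods), "methods, seed", x$provenance$seed, "\n")
  print(compare_methods(x)$table, row.names = FALSE)
  invisible(x)
}

#' @param x a `"pm_eval"` object.
#' @param ... passed to [graphics::boxplot()].
#' @rdname run_protocol
#' @export
plot.pm_eval <- function(x, ...) {
  graphics::boxplot(auc ~ method, data = x$results, ylab = "AUC",
                    xlab = "modality combination",
                    main = sprintf("AUC over %d CV groups",
                                   2 * x$provenance$n_tests), ...)
  invisible(x)
}

#' Summarize and compare methods over the matched result groups
#'
#' Produces the per-method mean and SD of AUC plus the mean sensitivity at
#' the specificity setpoint over the 20 matched result groups, and pairwise
#' paired t-test p-values on the matched AUC values (every pair of methods;
#' pairs sharing identical splits by construction), flagged at `alpha`.
#'
#' @param result a [run_protocol()] `"pm_eval"`, or a list of them (their
#'   provenance must agree on seed and test count -- the pairing requirement).
#' @param alpha flag level for p-values (default 0.05).
#' @return list with `table` (per-method summary) and `p_values` (matrix of
#'   paired p-values; the self-comparison diagonal is 1).
#' @export
compare_methods <- function(result, alpha = 0.05) {
  if (inherits(result, "pm_eval")) result <- list(result)
  prov <- lapply(result, function(r) r$provenance[c("seed", "n_tests", "n_subjects")])
  if (length(unique(vapply(prov, function(p) paste(unlist(p), collapse = "/"), ""))) != 1L)
    pm_stop("results come from different split provenance; comparison is unpaired",
            "provenance_mismatch")
  res <- do.call(rbind, lapply(result, `[[`, "results"))
  methods <- unique(res$method)
  tab <- do.call(rbind, lapply(methods, function(m) {
    r <- res[res$method == m, ]
    data.frame(method = m, n_groups = nrow(r),
               auc_mean = mean(r$auc), auc_sd = stats::sd(r$auc),
               sensitivity_at_setpoint = mean(r$sensitivity_at_setpoint))
  }))
  key <- function(m) {
    r <- res[res$method == m, ]
    r[order(r$test, r$round), "auc"]
  }
  p <- matrix(NA_real_, length(methods), length(methods),
              dimnames = list(methods, methods))
  for (i in seq_along(methods)) for (j in seq_along(methods)) {
    if (i == j) { p[i, j] <- 1; next }  # self-comparison: zero difference
    d <- key(methods[i]) - key(methods[j])
    p[i, j] <- if (stats::sd(d) == 0) 1 else stats::t.test(d)$p.value
  }
  list(table = tab, p_values = p, significant = p < alpha, alpha = alpha)
}
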