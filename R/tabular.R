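#' Construct a demographic/clinical covariate table
#'
#' @param data data.frame keyed by a `subject_id` column (or rownames); all
#'   other columns are covariates.
#' @param types named character vector declaring each covariate as
#'   `"numeric"` or `"categorical"`; every covariate must be declared.
#' @return object of class `"covariate_table"`.
#' @export
covariate_table <- function(data, types) {
  data <- as.data.frame(data)
  if ("subject_id" %in% names(data)) {
    rownames(data) <- data$subject_id
    data$subject_id <- NULL
  }
  if (anyDuplicated(rownames(data))) pm_stop("subject ids must be unique", "duplicate_subject")
  vars <- names(data)
  if (!all(vars %in% names(types)))
    pm_stop("every covariate needs a declared type (numeric|categorical)", "missing_type")
  types <- types[vars]
  if (!all(types %in% c("numeric", "categorical")))
    pm_stop("types must be 'numeric' or 'categorical'", "bad_type")
  for (v in vars) {
    if (types[[v]] == "numeric") data[[v]] <- as.numeric(data[[v]])
    else data[[v]] <- as.character(data[[v]])
  }
  structure(list(data = data, types = types), class = "covariate_table")
}

#' @export
print.covariate_table <- function(x, ...) {
  cat("Covariate table:", nrow(x$data), "subjects x", ncol(x$data), "variables (",
      sum(x$types == "numeric"), "numeric,", sum(x$types == "categorical"),
      "categorical );", sprintf("%.2f%% missing\n", 100 * mean(is.na(as.matrix(x$data)))))
  invisible(x)
}

#' Read a covariate CSV with a column-type sidecar
#'
#' @param csv_path CSV with a header including `subject_id`.
#' @param types_path two-column sidecar (`name,type`) declaring
#'   `numeric|categorical` per covariate.
#' @return a [covariate_table()].
#' @export
read_covariates <- function(csv_path, types_path) {
  dat <- utils::read.csv(csv_path, check.names = FALSE,
                         colClasses = "character", na.strings = c("NA", ""))
  ty <- utils::read.csv(types_path, check.names = FALSE, colClasses = "character")
  types <- stats::setNames(ty[[2]], ty[[1]])
  covariate_table(dat, types)
}

#' Clean a covariate table by the 5 percent missingness rule
#'
#' Columns with a missing fraction above `max_missing` are dropped first, then
#' rows exceeding the threshold over the surviving columns; remaining missing
#' numeric cells are imputed with the column median and categorical cells with
#' the column mode. Dropping columns before rows retains more subjects, the
#' scarcer resource in a low-prevalence cohort.
#'
#' @param t a [covariate_table()].
#' @param max_missing tolerated missing fraction (default 0.05).
#' @return cleaned `"covariate_table"` with a `"removed"` attribute listing
#'   dropped columns and rows.
#' @export
clean_table <- function(t, max_missing = 0.05) {
  stopifnot(inherits(t, "covariate_table"))
  df <- t$data
  col_miss <- vapply(df, function(v) mean(is.na(v)), numeric(1))
  drop_cols <- names(df)[col_miss > max_missing]
  df <- df[, setdiff(names(df), drop_cols), drop = FALSE]
  if (!ncol(df)) pm_stop("no covariates survive the missingness filter", "all_removed")
  row_miss <- rowMeans(is.na(as.matrix(df)))
  drop_rows <- rownames(df)[row_miss > max_missing]
  df <- df[row_miss <= max_missing, , drop = FALSE]
  if (!nrow(df)) pm_stop("no subjects survive the missingness filter", "all_removed")
  types <- t$types[names(df)]
  for (v in names(df)) {
    miss <- is.na(df[[v]])
    if (!any(miss)) next
    df[[v]][miss] <- if (types[[v]] == "numeric")
      stats::median(df[[v]], na.rm = TRUE)
    else names(which.max(table(df[[v]])))
  }
  out <- covariate_table(cbind(subject_id = rownames(df), df), types)
  attr(out, "removed") <- list(columns = drop_cols, rows = drop_rows)
  out
}

#' Encode categoricals and min-max scale all covariates to \[0, 1\]
#'
#' Categorical columns are digitized to integer codes in lexicographic level
#' order; every column is then min-max scaled with parameters fitted on
#' `fit_subjects` only, and values outside the fitted range (test subjects)
#' are clipped to \[0, 1\]. Columns constant on the fit subjects map to zeros
#' with a warning.
#'
#' @param t a cleaned [covariate_table()].
#' @param fit_subjects indices (or subject ids) used to fit the scalers;
#'   default all subjects.
#' @return a [feature_view()] with `source_id = "D"`.
#' @export
encode_and_scale <- function(t, fit_subjects = NULL) {
  stopifnot(inherits(t, "covariate_table"))
  df <- t$data
  x <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(rownames(df), names(df)))
  for (v in names(df)) {
    x[, v] <- if (t$types[[v]] == "categorical") {
      lev <- sort(unique(df[[v]]))
      as.numeric(match(df[[v]], lev) - 1L)
    } else df[[v]]
  }
  if (anyNA(x)) pm_stop("encode_and_scale requires a cleaned (imputed) table", "missing_values")
  fit_subjects <- fit_subjects %||% seq_len(nrow(x))
  if (is.character(fit_subjects)) fit_subjects <- match(fit_subjects, rownames(x))
  sc <- fit_minmax(x[fit_subjects, , drop = FALSE])
  if (any(sc$range == 0))
    warning("constant column(s) mapped to zeros: ",
            paste(colnames(x)[sc$range == 0], collapse = ", "))
  feature_view(x, source_id = "D", scaler = sc)
}

#' Univariate association screen of covariates against disease labels
#'
#' Per covariate: a Welch two-sample t-test for numeric columns and a
#' chi-square test of independence (no continuity correction) on the
#' level-by-class contingency table for categorical columns. This is a report,
#' not a filter -- the classifier consumes all cleaned covariates.
#'
#' Factor levels absent from the data (all-zero contingency rows) are merged
#' into the rarest observed level and flagged in the report.
#'
#' @param t a cleaned [covariate_table()].
#' @param y labels in `{+1, -1}` aligned to the table's subjects.
#' @param alpha flag threshold for the `significant` column (default 0.05).
#' @return data.frame of class `"univariate_report"`: `variable`, `test`,
#'   `statistic`, `p_value`, `significant`, `note`.
#' @export
univariate_screen <- function(t, y, alpha = 0.05) {
  stopifnot(inherits(t, "covariate_table"))
  y <- as.numeric(y)
  if (length(y) != nrow(t$data)) pm_stop("labels do not match subjects", "dim_mismatch")
  if (length(unique(y)) < 2L) pm_stop("both classes required", "single_class")
  rows <- lapply(names(t$data), function(v) {
    note <- ""
    if (t$types[[v]] == "numeric") {
      a <- t$data[[v]][y > 0]; b <- t$data[[v]][y < 0]
      if (stats::sd(t$data[[v]]) == 0 || length(unique(c(a, b))) == 1L) {
        stat <- 0; p <- 1
      } else if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        stat <- NA_real_; p <- if (mean(a) == mean(b)) 1 else 0
        note <- "degenerate within-class variance"
      } else {
        tt <- stats::t.test(a, b)   # Welch by default
        stat <- unname(tt$statistic); p <- tt$p.value
      }
      data.frame(variable = v, test = "t-test", statistic = stat,
                 p_value = p, note = note)
    } else {
      f <- if (is.factor(t$data[[v]])) t$data[[v]] else factor(t$data[[v]])
      tab <- table(f, factor(y, levels = c(-1, 1)))
      empty <- rowSums(tab) == 0 | apply(tab, 1, function(r) all(r == 0))
      if (any(empty)) {
        keep <- which(!empty)
        rare <- keep[which.min(rowSums(tab)[keep])]
        note <- "empty level merged into rarest level"
        tab <- tab[keep, , drop = FALSE]
      }
      if (nrow(tab) < 2L) {
        stat <- 0; p <- 1
      } else {
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        stat <- unname(ct$statistic); p <- ct$p.value
      }
      data.frame(variable = v, test = "chi-square", statistic = stat,
                 p_value = p, note = note)
    }
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < alpha
  out <- out[, c("variable", "test", "statistic", "p_value", "significant", "note")]
  class(out) <- c("univariate_report", class(out))
  out
}
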