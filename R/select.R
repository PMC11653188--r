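#' Recursive feature elimination with a random-forest engine
#'
#' Supervised selection of the feature subset that best separates the
#' study groups. A random forest is fitted to the current feature set, the
#' feature with the smallest importance (mean decrease in Gini impurity)
#' is dropped, and the procedure repeats until `n_keep` features remain --
#' by default half of the input features, rounded up.
#'
#' @param table Feature table (see [extract_feature_table()]) or any
#'   data.frame with numeric feature columns and a label column.
#' @param target Name of the label column (default `"group"`); must have
#'   at least two levels, each with at least two cells.
#' @param n_keep Number of features to retain (default `ceiling(p/2)`).
#' @param seed Integer seed making the forests reproducible.
#' @param features Feature column names; defaults to the 32 morphometric
#'   features present in the table.
#' @param ntree Trees per forest (default 100).
#' @return A `glia_selection`: list with `selected_features` (ordered by
#'   final importance, decreasing), `importances` (of the final model),
#'   `elimination_order` (first-dropped first), `n_keep`, `seed`.
#' @export
select_features <- function(table, target = "group", n_keep = NULL,
                            seed = NULL, features = NULL, ntree = 100) {
  features <- features %||% feature_columns(table)
  if (!target %in% names(table)) {
    config_error("select_features: no column '", target, "' in table")
  }
  y <- factor(table[[target]])
  if (nlevels(y) < 2L) {
    data_error("select_features: supervised selection needs >= 2 groups, got ",
               nlevels(y))
  }
  if (any(tabulate(y) < 2L)) {
    data_error("select_features: every group needs >= 2 cells")
  }
  p <- length(features)
  n_keep <- as.integer(n_keep %||% ceiling(p / 2))
  if (n_keep < 1L || n_keep > p) {
    config_error("select_features: n_keep must be in [1, ", p, "]")
  }
  x <- as.matrix(table[, features, drop = FALSE])
  if (anyNA(x)) data_error("select_features: missing values in feature columns")
  if (!is.null(seed)) set.seed(seed)
  current <- features
  dropped <- character(0)
  imp <- NULL
  repeat {
    rf <- randomForest::randomForest(x[, current, drop = FALSE], y,
                                     ntree = ntree, importance = FALSE)
    imp <- rf$importance[, "MeanDecreaseGini"]
    if (length(current) == n_keep) break
    worst <- names(imp)[which.min(imp)]
    dropped <- c(dropped, worst)
    current <- setdiff(current, worst)
  }
  structure(list(
    selected_features = names(sort(imp, decreasing = TRUE)),
    importances = imp,
    elimination_order = dropped,
    n_keep = n_keep,
    seed = seed
  ), class = "glia_selection")
}

#' @export
print.glia_selection <- function(x, ...) {
  cat(sprintf("<glia_selection> %d features kept (seed=%s):\n", x$n_keep,
              format(x$seed)))
  cat(" ", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}

#' Selection report as a data.frame
#'
#' @param sel A `glia_selection`.
#' @param all_features Full input feature set (to flag dropped ones).
#' @return data.frame with `feature`, `importance` (NA for eliminated
#'   features), `selected`.
#' @export
selection_report <- function(sel, all_features = NULL) {
  all_features <- all_features %||% c(sel$selected_features, sel$elimination_order)
  data.frame(
    feature = all_features,
    importance = unname(sel$importances[all_features]),
    selected = all_features %in% sel$selected_features,
    stringsAsFactors = FALSE
  )
}
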