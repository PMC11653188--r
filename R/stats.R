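#' Cluster-by-group contingency table
#'
#' Cross-tabulates non-noise cells. Noise (label -1) is excluded
#' throughout the statistics stage, matching the convention that only
#' classified cells enter downstream comparisons.
#'
#' @param labels Cluster labels (`glia_clusters` or integer vector,
#'   -1 = noise).
#' @param groups Per-cell study-group labels, same length/order.
#' @return Integer matrix clusters x groups.
#' @export
contingency <- function(labels, groups) {
  labs <- label_vector(labels)
  if (length(labs) != length(groups)) {
    data_error("contingency: ", length(labs), " labels vs ",
               length(groups), " groups")
  }
  keep <- labs >= 0L
  labs <- labs[keep]; groups <- as.character(groups)[keep]
  if (!length(labs)) data_error("contingency: no classified cells")
  tab <- table(cluster = labs, group = groups)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    data_error("contingency: need >= 2 clusters and >= 2 groups after ",
               "excluding noise (got ", nrow(tab), " x ", ncol(tab), ")")
  }
  mat <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
  mat
}

#' Chi-square test of cluster-group independence
#'
#' Pearson chi-square statistic `sum((O - E)^2 / E)` with expected counts
#' from the product of the margins. Residuals come in two flavours:
#' Pearson standardized residuals `(O - E)/sqrt(E)` (default) and
#' margin-adjusted residuals `(O - E)/sqrt(E(1 - row/N)(1 - col/N))`;
#' both are returned, `residuals` picks which one `std_residuals` aliases.
#' Positive residuals mark over-represented cluster-group combinations.
#'
#' @param tab Counts matrix (see [contingency()]).
#' @param residuals `"pearson"` or `"adjusted"`.
#' @param correct Yates continuity correction for 2x2 tables (default
#'   FALSE; never applied when df > 1).
#' @return List: `statistic`, `df`, `p_value`, `expected`,
#'   `std_residuals`, `pearson_residuals`, `adjusted_residuals`.
#' @examples
#' chi_square(matrix(c(10, 20, 20, 10), 2))$statistic  # 20/3
#' @export
chi_square <- function(tab, residuals = c("pearson", "adjusted"),
                       correct = FALSE) {
  residuals <- match.arg(residuals)
  tab <- as.matrix(tab)
  if (any(tab < 0)) data_error("chi_square: negative counts")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0)) {
    data_error("chi_square: empty row (cluster): ",
               paste(rownames(tab)[rs == 0] %||% which(rs == 0), collapse = ", "))
  }
  if (any(cs == 0)) {
    data_error("chi_square: empty column (group): ",
               paste(colnames(tab)[cs == 0] %||% which(cs == 0), collapse = ", "))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  N <- sum(tab)
  expected <- ct$expected
  adj <- ct$stdres
  pearson <- ct$residuals
  res <- list(statistic = unname(ct$statistic),
              df = unname(ct$parameter),
              p_value = unname(ct$p.value),
              expected = expected,
              std_residuals = if (residuals == "pearson") pearson else adj,
              pearson_residuals = pearson,
              adjusted_residuals = adj)
  res
}

#' Per-cluster (or per-group) mean z-scored feature heatmap matrix
#'
#' Each feature is z-scored over all cells, then averaged within each key
#' level. Entries far from zero mark features over- or under-expressed in
#' a cluster relative to the whole population. The between-level variance
#' of each feature (variance of the level means) quantifies how much
#' structure the keys capture: cluster keys should show more than
#' arbitrary groupings.
#'
#' @param table Feature table (see [extract_feature_table()]).
#' @param keys Factor-like per-cell key (cluster labels or group).
#' @param features Feature columns; default the morphometric 32.
#' @return List: `matrix` (levels x features), `between_var` (named per
#'   feature).
#' @export
cluster_heatmap <- function(table, keys, features = NULL) {
  features <- features %||% feature_columns(table)
  if (length(keys) != nrow(table)) {
    data_error("cluster_heatmap: keys length != table rows")
  }
  keys <- factor(keys)
  if (any(tabulate(keys) == 0L)) keys <- droplevels(keys)
  x <- as.matrix(table[, features, drop = FALSE])
  sdv <- apply(x, 2, stats::sd)
  if (any(sdv < 1e-12)) {
    warning("constant feature(s) z-scored to 0: ",
            paste(features[sdv < 1e-12], collapse = ", "))
  }
  z <- scale_features(x)
  mat <- do.call(rbind, lapply(levels(keys), function(l)
    colMeans(z[keys == l, , drop = FALSE])))
  rownames(mat) <- levels(keys)
  between <- apply(mat, 2, stats::var)
  if (nlevels(keys) < 2L) between[] <- 0
  list(matrix = mat, between_var = between)
}

#' Mann-Whitney U rank test
#'
#' Two-sided comparison of per-image counts (or relative frequencies)
#' between two groups. Exact distribution when both samples have at most
#' 8 observations and no ties; normal approximation with continuity
#' correction otherwise. Fully tied data yield `p = 1` with a warning.
#'
#' @param x,y Numeric samples (e.g. per-image cell counts per group).
#' @return List: `U` (statistic for `x`), `p_value`.
#' @examples
#' rank_test(c(1, 2, 3, 4), c(10, 11, 12, 13))$p_value  # 2/70
#' @export
rank_test <- function(x, y) {
  if (!length(x) || !length(y)) data_error("rank_test: empty sample")
  if (length(unique(c(x, y))) == 1L) {
    warning("rank_test: all observations tied; p = 1")
    return(list(U = length(x) * length(y) / 2, p_value = 1))
  }
  ties <- any(duplicated(c(x, y)))
  exact <- !ties && length(x) <= 8L && length(y) <= 8L
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Rank tests over layer counts
#'
#' Runs [rank_test()] for every (layer, cluster) combination comparing the
#' per-image values of two study groups, for counts or relative
#' frequencies. No multiple-testing correction is applied by default, but
#' any [stats::p.adjust()] method can be requested.
#'
#' @param layer_counts Output of [count_by_layer()] stacked over images.
#' @param group_a,group_b Group labels to compare.
#' @param value `"count"` or `"rel_freq"`.
#' @param p_adjust Correction method (default `"none"`).
#' @return data.frame: `unit_name`, `cluster`, `U`, `p_value`, `p_adj`,
#'   `n_a`, `n_b`.
#' @export
layer_rank_tests <- function(layer_counts, group_a, group_b,
                             value = c("count", "rel_freq"),
                             p_adjust = "none") {
  value <- match.arg(value)
  sub <- layer_counts[layer_counts$group %in% c(group_a, group_b), ]
  combos <- unique(sub[, c("unit_name", "cluster")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    u <- combos$unit_name[i]; k <- combos$cluster[i]
    s <- sub[sub$unit_name == u & sub$cluster == k, ]
    xa <- s[[value]][s$group == group_a]
    xb <- s[[value]][s$group == group_b]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (!length(xa) || !length(xb)) next
    rt <- suppressWarnings(rank_test(xa, xb))
    rows[[length(rows) + 1L]] <- data.frame(
      unit_name = u, cluster = k, U = rt$U, p_value = rt$p_value,
      n_a = length(xa), n_b = length(xb), stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(unit_name = character(), cluster = integer(),
                      U = numeric(), p_value = numeric(), p_adj = numeric(),
                      n_a = integer(), n_b = integer()))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}
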