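#' Column z-score matrix for heatmap display
#'
#' Mean-centers and variance-scales each column, exactly as [autoscale()]
#' does for the regression, but returning the bare matrix of z-scores for
#' heatmap rendering. Zero-variance columns come back as all zeros.
#'
#' @param mat Numeric matrix (conditions x measurement columns).
#' @param sd_type `"sample"` (default) or `"population"` SD convention.
#' @return Matrix of z-scores with the input's dimnames.
#' @export
zscore_matrix <- function(mat, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  mat <- as.matrix(mat)
  s <- col_sds(mat, sd_type)
  s[s == 0] <- 1
  sweep(sweep(mat, 2, colMeans(mat)), 2, s, "/")
}

#' Hierarchical clustering order for heatmap axes
#'
#' Agglomerative clustering on Euclidean distances between rows (or
#' columns), as used to order signaling heatmaps so that similar conditions
#' and similar (protein, time) profiles sit together. Items are pre-sorted
#' by label before clustering so the result is deterministic and invariant
#' to the input row order.
#'
#' @param mat Numeric matrix with dimnames on the clustered axis.
#' @param axis `"rows"` (default) or `"columns"`.
#' @param method Linkage: `"average"` (default), `"complete"`, or
#'   `"single"`.
#' @return An object of class `cluster_ordering`: `axis`, `method`, `merge`
#'   (hclust merge matrix), `heights` (non-decreasing), `leaf_order`
#'   (labels in dendrogram order), `labels`.
#' @export
hierarchical_order <- function(mat, axis = c("rows", "columns"),
                               method = c("average", "complete", "single")) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  mat <- as.matrix(mat)
  if (axis == "columns") mat <- t(mat)
  if (nrow(mat) < 2) stop_contract("need at least 2 items on the clustered axis")
  if (anyNA(mat)) stop_contract("matrix contains missing values")
  labels <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  ord <- order(labels)
  mat <- mat[ord, , drop = FALSE]
  labels <- labels[ord]
  h <- stats::hclust(stats::dist(mat, method = "euclidean"), method = method)
  structure(list(axis = axis, method = method, merge = h$merge,
                 heights = h$height, leaf_order = labels[h$order],
                 labels = labels),
            class = "cluster_ordering")
}

#' @export
print.cluster_ordering <- function(x, ...) {
  cat(sprintf("<cluster_ordering> %s, %s linkage, %d leaves\n",
              x$axis, x$method, length(x$labels)))
  cat("  leaf order:", paste(utils::head(x$leaf_order, 8), collapse = ", "),
      if (length(x$leaf_order) > 8) "..." else "", "\n")
  invisible(x)
}

#' Serialize a cluster ordering to JSON
#'
#' @param ordering A `cluster_ordering`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_cluster_ordering <- function(ordering, path) {
  stopifnot(inherits(ordering, "cluster_ordering"))
  jsonlite::write_json(
    list(axis = ordering$axis, method = ordering$method,
         merge = ordering$merge, heights = ordering$heights,
         leaf_order = ordering$leaf_order, labels = ordering$labels),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
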