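#' Spectral (HSI) staging by 1-D hierarchical clustering
#'
#' Groups scalar interlimb-delta values (severity scores derived from
#' \eqn{\Delta}LWR) into `k` stages by agglomerative clustering with Ward
#' linkage on the 1-D Euclidean distances, cut at `k` clusters. Clusters are
#' relabeled in ascending order of their means, so for the default `k = 3`
#' the labels are `low`, `mid`, `high`. On well-separated scalar data Ward's
#' criterion recovers the optimal contiguous partition, so labels are
#' monotone in the value.
#'
#' @param values numeric vector with at least `k` distinct values.
#' @param k number of stages.
#' @param linkage `hclust` agglomeration method; `"ward.D2"` (default),
#'   `"complete"` or `"average"`.
#' @return An `hsi_staging` object: list with `values`, `labels` (ordered
#'   factor, ascending severity), `cluster_means` (ascending), `k`,
#'   `linkage`.
#' @export
hsi_stage <- function(values, k = 3L, linkage = c("ward.D2", "complete", "average")) {
  linkage <- match.arg(linkage)
  values <- as.numeric(values)
  if (anyNA(values)) stop("staging values must not contain NA")
  if (length(unique(values)) < k)
    stop("need at least k = ", k, " distinct values to form ", k, " stages")
  if (k == 1L) {
    cl <- rep(1L, length(values))
  } else {
    hc <- stats::hclust(stats::dist(values), method = linkage)
    cl <- stats::cutree(hc, k = k)
  }
  means <- tapply(values, cl, mean)
  ord <- order(means)                       # ascending cluster mean
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  stage_num <- relabel[cl]
  lvl <- if (k == 3L) c("low", "mid", "high") else paste0("stage", seq_len(k))
  structure(list(
    values = values,
    labels = factor(lvl[stage_num], levels = lvl, ordered = TRUE),
    cluster_means = as.numeric(sort(means)),
    k = k, linkage = linkage
  ), class = "hsi_staging")
}

#' @export
print.hsi_staging <- function(x, ...) {
  cat(sprintf("<hsi_staging> n=%d, k=%d (%s linkage)\n", length(x$values),
              x$k, x$linkage))
  print(table(x$labels))
  cat("cluster means:", paste(signif(x$cluster_means, 4), collapse = ", "), "\n")
  invisible(x)
}
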