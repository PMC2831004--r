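#' Euclidean distance matrix between node socialities
#'
#' Distances are computed on the posterior mean socialities (scalars), so
#' `D[i, j] = |alpha_mean_i - alpha_mean_j|`.
#'
#' @param summary a `p2_fit_summary`.
#' @return symmetric distance matrix with zero diagonal, dimnames = node
#'   IDs (in the summary's alpha-mean order).
#' @export
sociality_distance <- function(summary) {
  alpha <- summary$nodes$alpha_mean
  names(alpha) <- summary$nodes$id
  as.matrix(stats::dist(alpha, method = "euclidean"))
}

#' Complete-linkage hierarchical clustering of a distance matrix
#'
#' Standard agglomerative clustering where the distance between two
#' clusters is the maximum pairwise distance across them, so merge
#' heights are non-decreasing.
#'
#' @param dist symmetric distance matrix (or `dist` object).
#' @return an `hclust` object (merge sequence + heights).
#' @export
complete_linkage <- function(dist) {
  d <- stats::as.dist(dist)
  if (attr(d, "Size") < 2L) stop("need at least 2 points to cluster")
  stats::hclust(d, method = "complete")
}

#' Cut a dendrogram into k sociality clusters
#'
#' Undoes the last k-1 merges. When mean socialities are supplied the
#' clusters are renumbered so that cluster 1 has the highest mean
#' sociality (and hence, in a well-fitted model, the highest degrees),
#' mirroring the convention of labelling the "very high"-connectivity
#' group first.
#'
#' @param merges an `hclust` object from [complete_linkage()].
#' @param k number of clusters, 1 <= k <= n; default 5.
#' @param alpha optional named vector of mean socialities (names = the
#'   clustered node IDs) used to order cluster labels.
#' @return named integer vector: node -> cluster label in 1..k.
#' @export
cut_clusters <- function(merges, k = 5, alpha = NULL) {
  n <- length(merges$labels)
  if (k < 1L || k > n) stop("k must be between 1 and ", n)
  labels <- stats::cutree(merges, k = k)
  if (!is.null(alpha)) {
    means <- tapply(alpha[names(labels)], labels, mean)
    remap <- integer(k)
    remap[as.integer(names(sort(means, decreasing = TRUE)))] <- seq_len(k)
    labels <- stats::setNames(remap[labels], names(labels))
  }
  labels
}

#' Structural summary of a clustering: sizes, degree ranges, flows
#'
#' Reports, per cluster, its size and the range of node degrees it
#' contains, and the flow matrix: the percentage of all network edges
#' running between each pair of clusters (within-cluster edges on the
#' diagonal). All entries sum to 100.
#'
#' @param labels named node -> cluster vector covering all network nodes.
#' @param net the `p2_network`.
#' @param summary optional `p2_fit_summary` used to report each
#'   cluster's mean sociality.
#' @return an object of class `p2_clusters` with components `clusters`
#'   (data frame: cluster, size, degree_min, degree_max, alpha_mean) and
#'   `flows` (k x k percentage matrix).
#' @export
cluster_report <- function(labels, net, summary = NULL) {
  miss <- setdiff(net$nodes, names(labels))
  if (length(miss)) {
    stop("labels missing for node(s): ", paste(miss, collapse = ", "))
  }
  ks <- sort(unique(labels))
  deg <- degree_sequence(net)
  clusters <- do.call(rbind, lapply(ks, function(k) {
    ids <- names(labels)[labels == k]
    data.frame(cluster = k, size = length(ids),
               degree_min = min(deg[ids]), degree_max = max(deg[ids]))
  }))
  if (!is.null(summary)) {
    am <- stats::setNames(summary$nodes$alpha_mean, summary$nodes$id)
    clusters$alpha_mean <- vapply(ks, function(k) {
      mean(am[names(labels)[labels == k]])
    }, numeric(1))
  }
  flows <- matrix(0, length(ks), length(ks),
                  dimnames = list(ks, ks))
  if (nrow(net$edges)) {
    ca <- labels[net$edges[, 1L]]
    cb <- labels[net$edges[, 2L]]
    lo <- pmin(ca, cb)
    hi <- pmax(ca, cb)
    tab <- table(factor(lo, levels = ks), factor(hi, levels = ks))
    flows[] <- as.numeric(tab) / nrow(net$edges) * 100
  }
  structure(list(clusters = clusters, flows = flows),
            class = "p2_clusters")
}

#' @export
print.p2_clusters <- function(x, ...) {
  cat("p2 sociality clusters:\n")
  print(x$clusters, digits = 3)
  cat("flows (% of edges):\n")
  print(round(x$flows, 1))
  invisible(x)
}

#' Write cluster summary and flow tables to CSV
#'
#' Emits `cluster_summary.csv` (cluster, size, degree_min, degree_max)
#' and `flows.csv` (cluster_a, cluster_b, percent) under `dir`.
#'
#' @param result a `p2_clusters` object.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_clusters <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$clusters,
                   file.path(dir, "cluster_summary.csv"), row.names = FALSE)
  ks <- rownames(result$flows)
  idx <- which(upper.tri(result$flows, diag = TRUE), arr.ind = TRUE)
  flows <- data.frame(cluster_a = ks[idx[, 1L]], cluster_b = ks[idx[, 2L]],
                      percent = result$flows[idx])
  utils::write.csv(flows, file.path(dir, "flows.csv"), row.names = FALSE)
  invisible(dir)
}
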