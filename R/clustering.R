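# k-means++ seeding: first centre uniform, subsequent centres sampled with
# probability proportional to squared distance to the nearest chosen centre.
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1, prob = probs), ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

#' Cluster gene variability profiles by k-means
#'
#' Rows are genes, columns the per-group LCV scores; profiles are clustered
#' on the raw 0-100 scale (already bounded and comparable, so no row
#' standardization). Lloyd's algorithm with k-means++ seeding, best of
#' `n_restarts` by total within-cluster sum of squares. Genes with any NA
#' score are excluded. Labels are renumbered by descending cluster mean LCV
#' so that the same input and seed always yield identical assignments.
#'
#' @param lcv Gene x group LCV matrix.
#' @param k Number of clusters (default 10).
#' @param seed Integer seed.
#' @param n_restarts Independent k-means++ starts (default 10).
#' @return List of class `lcv_clusters`: `cluster` (named integer labels),
#'   `k`, `sizes`, `centers` (k x groups), `tot_withinss`, `excluded`
#'   (gene ids dropped for NA scores), `seed`, `n_restarts`.
#' @export
kmeans_cluster <- function(lcv, k = 10L, seed = 1L, n_restarts = 10L) {
  if (k < 2) stop("k must be >= 2")
  complete <- rowSums(is.na(lcv)) == 0
  x <- lcv[complete, , drop = FALSE]
  if (k > nrow(x)) stop("k (", k, ") exceeds number of scored genes (", nrow(x), ")")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- tryCatch(
      suppressWarnings(kmeans(x, centers = .kmeanspp_centers(x, k),
                              algorithm = "Lloyd", iter.max = 100L)),
      error = function(e) NULL)  # duplicate seeds on degenerate data
    if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss))
      best <- fit
  }
  if (is.null(best))
    stop("k-means degenerate: could not place ", k, " distinct centres")
  # deterministic label order: descending mean LCV of the cluster centre
  ord <- order(rowMeans(best$centers), decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  labels <- relabel[best$cluster]
  names(labels) <- rownames(x)
  structure(list(cluster = labels, k = as.integer(k),
                 sizes = tabulate(labels, k),
                 centers = best$centers[ord, , drop = FALSE],
                 tot_withinss = best$tot.withinss,
                 excluded = rownames(lcv)[!complete],
                 seed = as.integer(seed), n_restarts = as.integer(n_restarts)),
            class = "lcv_clusters")
}

#' Mean silhouette width across candidate cluster numbers
#'
#' Runs [kmeans_cluster()] for each k and computes the mean silhouette
#' width (silhouette of point i = (b - a)/max(a, b), with a the mean
#' intra-cluster distance and b the smallest mean distance to another
#' cluster, Euclidean). Used to verify the chosen number of clusters.
#'
#' @param lcv Gene x group LCV matrix.
#' @param k_range Integer vector of candidate k (default 2:15).
#' @param seed Integer seed.
#' @param n_restarts Restarts per k.
#' @return Data frame `k`, `mean_silhouette` with attribute `selected_k`
#'   (the k attaining the maximum; ties go to the smallest k). A k whose
#'   fit degenerates to a single non-empty cluster is reported NA.
#' @export
silhouette_scan <- function(lcv, k_range = 2:15, seed = 1L, n_restarts = 5L) {
  complete <- rowSums(is.na(lcv)) == 0
  x <- lcv[complete, , drop = FALSE]
  if (any(k_range < 2) || any(k_range > nrow(x) - 1))
    stop("k_range must lie within [2, genes - 1]")
  d <- dist(x)
  width <- vapply(k_range, function(k) {
    cl <- tryCatch(
      kmeans_cluster(lcv, k = k, seed = seed, n_restarts = n_restarts)$cluster,
      error = function(e) NULL)
    if (is.null(cl) || length(unique(cl)) < 2) return(NA_real_)
    sil <- cluster::silhouette(as.integer(cl[rownames(x)]), d)
    mean(sil[, "sil_width"])
  }, numeric(1))
  out <- data.frame(k = as.integer(k_range), mean_silhouette = width)
  sel <- if (all(is.na(width))) NA_integer_ else
    out$k[which(out$mean_silhouette == max(out$mean_silhouette, na.rm = TRUE))[1]]
  attr(out, "selected_k") <- sel
  out
}

#' Row/column ordering and column dendrogram for a heatmap
#'
#' Rows are grouped by cluster (clusters in label order) and, within a
#' cluster, ordered by average-linkage hierarchical clustering of the
#' profiles. Columns (groups) are ordered by average-linkage hierarchical
#' clustering on Euclidean distances between group LCV profiles; the column
#' dendrogram is also returned serialized in Newick format, so that the
#' grouping of its tips (e.g. pairing of cross-types by maternal morph) can
#' be inspected.
#'
#' @param lcv Gene x group LCV matrix.
#' @param clusters [kmeans_cluster()] result.
#' @return List: `row_order`, `col_order` (character id vectors),
#'   `col_hclust` (the `hclust` object) and `col_newick` (string).
#' @export
order_for_heatmap <- function(lcv, clusters) {
  stopifnot(inherits(clusters, "lcv_clusters"))
  x <- lcv[names(clusters$cluster), , drop = FALSE]
  row_order <- unlist(lapply(seq_len(clusters$k), function(cl) {
    ids <- names(clusters$cluster)[clusters$cluster == cl]
    if (length(ids) > 2) {
      hc <- hclust(dist(x[ids, , drop = FALSE]), method = "average")
      ids <- ids[hc$order]
    }
    ids
  }), use.names = FALSE)
  col_hc <- hclust(dist(t(x)), method = "average")
  phy <- ape::as.phylo(col_hc)
  list(row_order = row_order,
       col_order = colnames(x)[col_hc$order],
       col_hclust = col_hc,
       col_newick = ape::write.tree(phy))
}

#' Test whether the column dendrogram pairs cross-types by maternal morph
#'
#' The qualitative signature of strong maternal effects on expression
#' variability: within each time point, the hybrid with a limnetic mother
#' (PLxSB) is a dendrogram sibling of the pure limnetic cross (PLxPL), and
#' the benthic-mothered hybrid (SBxPL) of the pure benthic cross (SBxSB).
#'
#' @param col_hclust Column `hclust` from [order_for_heatmap()].
#' @return TRUE when every PL-mothered group's nearest-merging partner among
#'   the groups of its time point shares the maternal morph.
#' @export
maternal_pairing <- function(col_hclust) {
  labs <- col_hclust$labels
  co <- stats::cophenetic(col_hclust)
  cm <- as.matrix(co)
  ok <- TRUE
  for (lab in labs) {
    tp <- sub("^.*_", "", lab)
    mates <- setdiff(labs[endsWith(labs, paste0("_", tp))], lab)
    if (!length(mates)) next
    nearest <- mates[which.min(cm[lab, mates])]
    ok <- ok && substr(nearest, 1, 2) == substr(lab, 1, 2)
  }
  ok
}
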