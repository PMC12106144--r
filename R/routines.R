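#' Cluster daily routines with k-means
#'
#' Groups (user, day) dedication vectors into k routine archetypes with seeded
#' k-means and grades the partition with the mean silhouette width under
#' Euclidean distance. Raw percentages are clustered by default; standardized
#' features (per-activity z-scores) are available as an option.
#'
#' @param table a `dedication_table` with at least k rows.
#' @param k number of clusters, `2 <= k <= nrow(table)`.
#' @param seed integer seed for centroid initialization.
#' @param standardize cluster per-activity z-scores instead of raw
#'   percentages.
#' @param nstart random restarts for k-means.
#' @return A `clustering_result`: `k`, `labels` (data.frame user, day,
#'   cluster), `centroids` (k x t, original scale), `silhouette`.
#' @export
cluster_routines <- function(table, k, seed = 1L, standardize = FALSE,
                             nstart = 10) {
  m <- dedication_matrix(table)
  if (k > nrow(m)) stop("k exceeds the number of user-days")
  if (k < 2) stop("k must be >= 2")
  feats <- if (standardize) {
    sds <- apply(m, 2, stats::sd); sds[sds == 0] <- 1
    scale(m, scale = sds)
  } else m
  set.seed(seed)
  if (k == nrow(m)) {
    warning("k equals the number of rows: every day is its own cluster")
    km <- list(cluster = seq_len(k), centers = feats, tot.withinss = 0)
  } else {
    km <- stats::kmeans(feats, centers = k, nstart = nstart, iter.max = 100)
  }
  sil <- if (k < nrow(m)) {
    mean(cluster::silhouette(km$cluster, stats::dist(feats))[, "sil_width"])
  } else NA_real_
  centroids <- do.call(rbind, lapply(seq_len(k), function(j) {
    colMeans(m[km$cluster == j, , drop = FALSE])
  }))
  structure(list(k = k,
                 labels = data.frame(user = table$user, day = table$day,
                                     cluster = km$cluster,
                                     stringsAsFactors = FALSE),
                 centroids = centroids, silhouette = sil,
                 withinss = km$tot.withinss, standardize = standardize),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("k-means routines: k = %d, silhouette %.3f\n",
              x$k, x$silhouette))
  invisible(x)
}

#' Choose k by silhouette over a grid
#'
#' Runs [cluster_routines()] for each k and returns the silhouette-maximizing
#' clustering together with the grid table.
#'
#' @param table a `dedication_table`.
#' @param ks candidate cluster counts (default 2..10).
#' @param seed,standardize passed through.
#' @return list with `best` (a `clustering_result`) and `grid` (data.frame k,
#'   silhouette).
#' @export
select_k <- function(table, ks = 2:10, seed = 1L, standardize = FALSE) {
  ks <- ks[ks <= nrow(table)]
  fits <- lapply(ks, cluster_routines, table = table, seed = seed,
                 standardize = standardize)
  sil <- vapply(fits, function(f) f$silhouette, 0)
  list(best = fits[[which.max(sil)]],
       grid = data.frame(k = ks, silhouette = sil))
}

#' Write cluster assignments and centroids to CSV
#' @param result a `clustering_result`.
#' @param assignments_path CSV `user,day,cluster`.
#' @param centroids_path CSV with one row per centroid and activity columns.
#' @export
write_clustering_csv <- function(result, assignments_path, centroids_path) {
  lab <- result$labels
  lab$day <- format(lab$day, "%Y-%m-%d")
  utils::write.csv(lab, assignments_path, row.names = FALSE, quote = FALSE)
  cent <- data.frame(cluster = seq_len(result$k),
                     round(result$centroids, 4), check.names = FALSE)
  utils::write.csv(cent, centroids_path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
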