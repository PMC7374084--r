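# Unsupervised k-means segmentation of preprocessed images into
# histology-like clusters, with color-coded maps (eliminated pixels
# rendered white), centroid spectra and a Ward dendrogram over centroids.

#' k-means over a matrix of spectra
#'
#' Seeded, best-of-restarts k-means with Euclidean distance; deterministic
#' for fixed `(seed, n_restarts)`.
#'
#' @param X numeric matrix, one spectrum per row.
#' @param k number of clusters (2 <= k <= number of distinct rows).
#' @param seed integer seed.
#' @param n_restarts number of random restarts; the lowest-inertia
#'   solution is kept.
#' @param iter_max maximum iterations per restart.
#' @return a `stats::kmeans` result.
#' @export
kmeans_spectra <- function(X, k, seed = 1L, n_restarts = 10L, iter_max = 300L) {
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > nrow(unique(X)))
    stop("k exceeds the number of distinct spectra", call. = FALSE)
  withr::with_seed(seed, {
    # Hartigan-Wong can fail on degenerate (duplicate-heavy) data; fall
    # back to Lloyd deterministically in that case
    tryCatch(
      withCallingHandlers(
        stats::kmeans(X, centers = k, nstart = n_restarts,
                      iter.max = iter_max),
        warning = function(w) {
          if (grepl("Quick-TRANSfer", conditionMessage(w)))
            stop("hartigan-wong degenerate case")
        }),
      error = function(e)
        withCallingHandlers(
          stats::kmeans(X, centers = k, nstart = n_restarts,
                        iter.max = iter_max, algorithm = "Lloyd"),
          # an unlucky restart may leave a cluster empty; the best
          # restart still wins, so this is not actionable
          warning = function(w) {
            if (grepl("empty cluster", conditionMessage(w)))
              invokeRestart("muffleWarning")
          }))
  })
}

#' Segment a preprocessed image by k-means
#'
#' Clusters the valid fingerprint pixel spectra into `k` groups. The
#' number of groups typically explored ranges from 3 to 11; the most
#' representative class number is a user decision after a sweep.
#'
#' @param img a `preprocessed_image` or [hyper_image()].
#' @param k number of clusters.
#' @param seed integer seed.
#' @param n_restarts restarts (default 10).
#' @return object of class `cluster_map`: `labels` (height x width
#'   integer matrix, `NA` on excluded pixels), `k`, `centroids` (k x
#'   bands), `sizes`, `inertia` (total within-cluster sum of squares),
#'   `excluded_mask`, `palette` (hex color per cluster), `wavenumber`.
#' @export
kmeans_segment <- function(img, k, seed = 1L, n_restarts = 10L) {
  if (inherits(img, "preprocessed_image")) img <- img$image
  stopifnot(inherits(img, "hyper_image"))
  px <- as_spectra_matrix(img)
  km <- kmeans_spectra(px$spectra, k, seed = seed, n_restarts = n_restarts)
  d <- dim(img$cube)
  labels <- matrix(NA_integer_, d[1L], d[2L])
  labels[cbind(px$coords$row, px$coords$col)] <- km$cluster
  palette <- grDevices::hcl(h = seq(15, 375, length.out = k + 1L)[-(k + 1L)],
                            c = 100, l = 60)
  structure(list(labels = labels, k = as.integer(k),
                 centroids = unname(km$centers), sizes = unname(km$size),
                 inertia = km$tot.withinss,
                 excluded_mask = !img$valid_mask,
                 palette = palette, wavenumber = img$wavenumber,
                 seed = as.integer(seed), n_restarts = as.integer(n_restarts)),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("<cluster_map> k = %d, sizes: %s, inertia = %.4g\n",
              x$k, paste(x$sizes, collapse = "/"), x$inertia))
  invisible(x)
}

#' Sweep k-means over a grid of cluster counts
#'
#' @param img a `preprocessed_image` or [hyper_image()].
#' @param k_grid integer vector of cluster counts (default 3:11).
#' @param seed,n_restarts passed to [kmeans_segment()].
#' @return named list of `cluster_map` objects, one per k.
#' @export
kmeans_sweep <- function(img, k_grid = 3:11, seed = 1L, n_restarts = 10L) {
  out <- lapply(k_grid, function(k)
    kmeans_segment(img, k, seed = seed, n_restarts = n_restarts))
  names(out) <- paste0("k", k_grid)
  out
}

#' Ward dendrogram over cluster centroids
#'
#' Agglomerative Ward linkage over the Euclidean distances between the k
#' centroid spectra, visualizing cluster heterogeneity; exactly k - 1
#' merges.
#'
#' @param cm a `cluster_map` with k >= 2.
#' @return object of class `centroid_dendrogram`: `hclust` (the tree),
#'   `merges` (merge pairs with heights), `leaf_order`.
#' @export
centroid_dendrogram <- function(cm) {
  stopifnot(inherits(cm, "cluster_map"), cm$k >= 2L)
  hc <- stats::hclust(stats::dist(cm$centroids), method = "ward.D2")
  structure(list(hclust = hc,
                 merges = data.frame(node_a = hc$merge[, 1L],
                                     node_b = hc$merge[, 2L],
                                     height = hc$height),
                 leaf_order = hc$order),
            class = "centroid_dendrogram")
}

#' Export a centroid dendrogram as newick
#'
#' @param cd a [centroid_dendrogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(cd, path) {
  stopifnot(inherits(cd, "centroid_dendrogram"))
  phy <- ape::as.phylo(cd$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Render a cluster map as an RGB image
#'
#' One distinct color per cluster; excluded (eliminated-paraffin) pixels
#' are rendered pure white.
#'
#' @param cm a `cluster_map`.
#' @param path optional PNG output path.
#' @return the height x width x 3 RGB array (values in 0..1), invisibly
#'   if `path` is given.
#' @export
render_cluster_map <- function(cm, path = NULL) {
  stopifnot(inherits(cm, "cluster_map"))
  d <- dim(cm$labels)
  rgb <- array(1, c(d, 3L))
  cols <- grDevices::col2rgb(cm$palette) / 255
  for (i in seq_len(cm$k)) {
    sel <- which(cm$labels == i)
    if (length(sel))
      for (ch in 1:3) rgb[sel + (ch - 1L) * prod(d)] <- cols[ch, i]
  }
  if (!is.null(path)) {
    png::writePNG(rgb, path)
    return(invisible(rgb))
  }
  rgb
}

#' Extract member-pixel spectra of selected clusters
#'
#' Returns all and only the spectra of pixels belonging to the selected
#' clusters, with their image coordinates retained so they can be
#' retrieved on the digital maps at any time.
#'
#' @param img the segmented `preprocessed_image` or [hyper_image()].
#' @param cm the `cluster_map`.
#' @param cluster_ids integer set within `1..k`.
#' @return list with `spectra` (n x bands matrix) and `coords`
#'   (data.frame `row`, `col`, `cluster`).
#' @export
extract_cluster_spectra <- function(img, cm, cluster_ids) {
  if (inherits(img, "preprocessed_image")) img <- img$image
  stopifnot(inherits(cm, "cluster_map"))
  if (!all(cluster_ids %in% seq_len(cm$k)))
    stop("cluster_ids must lie in 1..k", call. = FALSE)
  px <- as_spectra_matrix(img)
  lab <- cm$labels[cbind(px$coords$row, px$coords$col)]
  sel <- which(lab %in% cluster_ids)
  if (!length(sel)) warning("selected clusters contain no pixels")
  list(spectra = px$spectra[sel, , drop = FALSE],
       coords = data.frame(px$coords[sel, , drop = FALSE],
                           cluster = lab[sel], row.names = NULL))
}

#' Adjusted Rand index between a segmentation and ground truth
#'
#' Chance-corrected partition agreement on the common pixel domain
#' (pixels labeled in both partitions); 1 iff the partitions are
#' identical up to relabeling.
#'
#' @param labels a `cluster_map` or a label matrix (`NA` = unlabeled).
#' @param truth a `ground_truth` or a label matrix of the same size.
#' @return ARI in `[-1, 1]`.
#' @export
segmentation_quality <- function(labels, truth) {
  a <- if (inherits(labels, "cluster_map")) labels$labels else labels
  b <- if (inherits(truth, "ground_truth")) truth$labels else truth
  if (!all(dim(a) == dim(b)))
    stop("segmentation and ground truth domains differ", call. = FALSE)
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) stop("no common labeled pixels", call. = FALSE)
  r <- mclust::adjustedRandIndex(as.vector(a[keep]), as.vector(b[keep]))
  if (is.nan(r)) {
    # degenerate 0/0 case (e.g. two all-singleton partitions): score by
    # whether the partitions correspond one-to-one
    tab <- table(as.vector(a[keep]), as.vector(b[keep]))
    one_to_one <- all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
    r <- if (one_to_one) 1 else 0
  }
  r
}

#' Assign clusters to histology classes by ground-truth overlap
#'
#' Synthetic-scene stand-in for reference-image plus pathologist
#' assignment: each cluster is assigned the majority ground-truth label
#' among its member pixels.
#'
#' @param cm a `cluster_map`.
#' @param truth a `ground_truth` for the same scene.
#' @return named character vector, cluster id -> histology label.
#' @export
assign_clusters <- function(cm, truth) {
  stopifnot(inherits(cm, "cluster_map"), inherits(truth, "ground_truth"))
  keep <- !is.na(cm$labels)
  tab <- table(cluster = cm$labels[keep], histology = truth$labels[keep])
  out <- colnames(tab)[apply(tab, 1L, which.max)]
  names(out) <- rownames(tab)
  stats::setNames(out[as.character(seq_len(cm$k))],
                  as.character(seq_len(cm$k)))
}
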