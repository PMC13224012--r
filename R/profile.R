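#' Z-score normalize a profile matrix
#'
#' Centers each column to mean 0 and scales to unit population SD
#' (`sqrt(mean((x - mean(x))^2))`). Zero-variance columns are dropped
#' and reported.
#'
#' @param profiles numeric matrix or data.frame (rows = images).
#' @param tol variance tolerance below which a column counts as
#'   constant.
#' @return list with `normalized` (matrix) and `dropped` (character
#'   vector of removed columns).
#' @export
zscore_normalize <- function(profiles, tol = 1e-12) {
  x <- as.matrix(profiles)
  if (nrow(x) < 2) stop_ms("need at least 2 rows to normalize")
  mu <- colMeans(x)
  sdp <- sqrt(colMeans(sweep(x, 2, mu)^2))
  keep <- which(sdp > tol & !is.na(sdp))
  dropped <- colnames(x)[setdiff(seq_len(ncol(x)), keep)]
  z <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sdp[keep], "/")
  list(normalized = z, dropped = dropped)
}

#' Principal-component embedding of normalized profiles
#'
#' PCA via singular value decomposition of the column-centered matrix;
#' components are the eigenvectors of the sample covariance. Sign
#' convention: within each component the largest-magnitude loading is
#' positive. `variance_explained` are fractions of total variance, so
#' they sum to 1 over the full rank.
#'
#' @param x normalized numeric matrix (rows = images).
#' @param k number of components (truncated to the rank, with a
#'   warning, if too large).
#' @return object of class `PcaResult`: `scores` (n x k), `loadings`
#'   (p x k), `variance_explained` (length k), `center`,
#'   `all_variance_explained`.
#' @export
pca_embed <- function(x, k = 2L) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 1) stop_ms("need >= 2 rows and >= 1 column")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ve_all <- pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-12)
  if (k > rank) {
    warning("k = ", k, " exceeds rank ", rank, "; truncated")
    k <- rank
  }
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    sgn <- sign(load[which.max(abs(load[, j])), j])
    if (sgn < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  structure(list(scores = scores, loadings = load,
                 variance_explained = ve_all[seq_len(k)],
                 all_variance_explained = ve_all,
                 center = pc$center,
                 dropped_features = attr(x, "dropped") %||% character(0)),
            class = "PcaResult")
}

#' @export
print.PcaResult <- function(x, ...) {
  cat("PcaResult:", nrow(x$scores), "images x", ncol(x$scores),
      "components\n  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      "\n")
  invisible(x)
}

#' Rank feature-family contributions to the leading components
#'
#' Per family: the sum of squared loadings over PC1--PC2 (or fewer if
#' the embedding has fewer), normalized to sum 1 across families and
#' ranked descending.
#'
#' @param pca a [pca_embed()] result.
#' @param manifest the [feature_manifest()] covering the loaded
#'   features.
#' @return data.frame with `family`, `contribution` columns, descending.
#' @export
rank_family_contributions <- function(pca, manifest) {
  feats <- rownames(pca$loadings)
  missing <- setdiff(feats, manifest$name)
  if (length(missing))
    stop_ms("features absent from manifest: ",
            paste(head(missing, 5), collapse = ", "))
  fam <- manifest$family[match(feats, manifest$name)]
  kk <- seq_len(min(2L, ncol(pca$loadings)))
  w <- rowSums(pca$loadings[, kk, drop = FALSE]^2)
  contrib <- tapply(w, fam, sum)
  contrib <- contrib / sum(contrib)
  out <- data.frame(family = names(contrib),
                    contribution = as.numeric(contrib))
  out <- out[order(-out$contribution), ]
  rownames(out) <- NULL
  out
}

#' Hierarchical clustering of profiles with heatmap ordering
#'
#' Agglomerative clustering (default: average linkage on the
#' correlation distance `1 - PCC` between rows); returns the merge
#' history, the dendrogram leaf order and the input matrix reordered
#' accordingly.
#'
#' @param x numeric matrix (rows = groups or images).
#' @param distance `"correlation"` (1 - Pearson between rows) or
#'   `"euclidean"`.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return list with `hclust`, `order`, `matrix` (reordered), `newick`
#'   (dendrogram as a Newick string).
#' @export
cluster_heatmap <- function(x, distance = c("correlation", "euclidean"),
                            linkage = "average") {
  x <- as.matrix(x)
  distance <- match.arg(distance)
  if (nrow(x) < 2) stop_ms("need at least 2 rows to cluster")
  if (is.null(rownames(x))) rownames(x) <- paste0("row", seq_len(nrow(x)))
  if (distance == "correlation") {
    sds <- apply(x, 1, sd)
    if (any(sds == 0))
      stop_ms("constant row(s) under correlation distance: ",
              paste(rownames(x)[sds == 0], collapse = ", "),
              "; use distance = \"euclidean\"")
    d <- as.dist(1 - cor(t(x)))
  } else {
    d <- dist(x)
  }
  hc <- hclust(d, method = linkage)
  nw <- tryCatch(ape::write.tree(ape::as.phylo(hc)),
                 error = function(e) NA_character_)
  list(hclust = hc, order = hc$order,
       matrix = x[hc$order, , drop = FALSE], newick = nw)
}

#' Mean silhouette width of a 2-group split in an embedding
#'
#' Convenience wrapper around [cluster::silhouette()] on Euclidean
#' distances between embedding coordinates, used to measure how well
#' two treatment-group sets separate in PC1--PC2.
#'
#' @param scores numeric matrix of embedding coordinates.
#' @param labels grouping vector (2 levels).
#' @return mean silhouette width.
#' @export
silhouette_separation <- function(scores, labels) {
  f <- as.integer(factor(labels))
  if (length(unique(f)) < 2) stop_ms("need two groups")
  sil <- cluster::silhouette(f, dist(scores))
  mean(sil[, "sil_width"])
}
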