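#' Scatter plot of PCA scores colored by treatment group
#'
#' Base-graphics PC1/PC2 plot of per-image profiles, axes annotated
#' with the percentage of variance explained.
#'
#' @param pca a [pca_embed()] result.
#' @param groups grouping vector, one entry per score row.
#' @param main plot title.
#' @export
plot_pca_scores <- function(pca, groups, main = "Per-image profiles") {
  g <- factor(groups)
  cols <- grDevices::hcl.colors(nlevels(g), "Dark 3")
  ve <- 100 * pca$variance_explained
  graphics::plot(pca$scores[, 1], pca$scores[, 2], col = cols[g], pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", ve[1]),
                 ylab = sprintf("PC2 (%.1f%%)", ve[2]), main = main)
  graphics::legend("topright", legend = levels(g), col = cols, pch = 19,
                   cex = 0.8, bty = "n")
}

#' Violin-style summary of per-image coupling correlations
#'
#' Boxplot of per-image Pearson r values per group with the group mean
#' marked by a red line, mirroring the conventional violin/box display
#' of coupling distributions under treatment.
#'
#' @param coupling result of [coupling_profile()].
#' @param pair which correlation pair to show.
#' @export
plot_coupling_violin <- function(coupling, pair = "MMP-mtROS") {
  keys <- names(coupling$per_image)
  keep <- grepl(paste0("\\|", pair, "$"), keys)
  vals <- coupling$per_image[keep]
  if (length(vals) == 0) stop_ms("no per-image correlations for ", pair)
  names(vals) <- sub("\\|[^|]+$", "", names(vals))
  graphics::boxplot(vals, las = 2, ylab = "PCC (r), per image",
                    main = paste("Coupling:", pair), cex.axis = 0.7)
  mns <- vapply(vals, mean, 0)
  graphics::segments(seq_along(mns) - 0.35, mns, seq_along(mns) + 0.35, mns,
                     col = "red", lwd = 2)
}

#' Clustered heatmap of group profiles
#'
#' Renders the reordered matrix of [cluster_heatmap()]; uses `pheatmap`
#' when installed, else base [graphics::image()].
#'
#' @param ch a [cluster_heatmap()] result.
#' @param main title.
#' @export
plot_heatmap <- function(ch, main = "Group profiles") {
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(ch$matrix, cluster_rows = FALSE, cluster_cols = FALSE,
                       main = main, show_colnames = ncol(ch$matrix) <= 50)
  } else {
    graphics::image(t(ch$matrix[rev(seq_len(nrow(ch$matrix))), ]),
                    main = main, axes = FALSE)
  }
}
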