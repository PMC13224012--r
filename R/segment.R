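#' Segment nuclei from the Hoechst channel
#'
#' Gaussian smoothing, automatic (Otsu) or fixed thresholding, removal
#' of small objects and optional watershed splitting of touching nuclei
#' on the distance transform. Labels are renumbered contiguously
#' 1..K. Coordinates throughout the package are (row, column),
#' 0-based in exported tables.
#'
#' @param hoechst single-channel numeric matrix.
#' @param smooth_sigma Gaussian smoothing sigma in px.
#' @param threshold `"otsu"` or a fixed numeric threshold in counts.
#' @param min_area minimum object area in px; smaller objects removed.
#' @param split split touching objects by watershed on the distance
#'   transform.
#' @param exclude_border drop objects touching the field border
#'   (default FALSE: edge objects kept).
#' @return integer label matrix (`LabelMap`), 0 = background. A blank
#'   image yields an empty map.
#' @export
segment_nuclei <- function(hoechst, smooth_sigma = 2, threshold = "otsu",
                           min_area = 50L, split = TRUE,
                           exclude_border = FALSE) {
  stopifnot(is.matrix(hoechst))
  empty <- matrix(0L, nrow(hoechst), ncol(hoechst))
  if (is_blank(hoechst)) return(empty)
  img <- hoechst / 65535
  if (smooth_sigma > 0)
    img <- ebi_mat(EBImage::gblur(EBImage::Image(img), sigma = smooth_sigma))
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(img), range = range(img), levels = 256L)
  } else {
    as.numeric(threshold) / 65535
  }
  bin <- img > thr
  if (!any(bin)) return(empty)
  lab <- if (split) {
    dm <- EBImage::distmap(EBImage::Image(bin * 1))
    ebi_mat(EBImage::watershed(dm, tolerance = 1, ext = 1))
  } else {
    ebi_mat(EBImage::bwlabel(EBImage::Image(bin * 1)))
  }
  storage.mode(lab) <- "integer"
  lab <- .filter_objects(lab, min_area, exclude_border)
  renumber_labels(lab)
}

.filter_objects <- function(lab, min_area, exclude_border) {
  nlab <- max(lab)
  if (nlab == 0) return(lab)
  areas <- label_areas(lab, nlab)
  drop <- which(areas < min_area)
  if (exclude_border) {
    edge <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    drop <- union(drop, edge[edge > 0])
  }
  if (length(drop)) lab[lab %in% drop] <- 0L
  lab
}

#' Expand nuclei to cell bodies
#'
#' Seeded propagation (CellProfiler-style secondary-object
#' identification) from each nucleus over a guide channel, restricted to
#' foreground pixels within `max_distance` of the nucleus set. Each cell
#' keeps its seed's label; cells are disjoint and contain their nucleus.
#'
#' @param nuclei nucleus label matrix (possibly empty).
#' @param guide single-channel numeric matrix (e.g. the whole-cell ROS
#'   stain) guiding the expansion.
#' @param max_distance maximum expansion in px from the nucleus
#'   boundary; 0 returns the nucleus map unchanged.
#' @param fg_threshold `"bg3mad"` (default: median + 3 MAD of the guide,
#'   a robust background-based cutoff that keeps dim cells), `"otsu"`, a
#'   fixed numeric value in counts, or `NA` to disable foreground gating
#'   (expansion limited by distance only; also the automatic behavior on
#'   a uniform guide).
#' @param lambda regularization of [EBImage::propagate()] balancing
#'   image gradient against Euclidean distance.
#' @return integer cell label matrix aligned with `nuclei`.
#' @export
expand_to_cells <- function(nuclei, guide, max_distance = 20,
                            fg_threshold = "bg3mad", lambda = 1e-4) {
  if (!all(dim(nuclei) == dim(guide)))
    stop_ms("nuclei map and guide image have different shapes")
  if (max(nuclei) == 0 || max_distance <= 0) return(nuclei)
  img <- guide / 65535
  fg <- if (is.na(fg_threshold[1]) || is_blank(guide)) {
    matrix(TRUE, nrow(guide), ncol(guide))
  } else if (identical(fg_threshold, "otsu")) {
    img > EBImage::otsu(EBImage::Image(img), range = range(img), levels = 256L)
  } else if (identical(fg_threshold, "bg3mad")) {
    guide > median(guide) + 3 * mad(guide)
  } else {
    guide > as.numeric(fg_threshold)
  }
  ## distance from each background pixel to the nearest nucleus pixel
  d <- ebi_mat(EBImage::distmap(EBImage::Image((nuclei == 0) * 1)))
  mask <- (fg & d <= max_distance) | nuclei > 0
  lab <- EBImage::propagate(EBImage::Image(img),
                            seeds = EBImage::Image(nuclei),
                            mask = EBImage::Image(mask * 1), lambda = lambda)
  lab <- ebi_mat(lab)
  storage.mode(lab) <- "integer"
  lab
}

#' Segment mitochondria within cells
#'
#' White top-hat filtering with a disc structuring element followed by a
#' per-cell automatic threshold; the mask is intersected with its parent
#' cell and labeled by the parent-cell label.
#'
#' @param mmp mitochondria-marking channel (e.g. the MMP/TMRE channel).
#' @param cells cell label matrix.
#' @param tophat_radius disc radius in px (must be >= 1).
#' @param threshold `"otsu"` (per cell) or fixed numeric counts applied
#'   to the top-hat image.
#' @return integer label matrix; mitochondrial pixels carry their parent
#'   cell's label.
#' @export
segment_mitochondria <- function(mmp, cells, tophat_radius = 4,
                                 threshold = "otsu") {
  if (tophat_radius < 1) stop_ms("tophat_radius must be >= 1")
  if (!all(dim(mmp) == dim(cells)))
    stop_ms("image and cell map have different shapes")
  out <- matrix(0L, nrow(mmp), ncol(mmp))
  nlab <- max(cells)
  if (nlab == 0 || is_blank(mmp)) return(out)
  th <- ebi_mat(EBImage::whiteTopHat(EBImage::Image(mmp / 65535),
                                       disc_brush(tophat_radius)))
  if (is.numeric(threshold)) {
    sel <- th > as.numeric(threshold) / 65535 & cells > 0
    out[sel] <- cells[sel]
    return(out)
  }
  bb <- label_bboxes(cells)
  for (k in seq_len(nlab)) {
    b <- bb[[k]]
    if (is.null(b)) next
    sub <- th[b["r0"]:b["r1"], b["c0"]:b["c1"], drop = FALSE]
    inside <- cells[b["r0"]:b["r1"], b["c0"]:b["c1"], drop = FALSE] == k
    v <- sub[inside]
    if (length(v) < 2 || max(v) <= min(v)) next
    thr <- EBImage::otsu(EBImage::Image(matrix(v, ncol = 1)),
                         range = range(v), levels = 256L)
    sel <- inside & sub > thr
    blk <- out[b["r0"]:b["r1"], b["c0"]:b["c1"], drop = FALSE]
    blk[sel] <- k
    out[b["r0"]:b["r1"], b["c0"]:b["c1"]] <- blk
  }
  out
}

#' Match segmented objects to ground truth
#'
#' Greedy IoU matching between two label maps (one-to-one, best IoU
#' first). Used for segmentation-quality acceptance checks.
#'
#' @param pred,truth label matrices.
#' @param iou_threshold minimum IoU for a match (default 0.5).
#' @return list with `f1`, `precision`, `recall`, `median_iou` (over
#'   matches) and the match table.
#' @export
match_objects <- function(pred, truth, iou_threshold = 0.5) {
  np <- max(pred); nt <- max(truth)
  if (np == 0 || nt == 0)
    return(list(f1 = 0, precision = 0, recall = 0, median_iou = NA_real_,
                matches = data.frame()))
  both <- pred > 0 & truth > 0
  inter <- table(factor(pred[both], levels = seq_len(np)),
                 factor(truth[both], levels = seq_len(nt)))
  ap <- label_areas(pred, np); at <- label_areas(truth, nt)
  iou <- as.matrix(inter) /
    (outer(ap, at, `+`) - as.matrix(inter))
  matches <- data.frame(pred = integer(0), truth = integer(0),
                        iou = numeric(0))
  iou_w <- iou
  repeat {
    best <- which.max(iou_w)
    if (length(best) == 0 || iou_w[best] < iou_threshold) break
    i <- (best - 1) %% np + 1; j <- (best - 1) %/% np + 1
    matches <- rbind(matches, data.frame(pred = i, truth = j,
                                         iou = iou_w[best]))
    iou_w[i, ] <- -1; iou_w[, j] <- -1
  }
  tp <- nrow(matches)
  prec <- tp / np; rec <- tp / nt
  f1 <- if (tp == 0) 0 else 2 * prec * rec / (prec + rec)
  list(f1 = f1, precision = prec, recall = rec,
       median_iou = if (tp) median(matches$iou) else NA_real_,
       matches = matches)
}

#' Segment a whole field
#'
#' Convenience wrapper running [segment_nuclei()], [expand_to_cells()]
#' and [segment_mitochondria()] with one parameter list.
#'
#' @param stack a [channel_stack()].
#' @param params list overriding defaults: `smooth_sigma`, `threshold`,
#'   `min_area`, `split`, `exclude_border`, `max_distance`,
#'   `fg_threshold`, `tophat_radius`.
#' @return list of label matrices `nuclei`, `cells`, `mito`.
#' @export
segment_field <- function(stack, params = list()) {
  p <- modifyList(list(smooth_sigma = 2, threshold = "otsu", min_area = 50L,
                       split = TRUE, exclude_border = FALSE,
                       max_distance = 20, fg_threshold = "bg3mad",
                       tophat_radius = 4), params)
  nuc <- segment_nuclei(stack$channels$hoechst, p$smooth_sigma, p$threshold,
                        p$min_area, p$split, p$exclude_border)
  cells <- expand_to_cells(nuc, stack$channels$ros, p$max_distance,
                           p$fg_threshold)
  mito <- segment_mitochondria(stack$channels$mmp, cells, p$tophat_radius)
  list(nuclei = nuc, cells = cells, mito = mito)
}
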