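## Morphological feature extraction: the CellProfiler-style catalogue.
## All operators take a numeric image matrix and a logical mask of the
## object; degenerate geometry yields NA ("missing, never silently 0"),
## with the single documented exception of the Haralick correlation,
## which is 0 by convention on zero-variance regions.

.glcm_offsets <- list(`0` = c(0L, 1L), `90` = c(1L, 0L),
                      `45` = c(1L, 1L), `135` = c(1L, -1L))

#' Haralick texture features of a masked region
#'
#' Intensities within the mask are min--max rescaled to `levels` gray
#' levels; symmetric, normalized gray-level co-occurrence matrices at
#' the four axial/diagonal offsets of length `distance` are averaged and
#' the 13 classical Haralick statistics returned. On a zero-variance
#' region contrast is 0, the inverse difference moment 1 and the
#' Haralick correlation defined as 0 (CellProfiler-compatible
#' convention, avoiding missing-value cascades).
#'
#' @param image numeric matrix.
#' @param mask logical matrix, same shape.
#' @param levels number of gray levels after quantization.
#' @param distance offset length in px.
#' @param angles subset of `c("0", "45", "90", "135")` to average over.
#' @return named numeric vector of 13 features (all `NA` when the mask
#'   has fewer than 2 pixels).
#' @export
glcm_texture <- function(image, mask, levels = 64L, distance = 3L,
                         angles = c("0", "45", "90", "135")) {
  out <- setNames(rep(NA_real_, 13L), .haralick_stats)
  if (sum(mask) < 2) return(out)
  P <- .glcm_matrix(image, mask, levels, distance, angles)
  if (is.null(P)) return(out)
  .haralick_from_glcm(P)
}

## quantize and accumulate the angle-averaged symmetric normalized GLCM
.glcm_matrix <- function(image, mask, levels, distance, angles) {
  rr <- range(which(rowSums(mask) > 0)); cc <- range(which(colSums(mask) > 0))
  img <- image[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  msk <- mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  v <- img[msk]
  lo <- min(v); hi <- max(v)
  q <- matrix(NA_integer_, nrow(img), ncol(img))
  if (hi > lo) {
    code <- floor((img - lo) / (hi - lo) * levels) + 1L
    code[code > levels] <- levels
  } else {
    code <- matrix(1L, nrow(img), ncol(img))
  }
  q[msk] <- code[msk]
  acc <- matrix(0, levels, levels)
  used <- 0L
  for (a in angles) {
    off <- .glcm_offsets[[a]]
    pp <- .glcm_pairs(q, off[1], off[2], levels)
    if (is.null(pp)) next
    acc <- acc + pp
    used <- used + 1L
  }
  if (used == 0L || sum(acc) == 0) return(NULL)
  acc / used
}

## symmetric normalized co-occurrence counts for one (dr, dc) offset
.glcm_pairs <- function(q, dr, dc, levels) {
  nr <- nrow(q); nc <- ncol(q)
  dr <- dr; dc <- dc
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(r1) < 1 || length(c1) < 1) return(NULL)
  A <- q[r1, c1, drop = FALSE]
  B <- q[r1 + dr, c1 + dc, drop = FALSE]
  sel <- !is.na(A) & !is.na(B)
  if (!any(sel)) return(NULL)
  i <- A[sel]; j <- B[sel]
  counts <- tabulate((i - 1L) * levels + j, nbins = levels * levels) +
    tabulate((j - 1L) * levels + i, nbins = levels * levels)
  P <- matrix(counts, levels, levels, byrow = TRUE)
  P / sum(P)
}

.haralick_from_glcm <- function(P) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(seq_len(L) * px); mu_y <- sum(seq_len(L) * py)
  sd_x <- sqrt(sum((seq_len(L) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(L) - mu_y)^2 * py))
  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (sd_x > 0 && sd_y > 0)
    (sum(i * j * P) - mu_x * mu_y) / (sd_x * sd_y) else 0
  variance <- sum((i - mu_x)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  ## p_{x+y}(k), k = 2..2L and p_{x-y}(k), k = 0..L-1
  psum <- vapply(2:(2 * L), function(k) sum(P[i + j == k]), 0)
  pdif <- vapply(0:(L - 1), function(k) sum(P[abs(i - j) == k]), 0)
  sum_avg <- sum((2:(2 * L)) * psum)
  sum_var <- sum(((2:(2 * L)) - sum_avg)^2 * psum)
  sum_ent <- -sum(xlogx(psum))
  entropy <- -sum(xlogx(P))
  dif_mean <- sum((0:(L - 1)) * pdif)
  dif_var <- sum(((0:(L - 1)) - dif_mean)^2 * pdif)
  dif_ent <- -sum(xlogx(pdif))
  hx <- -sum(xlogx(px)); hy <- -sum(xlogx(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(ifelse(pxy > 0, P * log(pxy), 0))
  hxy2 <- -sum(xlogx(pxy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - entropy)), 0))

  setNames(c(asm, contrast, correlation, variance, idm, sum_avg, sum_var,
             sum_ent, entropy, dif_var, dif_ent, imc1, imc2),
           .haralick_stats)
}

#' Shape descriptors of a binary mask
#'
#' Fifteen classical shape features. Perimeter uses the 8-connected
#' boundary chain-length convention (diagonal steps count sqrt(2);
#' isolated pixels contribute 4), under which the form factor
#' 4*pi*A/P^2 of a digital disc lies near 1 (slight discretization
#' overshoot up to ~1.1 is possible). Axis lengths and orientation are
#' moment-based; solidity is the area over the convex-hull area capped
#' at 1.
#'
#' @param mask logical matrix (may contain several connected
#'   components, e.g. a cell's mitochondrial pixel set).
#' @return named numeric vector of 15 features, `NA` if empty.
#' @export
shape_descriptors <- function(mask) {
  out <- setNames(rep(NA_real_, 15L), .shape_stats)
  area <- sum(mask)
  if (area == 0) return(out)
  idx <- which(mask)
  r <- (idx - 1L) %% nrow(mask) + 1L
  c <- (idx - 1L) %/% nrow(mask) + 1L
  per <- .chain_perimeter(mask)
  mu_r <- mean(r); mu_c <- mean(c)
  vrr <- mean((r - mu_r)^2); vcc <- mean((c - mu_c)^2)
  vrc <- mean((r - mu_r) * (c - mu_c))
  tr <- vrr + vcc
  det_ <- vrr * vcc - vrc^2
  disc <- sqrt(max((tr / 2)^2 - det_, 0))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 0)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  ecc <- if (l1 > 0) sqrt(1 - l2 / l1) else 0
  aspect <- if (minor > 0) major / minor else if (area == 1) 1 else Inf
  orient <- if (abs(vrc) < 1e-12 && abs(vcc - vrr) < 1e-12) 0
            else 0.5 * atan2(2 * vrc, vcc - vrr)
  hull <- .hull_area(r, c)
  solidity <- min(1, area / max(hull, 1e-9))
  bb_r <- diff(range(r)) + 1L; bb_c <- diff(range(c)) + 1L
  out["area"] <- area
  out["perimeter"] <- per
  out["form_factor"] <- if (per > 0) 4 * pi * area / per^2 else NA_real_
  out["eccentricity"] <- ecc
  out["solidity"] <- solidity
  out["extent"] <- area / (bb_r * bb_c)
  out["major_axis"] <- major
  out["minor_axis"] <- minor
  out["aspect_ratio"] <- aspect
  out["orientation"] <- orient
  out["equiv_diameter"] <- 2 * sqrt(area / pi)
  out["euler"] <- .euler_number(mask)
  out["bbox_rows"] <- bb_r
  out["bbox_cols"] <- bb_c
  out["compactness"] <- if (area > 0 && per > 0) per^2 / (4 * pi * area)
                        else NA_real_
  out
}

## 8-connected contour chain length summed over connected components
.chain_perimeter <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  ct <- EBImage::ocontour(lab)
  total <- 0
  for (p in ct) {
    if (nrow(p) == 1) { total <- total + 4; next }
    d <- rbind(diff(p), p[1, ] - p[nrow(p), ])
    total <- total + sum(sqrt(rowSums(d^2)))
  }
  total
}

.hull_area <- function(r, c) {
  if (length(r) < 3) return(length(r))
  pts <- unique(cbind(r, c))
  if (nrow(pts) < 3) return(nrow(pts))
  h <- grDevices::chull(pts[, 2], pts[, 1])
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3) return(nrow(pts))
  x <- hp[, 2]; y <- hp[, 1]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

## Euler number = components - holes (4-connected holes)
.euler_number <- function(mask) {
  ncomp <- max(EBImage::bwlabel(EBImage::Image(mask * 1)))
  pad <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  bglab <- ebi_mat(EBImage::bwlabel(EBImage::Image((!pad) * 1)))
  border <- unique(c(bglab[1, ], bglab[nrow(bglab), ],
                     bglab[, 1], bglab[, ncol(bglab)]))
  holes <- length(setdiff(unique(bglab[bglab > 0]), border))
  ncomp - holes
}

#' Intensity descriptors of a masked region
#'
#' Thirteen statistics: mean, median, SD (sample), MAD, min, max,
#' integrated intensity, quantiles 5/25/75/95% (type-7 interpolation),
#' mass displacement (distance between the geometric and
#' intensity-weighted centroids, px) and the mean intensity over the
#' object's boundary pixels.
#'
#' @param image numeric matrix.
#' @param mask logical matrix.
#' @return named numeric vector of 13 features, `NA` on an empty mask.
#' @export
intensity_descriptors <- function(image, mask) {
  out <- setNames(rep(NA_real_, 13L), .intensity_stats)
  if (!any(mask)) return(out)
  v <- image[mask]
  idx <- which(mask)
  r <- (idx - 1L) %% nrow(mask) + 1L
  c <- (idx - 1L) %/% nrow(mask) + 1L
  tot <- sum(v)
  md <- if (tot > 0) {
    sqrt((sum(r * v) / tot - mean(r))^2 + (sum(c * v) / tot - mean(c))^2)
  } else NA_real_
  edge <- .boundary_pixels(mask)
  out[] <- c(mean(v), median(v), if (length(v) > 1) sd(v) else 0, mad(v),
             min(v), max(v), tot,
             quantile(v, c(0.05, 0.25, 0.75, 0.95), names = FALSE),
             md, mean(image[edge]))
  out
}

## logical matrix of mask pixels with at least one 4-neighbor outside
.boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- function(dr, dc) {
    m <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    m[rs, cs] <- mask[rs - dr, cs - dc]
    m
  }
  inner <- pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
  mask & !inner
}

#' Cross-channel colocalization metrics within a mask
#'
#' Pearson correlation, overlap coefficient
#' `sum(ab) / sqrt(sum(a^2) sum(b^2))` and the Manders fraction
#' `sum(a[b > 0]) / sum(a)` over the masked pixels.
#'
#' @param a,b numeric matrices (two channels).
#' @param mask logical matrix with at least 2 pixels.
#' @return named numeric vector `pcc`, `overlap`, `manders`; `pcc` is
#'   `NA` when either channel has zero variance in the mask.
#' @export
cross_channel_corr <- function(a, b, mask) {
  out <- setNames(rep(NA_real_, 3L), .corr_metrics)
  if (sum(mask) < 2) return(out)
  va <- a[mask]; vb <- b[mask]
  if (sd(va) > 0 && sd(vb) > 0) out["pcc"] <- cor(va, vb)
  den <- sqrt(sum(va^2) * sum(vb^2))
  out["overlap"] <- if (den > 0) sum(va * vb) / den else NA_real_
  out["manders"] <- if (sum(va) > 0) sum(va[vb > 0]) / sum(va) else NA_real_
  out
}

#' Granularity spectrum of a masked region
#'
#' Normalized loss of masked intensity under successive morphological
#' openings with disc structuring elements of radii `radii`:
#' `G_k = (S_{k-1} - S_k) / S_0` with `S_k` the masked intensity sum
#' after opening at radius `k` (increments clamped at 0 against
#' digital-disc non-monotonicity). The spectrum sums to 1 when the
#' largest opening removes all signal.
#'
#' @param image numeric matrix.
#' @param mask logical matrix.
#' @param radii increasing disc radii (default 1:16).
#' @return numeric vector, one value per radius; `NA` when the mask is
#'   empty or carries no intensity.
#' @export
granularity_spectrum <- function(image, mask, radii = 1:16) {
  out <- rep(NA_real_, length(radii))
  if (!any(mask)) return(out)
  rr <- range(which(rowSums(mask) > 0)); cc <- range(which(colSums(mask) > 0))
  padr <- max(radii) + 1L
  r0 <- max(1, rr[1] - padr); r1 <- min(nrow(mask), rr[2] + padr)
  c0 <- max(1, cc[1] - padr); c1 <- min(ncol(mask), cc[2] + padr)
  img <- image[r0:r1, c0:c1, drop = FALSE]
  msk <- mask[r0:r1, c0:c1, drop = FALSE]
  masked <- img * msk
  s0 <- sum(masked)
  if (s0 <= 0) return(out)
  prev <- s0
  scale <- max(masked)
  norm <- masked / scale
  for (k in seq_along(radii)) {
    op <- ebi_mat(EBImage::opening(EBImage::Image(norm),
                                     disc_brush(radii[k]))) * scale
    sk <- sum(op[msk])
    out[k] <- max(prev - sk, 0) / s0
    prev <- sk
  }
  out
}

#' Radial intensity distribution within the cell
#'
#' Intensity is binned into 4 concentric equal-area annuli around a
#' reference centroid (the cell's nucleus centroid), scaled to the
#' cell's maximal radius. Per bin: fraction of total intensity
#' (`fracatd`), that fraction normalized by the bin's area fraction
#' (`meanfrac`), and the coefficient of variation of intensity across 8
#' angular wedges (`radialcv`).
#'
#' @param image numeric matrix.
#' @param mask logical cell mask.
#' @param center length-2 (row, col) reference point.
#' @return named vector of 12 features (3 stats x 4 bins).
#' @export
radial_distribution <- function(image, mask, center) {
  ## stat-major order: fracatd_bin1..4, meanfrac_bin1..4, radialcv_bin1..4
  nm <- as.vector(outer(1:4, .radial_stats,
                        function(b, s) sprintf("%s_bin%d", s, b)))
  out <- setNames(rep(NA_real_, 12L), nm)
  if (!any(mask)) return(out)
  idx <- which(mask)
  r <- (idx - 1L) %% nrow(mask) + 1L
  c <- (idx - 1L) %/% nrow(mask) + 1L
  v <- image[idx]
  tot <- sum(v)
  if (tot <= 0) return(out)
  d <- sqrt((r - center[1])^2 + (c - center[2])^2)
  dmax <- max(d)
  frac <- if (dmax > 0) d / dmax else rep(0, length(d))
  bin <- pmin(findInterval(frac, sqrt((0:4) / 4), rightmost.closed = TRUE,
                           left.open = FALSE), 4L)
  bin[bin < 1] <- 1L
  ang <- atan2(r - center[1], c - center[2])
  wedge <- pmin(floor((ang + pi) / (2 * pi) * 8) + 1L, 8L)
  for (b in 1:4) {
    sel <- bin == b
    a_frac <- sum(sel) / length(d)
    i_frac <- sum(v[sel]) / tot
    out[sprintf("fracatd_bin%d", b)] <- i_frac
    out[sprintf("meanfrac_bin%d", b)] <-
      if (a_frac > 0) i_frac / a_frac else NA_real_
    if (any(sel)) {
      w <- vapply(1:8, function(k) sum(v[sel & wedge == k]), 0)
      mw <- mean(w)
      out[sprintf("radialcv_bin%d", b)] <-
        if (mw > 0) sqrt(mean((w - mw)^2)) / mw else NA_real_
    }
  }
  out
}

#' Neighbor features for every object of a label map
#'
#' Per object: number of adjacent objects (within a 1-px dilation),
#' percent of boundary pixels touching another object, distances to the
#' first and second closest centroids, the angle (degrees) subtended at
#' the object between its two closest neighbors, and the number of
#' centroids within `within_distance`.
#'
#' @param labels integer label matrix.
#' @param within_distance radius in px for the neighbor count.
#' @return data.frame, one row per label 1..K.
#' @export
neighbor_features <- function(labels, within_distance = 50) {
  nlab <- max(labels)
  nm <- .neighbor_stats
  if (nlab == 0)
    return(as.data.frame(setNames(rep(list(numeric(0)), 6), nm)))
  nr <- nrow(labels); nc <- ncol(labels)
  ## adjacency via 8 shifts of the label map
  adj <- vector("list", nlab)
  touch <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    A <- labels[rs, cs]; B <- labels[rs - dr, cs - dc]
    sel <- A > 0 & B > 0 & A != B
    if (any(sel)) {
      pr <- unique(cbind(A[sel], B[sel]))
      for (k in seq_len(nrow(pr)))
        adj[[pr[k, 1]]] <- union(adj[[pr[k, 1]]], pr[k, 2])
      tt <- matrix(FALSE, length(rs), length(cs))
      tt[sel] <- TRUE
      touch[rs, cs] <- touch[rs, cs] | tt
    }
  }
  idx <- which(labels > 0L)
  r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
  lab <- labels[idx]
  cen_r <- tapply(r, lab, mean)[as.character(seq_len(nlab))]
  cen_c <- tapply(c, lab, mean)[as.character(seq_len(nlab))]
  bmask <- .boundary_pixels(labels > 0L)
  out <- data.frame(matrix(NA_real_, nlab, 6, dimnames = list(NULL, nm)))
  for (k in seq_len(nlab)) {
    out$n_adjacent[k] <- length(adj[[k]])
    bk <- bmask & labels == k
    nb <- sum(bk)
    out$percent_touching[k] <-
      if (nb > 0) 100 * sum(bk & touch) / nb else NA_real_
    if (nlab > 1) {
      d <- sqrt((cen_r - cen_r[k])^2 + (cen_c - cen_c[k])^2)
      d[k] <- Inf
      ord <- order(d)
      out$first_closest[k] <- d[ord[1]]
      out$n_within[k] <- sum(d <= within_distance)
      if (nlab > 2) {
        out$second_closest[k] <- d[ord[2]]
        v1 <- c(cen_r[ord[1]] - cen_r[k], cen_c[ord[1]] - cen_c[k])
        v2 <- c(cen_r[ord[2]] - cen_r[k], cen_c[ord[2]] - cen_c[k])
        cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
        out$angle_closest[k] <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      }
    } else {
      out$n_adjacent[k] <- 0
      out$percent_touching[k] <- if (nb > 0) 0 else NA_real_
      out$n_within[k] <- 0
    }
  }
  out
}

## ---- per-cell assembly -------------------------------------------------

#' Extract the full feature table for one field
#'
#' Computes every feature of `manifest` for every cell of the field.
#' Features undefined on a cell's geometry (e.g. texture of an empty
#' mitochondrial mask) are recorded as `NA`, never silently 0.
#' Coordinates in location features are 0-based (row, col).
#'
#' @param stack a [channel_stack()].
#' @param maps list with `cells`, `nuclei`, `mito` label matrices (from
#'   [segment_field()]).
#' @param manifest a [feature_manifest()] (any subset; order preserved).
#' @param meta optional one-row metadata data.frame replicated per cell.
#' @param levels,distance Haralick quantization levels and offset.
#' @return `FeatureTable` data.frame: key columns (`cell_id` + metadata)
#'   then exactly the manifest's columns, in order.
#' @export
extract_features <- function(stack, maps, manifest = feature_manifest(),
                             meta = NULL, levels = 64L, distance = 3L) {
  validate_manifest(manifest)
  nlab <- max(maps$cells)
  fam <- unique(manifest$family)
  mat <- matrix(NA_real_, nlab, nrow(manifest),
                dimnames = list(NULL, manifest$name))
  if (nlab > 0) {
    neigh <- list(cell = if ("neighbors" %in% fam)
                    neighbor_features(maps$cells) else NULL,
                  nucleus = if ("neighbors" %in% fam)
                    neighbor_features(maps$nuclei) else NULL)
    bb <- label_bboxes(maps$cells)
    pad <- 2L
    nr <- nrow(maps$cells); nc <- ncol(maps$cells)
    for (k in seq_len(nlab)) {
      b <- bb[[k]]
      if (is.null(b)) next
      r0 <- max(1, b["r0"] - pad); r1 <- min(nr, b["r1"] + pad)
      c0 <- max(1, b["c0"] - pad); c1 <- min(nc, b["c1"] + pad)
      crop <- function(m) m[r0:r1, c0:c1, drop = FALSE]
      masks <- list(cell = crop(maps$cells) == k,
                    nucleus = crop(maps$nuclei) == k,
                    mito = crop(maps$mito) == k)
      chans <- lapply(stack$channels, crop)
      mat[k, ] <- .cell_feature_row(chans, masks, manifest, neigh, k,
                                    offset = c(r0, c0), levels, distance)
    }
  }
  df <- as.data.frame(mat)
  keys <- data.frame(cell_id = seq_len(nlab))
  if (!is.null(meta) && nlab > 0)
    keys <- cbind(meta[rep(1L, nlab), , drop = FALSE], keys,
                  row.names = NULL)
  if (!is.null(meta) && nlab == 0)
    keys <- cbind(meta[integer(0), , drop = FALSE], keys)
  cbind(keys, df, row.names = NULL)
}

.cell_feature_row <- function(chans, masks, manifest, neigh, k, offset,
                              levels, distance) {
  vals <- setNames(rep(NA_real_, nrow(manifest)), manifest$name)
  fam <- unique(manifest$family)
  cen <- lapply(masks, function(m) {
    if (!any(m)) return(c(NA_real_, NA_real_))
    idx <- which(m)
    c(mean((idx - 1L) %% nrow(m) + 1L), mean((idx - 1L) %/% nrow(m) + 1L))
  })
  if ("shape" %in% fam)
    for (comp in .ms_compartments) {
      nmv <- paste("shape", comp, .shape_stats, sep = "_")
      hit <- nmv %in% names(vals)
      if (any(hit)) {
        s <- if (any(masks[[comp]])) shape_descriptors(masks[[comp]])
             else setNames(rep(NA_real_, 15), .shape_stats)
        vals[nmv[hit]] <- s[hit]
      }
    }
  if ("intensity" %in% fam)
    for (comp in .ms_compartments) for (ch in .ms_channels) {
      nmv <- paste("intensity", comp, ch, .intensity_stats, sep = "_")
      hit <- nmv %in% names(vals)
      if (any(hit)) {
        s <- intensity_descriptors(chans[[ch]], masks[[comp]])
        vals[nmv[hit]] <- s[hit]
      }
    }
  if ("texture" %in% fam)
    for (comp in .ms_compartments) for (ch in .ms_channels) {
      nmv <- paste("texture", comp, ch, .haralick_stats, sep = "_")
      hit <- nmv %in% names(vals)
      if (any(hit)) {
        s <- glcm_texture(chans[[ch]], masks[[comp]], levels, distance)
        vals[nmv[hit]] <- s[hit]
      }
    }
  if ("correlation" %in% fam)
    for (comp in c("cell", "nucleus")) for (pr in .channel_pairs()) {
      nmv <- paste("corr", comp, pr[1], pr[2], .corr_metrics, sep = "_")
      hit <- nmv %in% names(vals)
      if (any(hit)) {
        s <- cross_channel_corr(chans[[pr[1]]], chans[[pr[2]]], masks[[comp]])
        vals[nmv[hit]] <- s[hit]
      }
    }
  if ("granularity" %in% fam)
    for (ch in .ms_channels) {
      nmv <- sprintf("gran_cell_%s_r%02d", ch, 1:16)
      hit <- nmv %in% names(vals)
      if (any(hit)) {
        s <- granularity_spectrum(chans[[ch]], masks$cell)
        vals[nmv[hit]] <- s[hit]
      }
    }
  if ("radial" %in% fam) {
    cenref <- if (!anyNA(cen$nucleus)) cen$nucleus else cen$cell
    for (ch in .ms_channels) {
      nmv <- as.vector(vapply(.radial_stats, function(s)
        sprintf("radial_cell_%s_%s_bin%d", ch, s, 1:4), character(4)))
      hit <- nmv %in% names(vals)
      if (any(hit)) {
        s <- radial_distribution(chans[[ch]], masks$cell, cenref)
        vals[nmv[hit]] <- s[hit]
      }
    }
  }
  if ("neighbors" %in% fam)
    for (comp in c("cell", "nucleus")) {
      nmv <- paste("neigh", comp, .neighbor_stats, sep = "_")
      hit <- nmv %in% names(vals)
      if (any(hit) && !is.null(neigh[[comp]]) && k <= nrow(neigh[[comp]]))
        vals[nmv[hit]] <- as.numeric(neigh[[comp]][k, ])[hit]
    }
  if ("location" %in% fam) {
    for (comp in .ms_compartments) {
      vals[.keep(paste("loc", comp, "center_row", sep = "_"), vals)] <-
        cen[[comp]][1] + offset[1] - 2 # 0-based absolute row
      vals[.keep(paste("loc", comp, "center_col", sep = "_"), vals)] <-
        cen[[comp]][2] + offset[2] - 2
      for (ch in c("ros", "mtros", "mmp")) {
        m <- masks[[comp]]
        if (any(m)) {
          v <- chans[[ch]][m]
          tot <- sum(v)
          idx <- which(m)
          rr <- (idx - 1L) %% nrow(m) + 1L
          cc <- (idx - 1L) %/% nrow(m) + 1L
          if (tot > 0) {
            vals[.keep(paste("loc", comp, ch, "cmass_row", sep = "_"), vals)] <-
              sum(rr * v) / tot + offset[1] - 2
            vals[.keep(paste("loc", comp, ch, "cmass_col", sep = "_"), vals)] <-
              sum(cc * v) / tot + offset[2] - 2
          }
        }
      }
    }
  }
  vals
}

.keep <- function(nm, vals) nm[nm %in% names(vals)]

#' Aggregate a per-cell feature table into per-image profiles
#'
#' Per (well, field): the mean over cells of every feature, ignoring
#' missing values, with a cell-count column appended.
#'
#' @param features `FeatureTable` from [extract_features()] with `well`
#'   and `field` key columns.
#' @param keys grouping columns (default `c("well", "field")`); any
#'   further metadata columns constant within a group are carried over.
#' @return per-image profile data.frame.
#' @export
aggregate_image_profiles <- function(features, keys = c("well", "field")) {
  if (nrow(features) == 0) stop_ms("feature table is empty")
  if (!all(keys %in% names(features)))
    stop_ms("missing grouping keys: ",
            paste(setdiff(keys, names(features)), collapse = ", "))
  num <- names(features)[vapply(features, is.numeric, TRUE)]
  num <- setdiff(num, c(keys, "cell_id"))
  gid <- interaction(features[keys], drop = TRUE, lex.order = TRUE)
  meta_cols <- setdiff(names(features), c(num, "cell_id"))
  prof <- do.call(rbind, lapply(split(seq_len(nrow(features)), gid),
    function(ix) {
      sub <- features[ix, , drop = FALSE]
      mrow <- sub[1, meta_cols, drop = FALSE]
      vals <- vapply(num, function(cn) {
        v <- sub[[cn]]
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      }, 0)
      cbind(mrow, as.data.frame(as.list(vals)), n_cells = length(ix))
    }))
  rownames(prof) <- NULL
  prof
}
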