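## Independent brute-force oracles used to check the vectorized
## implementations. These deliberately use naive loops and re-derived
## formulas, not the package's code paths.

## -- gray-level co-occurrence -------------------------------------------

oracle_quantize <- function(image, mask, levels) {
  v <- image[mask]
  lo <- min(v); hi <- max(v)
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  for (i in seq_len(nrow(image))) for (j in seq_len(ncol(image))) {
    if (!mask[i, j]) next
    q[i, j] <- if (hi > lo)
      min(floor((image[i, j] - lo) / (hi - lo) * levels) + 1L, levels)
    else 1L
  }
  q
}

oracle_glcm <- function(image, mask, levels, distance,
                        angles = c("0", "45", "90", "135")) {
  q <- oracle_quantize(image, mask, levels)
  offs <- list(`0` = c(0, 1), `90` = c(1, 0), `45` = c(1, 1),
               `135` = c(1, -1))
  mats <- list()
  for (a in angles) {
    o <- offs[[a]] * distance
    cnt <- matrix(0, levels, levels)
    for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q))) {
      i2 <- i + o[1]; j2 <- j + o[2]
      if (i2 < 1 || i2 > nrow(q) || j2 < 1 || j2 > ncol(q)) next
      if (is.na(q[i, j]) || is.na(q[i2, j2])) next
      cnt[q[i, j], q[i2, j2]] <- cnt[q[i, j], q[i2, j2]] + 1
      cnt[q[i2, j2], q[i, j]] <- cnt[q[i2, j2], q[i, j]] + 1
    }
    if (sum(cnt) > 0) mats[[length(mats) + 1]] <- cnt / sum(cnt)
  }
  Reduce(`+`, mats) / length(mats)
}

## the 13 Haralick statistics, loop-based re-derivation
oracle_haralick <- function(P) {
  L <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mx <- 0; my <- 0
  for (i in 1:L) { mx <- mx + i * px[i]; my <- my + i * py[i] }
  sx <- 0; sy <- 0
  for (i in 1:L) { sx <- sx + (i - mx)^2 * px[i]; sy <- sy + (i - my)^2 * py[i] }
  sx <- sqrt(sx); sy <- sqrt(sy)
  asm <- 0; con <- 0; corr_num <- 0; varr <- 0; idm <- 0; ent <- 0
  psum <- rep(0, 2 * L); pdif <- rep(0, L)
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    asm <- asm + p^2
    con <- con + (i - j)^2 * p
    corr_num <- corr_num + i * j * p
    varr <- varr + (i - mx)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    if (p > 0) ent <- ent - p * log(p)
    psum[i + j] <- psum[i + j] + p
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p
  }
  corr <- if (sx > 0 && sy > 0) (corr_num - mx * my) / (sx * sy) else 0
  sa <- 0; for (k in 2:(2 * L)) sa <- sa + k * psum[k]
  sv <- 0; for (k in 2:(2 * L)) sv <- sv + (k - sa)^2 * psum[k]
  se <- 0; for (k in 2:(2 * L)) if (psum[k] > 0) se <- se - psum[k] * log(psum[k])
  dm <- 0; for (k in 0:(L - 1)) dm <- dm + k * pdif[k + 1]
  dv <- 0; for (k in 0:(L - 1)) dv <- dv + (k - dm)^2 * pdif[k + 1]
  de <- 0; for (k in 0:(L - 1)) if (pdif[k + 1] > 0) de <- de - pdif[k + 1] * log(pdif[k + 1])
  hx <- 0; for (i in 1:L) if (px[i] > 0) hx <- hx - px[i] * log(px[i])
  hy <- 0; for (j in 1:L) if (py[j] > 0) hy <- hy - py[j] * log(py[j])
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:L) for (j in 1:L) {
    pp <- px[i] * py[j]
    if (pp > 0) {
      hxy1 <- hxy1 - P[i, j] * log(pp)
      hxy2 <- hxy2 - pp * log(pp)
    }
  }
  imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(1 - exp(-2 * (hxy2 - ent)), 0))
  c(asm = asm, contrast = con, correlation = corr, variance = varr,
    idm = idm, sum_average = sa, sum_variance = sv, sum_entropy = se,
    entropy = ent, diff_variance = dv, diff_entropy = de,
    imc1 = imc1, imc2 = imc2)
}

## -- per-label pixel statistics -----------------------------------------

oracle_label_stats <- function(image, labels) {
  out <- list()
  for (k in sort(unique(labels[labels > 0]))) {
    vals <- c()
    for (i in seq_len(nrow(labels))) for (j in seq_len(ncol(labels)))
      if (labels[i, j] == k) vals <- c(vals, image[i, j])
    out[[as.character(k)]] <- list(mean = sum(vals) / length(vals),
                                   median = median(vals),
                                   integrated = sum(vals),
                                   area = length(vals))
  }
  out
}

## -- binary dilation by a Euclidean disc --------------------------------

oracle_dilate_disc <- function(mask, d) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  on <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (any((on[, 1] - i)^2 + (on[, 2] - j)^2 <= d^2)) out[i, j] <- TRUE
  }
  out
}

## -- exhaustive average-linkage agglomeration ---------------------------

oracle_agglomerate <- function(D) {
  ## D: full symmetric distance matrix; returns merge heights in order
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      dd <- mean(D[clusters[[a]], clusters[[b]]])
      if (dd < bestd) { bestd <- dd; best <- c(a, b) }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

## -- misc fixtures -------------------------------------------------------

## small latent group with the default normal-fibroblast coupling
fixture_group <- function(cells_per_field = 12L, wells = "A1",
                          fields_per_well = 2L,
                          rho = coupling_rho(0.35, 0.75, 0.40)) {
  group_spec("HPFC", "control", 0, rho = rho,
             cells_per_field = cells_per_field,
             fields_per_well = fields_per_well, wells = wells)
}

fixture_geom_small <- function(...)
  field_geometry(image_size = 256L, ...)

## draw a filled disc into a matrix
draw_disc <- function(size, cr, cc, r, value = 1, base = NULL) {
  m <- if (is.null(base)) matrix(0, size, size) else base
  for (i in seq_len(size)) for (j in seq_len(size))
    if ((i - cr)^2 + (j - cc)^2 <= r^2) m[i, j] <- value
  m
}
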