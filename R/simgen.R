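#' Sample per-cell latent (MMP, ROS, mtROS) triples
#'
#' Draws `n` cells from the trivariate log-normal latent model of a
#' [group_spec()]: `log(M, R, S) ~ N(mu, diag(sigma) rho diag(sigma))`.
#' Latents are returned on the linear (exponentiated) scale, so sample
#' correlations of their logs converge to `spec$rho` as `n` grows.
#'
#' @param spec a [group_spec()].
#' @param n number of cells (0 returns an empty table).
#' @param seed integer seed; fixed seed gives identical output.
#' @return data.frame with columns `cell_id`, `M`, `R`, `S` (strictly
#'   positive).
#' @export
sample_latents <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "GroupSpec"), n >= 0)
  check_corr_matrix(spec$rho)
  if (n == 0)
    return(data.frame(cell_id = integer(0), M = numeric(0),
                      R = numeric(0), S = numeric(0)))
  sig <- diag(spec$sigma) %*% spec$rho %*% diag(spec$sigma)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  z <- MASS::mvrnorm(n, mu = spec$mu, Sigma = sig)
  if (n == 1) z <- matrix(z, nrow = 1)
  data.frame(cell_id = seq_len(n),
             M = exp(z[, 1]), R = exp(z[, 2]), S = exp(z[, 3]))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Construct a multichannel field stack
#'
#' @param channels named list of equally sized numeric matrices; names
#'   must include `hoechst`, `ros`, `mtros`, `mmp` (optionally `bf`).
#' @return an object of class `ChannelStack`.
#' @export
channel_stack <- function(channels) {
  need <- c("hoechst", "ros", "mtros", "mmp")
  if (!all(need %in% names(channels)))
    stop_ms("channels must include ", paste(need, collapse = ", "))
  dims <- vapply(channels, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) != 1)
    stop_ms("all channels must share identical dimensions")
  rng <- range(unlist(lapply(channels, range)))
  if (rng[1] < 0 || rng[2] > 65535)
    stop_ms("channel values must lie in [0, 65535]")
  structure(list(channels = channels), class = "ChannelStack")
}

#' @export
print.ChannelStack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("ChannelStack", d[1], "x", d[2], "px;",
      paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

## place n non-overlapping nuclei; returns data.frame or errors with the
## number achieved. Cytoplasm may touch; only nuclei are kept disjoint.
.place_cells <- function(n, geom, max_tries = 300L) {
  sz <- geom$image_size
  rn <- runif(n, geom$nucleus_radius[1], geom$nucleus_radius[2])
  rc <- runif(n, geom$cell_radius[1], geom$cell_radius[2])
  cx <- numeric(0); cy <- numeric(0)
  margin <- max(geom$nucleus_radius) + 2
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      x <- runif(1, margin, sz - margin)
      y <- runif(1, margin, sz - margin)
      if (length(cx) == 0 ||
          all((cx - x)^2 + (cy - y)^2 > (rn[seq_along(cx)] + rn[i] + 2)^2)) {
        cx <- c(cx, x); cy <- c(cy, y); placed <- TRUE; break
      }
    }
    if (!placed)
      stop_ms("field too crowded: placed ", i - 1L, " of ", n, " nuclei")
  }
  data.frame(cell_id = seq_len(n), cx = cx, cy = cy,
             nucleus_radius = rn, cell_radius = rc)
}

## rasterize nucleus + cell label maps. Cells are discs around the same
## centers; overlapping cytoplasm is split by normalized distance
## (Voronoi-like), and nucleus pixels are forced to their own cell.
.rasterize_cells <- function(pl, sz) {
  nuc <- matrix(0L, sz, sz)
  cell <- matrix(0L, sz, sz)
  best <- matrix(Inf, sz, sz)
  for (i in seq_len(nrow(pl))) {
    r0 <- max(1L, floor(pl$cy[i] - pl$cell_radius[i]))
    r1 <- min(sz, ceiling(pl$cy[i] + pl$cell_radius[i]))
    c0 <- max(1L, floor(pl$cx[i] - pl$cell_radius[i]))
    c1 <- min(sz, ceiling(pl$cx[i] + pl$cell_radius[i]))
    rows <- r0:r1; cols <- c0:c1
    d2 <- outer((rows - pl$cy[i])^2, (cols - pl$cx[i])^2, `+`)
    norm <- sqrt(d2) / pl$cell_radius[i]
    sub_best <- best[rows, cols]
    take <- norm <= 1 & norm < sub_best
    if (any(take)) {
      sub_best[take] <- norm[take]
      best[rows, cols] <- sub_best
      sub_cell <- cell[rows, cols]
      sub_cell[take] <- i
      cell[rows, cols] <- sub_cell
    }
    innuc <- d2 <= pl$nucleus_radius[i]^2
    if (any(innuc)) {
      sub_nuc <- nuc[rows, cols]
      sub_nuc[innuc] <- i
      nuc[rows, cols] <- sub_nuc
    }
  }
  ## nuclei are disjoint by construction; force nucleus pixels into their
  ## own cell so containment holds even where normalized distances tie
  cell[nuc > 0L] <- nuc[nuc > 0L]
  list(nucleus = nuc, cell = cell)
}

## random-walk mitochondrial filaments inside the cytoplasm of one cell;
## membership tested against the full label maps in O(1) per step
.draw_mitochondria <- function(cyto_idx, cell_lab, nuc_lab, i, sz, geom) {
  k <- sample(geom$mito_count[1]:geom$mito_count[2], 1)
  if (length(cyto_idx) == 0 || k == 0) return(integer(0))
  pix <- integer(0)
  for (m in seq_len(k)) {
    start <- cyto_idx[sample.int(length(cyto_idx), 1)]
    fr <- (start - 1L) %% sz + 1L
    fc <- (start - 1L) %/% sz + 1L
    len <- round(runif(1, geom$mito_segment_length[1],
                       geom$mito_segment_length[2]))
    theta <- runif(1, 0, 2 * pi)
    for (s in seq_len(len)) {
      theta <- theta + rnorm(1, 0, 0.4)
      fr <- fr + sin(theta); fc <- fc + cos(theta)
      pr <- round(fr); pc <- round(fc)
      if (pr < 1 || pr > sz || pc < 1 || pc > sz) break
      idx <- (pc - 1L) * sz + pr
      if (cell_lab[idx] != i || nuc_lab[idx] == i) break
      pix <- c(pix, idx)
    }
  }
  unique(pix)
}

#' Render one synthetic multichannel field
#'
#' Rasterizes the cells of a latent table into a four-channel field:
#' Hoechst confined to nuclei; ROS spread over the whole cell scaled by
#' `R`; mtROS and MMP concentrated on mitochondrial filament pixels
#' scaled by `S` and `M` with a weak cytoplasmic haze. Poisson shot
#' noise then Gaussian read noise are applied last and the result is
#' clipped to the detector bit depth. With both noise sources disabled
#' (`poisson_gain = 0`, `read_noise_sd = 0`) the returned images are the
#' exact (unrounded) expectations, so signal identities hold exactly.
#'
#' @param latents data.frame from [sample_latents()] (may have 0 rows).
#' @param geom a [field_geometry()].
#' @param seed integer seed; rendering is bit-reproducible under it.
#' @return list with elements `stack` ([channel_stack()]) and `truth`
#'   (ground truth: `cells` table with latents and geometry,
#'   `nucleus_mask`, `cell_mask`, `mito_mask` label matrices).
#' @export
render_field <- function(latents, geom = field_geometry(), seed = 1L) {
  stopifnot(inherits(geom, "FieldGeometry"))
  sz <- geom$image_size
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(latents)
  if (n > 0) {
    pl <- .place_cells(n, geom)
    masks <- .rasterize_cells(pl, sz)
    cell_pos <- which(masks$cell > 0L)
    cell_idx <- split(cell_pos, masks$cell[cell_pos])
    nuc_pos <- which(masks$nucleus > 0L)
    nuc_idx <- split(nuc_pos, masks$nucleus[nuc_pos])
    mito <- matrix(0L, sz, sz)
    mito_idx <- vector("list", n)
    for (i in seq_len(n)) {
      ci <- cell_idx[[as.character(i)]] %||% integer(0)
      cyto <- ci[masks$nucleus[ci] != i]
      mp <- .draw_mitochondria(cyto, masks$cell, masks$nucleus, i, sz, geom)
      mito[mp] <- i
      mito_idx[[i]] <- mp
    }
    hoechst_amp <- exp(rnorm(n, log(geom$hoechst_level), 0.15))
  } else {
    pl <- data.frame(cell_id = integer(0), cx = numeric(0), cy = numeric(0),
                     nucleus_radius = numeric(0), cell_radius = numeric(0))
    masks <- list(nucleus = matrix(0L, sz, sz), cell = matrix(0L, sz, sz))
    mito <- matrix(0L, sz, sz)
    hoechst_amp <- numeric(0)
  }

  bg <- geom$background_level
  ch <- list(hoechst = matrix(bg, sz, sz), ros = matrix(bg, sz, sz),
             mtros = matrix(bg, sz, sz), mmp = matrix(bg, sz, sz))
  for (i in seq_len(n)) {
    ni <- nuc_idx[[as.character(i)]] %||% integer(0)
    ci <- cell_idx[[as.character(i)]] %||% integer(0)
    mi <- mito_idx[[i]]
    ch$hoechst[ni] <- ch$hoechst[ni] + hoechst_amp[i]
    ch$ros[ci] <- ch$ros[ci] + latents$R[i]
    ch$mtros[ci] <- ch$mtros[ci] + geom$haze_fraction * latents$S[i]
    ch$mtros[mi] <- ch$mtros[mi] + latents$S[i]
    ch$mmp[ci] <- ch$mmp[ci] + geom$haze_fraction * latents$M[i]
    ch$mmp[mi] <- ch$mmp[mi] + latents$M[i]
  }

  maxv <- 2^geom$bit_depth - 1
  noisy <- geom$poisson_gain > 0 || geom$read_noise_sd > 0
  ch <- lapply(ch, function(m) {
    if (geom$poisson_gain > 0)
      m <- matrix(rpois(length(m), m / geom$poisson_gain) * geom$poisson_gain,
                  nrow = sz)
    if (geom$read_noise_sd > 0)
      m <- m + rnorm(length(m), 0, geom$read_noise_sd)
    if (noisy) m <- round(m)
    pmin(pmax(m, 0), maxv)
  })

  truth_cells <- cbind(pl, latents[, c("M", "R", "S"), drop = FALSE])
  truth_cells$mito_px <- if (n > 0) label_areas(mito, n) else integer(0)
  list(stack = channel_stack(ch),
       truth = list(cells = truth_cells,
                    nucleus_mask = masks$nucleus,
                    cell_mask = masks$cell,
                    mito_mask = mito))
}

#' Field-level manifest for a plate layout
#'
#' Expands a layout into one row per (well, field) with a deterministic
#' per-field child seed derived from the master seed.
#'
#' @param layout a [plate_layout()].
#' @param seed master integer seed.
#' @return data.frame with columns `group`, `cell_line`, `compound`,
#'   `dose`, `well`, `field`, `field_seed`.
#' @export
plate_manifest <- function(layout, seed = 1L) {
  stopifnot(inherits(layout, "PlateLayout"))
  rows <- do.call(rbind, lapply(names(layout$groups), function(gname) {
    g <- layout$groups[[gname]]
    expand.grid(well = g$wells, field = seq_len(g$fields_per_well),
                stringsAsFactors = FALSE)[, 2:1] -> ef
    data.frame(group = gname, cell_line = g$cell_line,
               compound = g$compound, dose = g$dose,
               well = ef$well, field = ef$field,
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$well, rows$field), ]
  rownames(rows) <- NULL
  rows$field_seed <- child_seeds(seed, nrow(rows), stream = 1L)
  rows
}

#' Render one field of a plate from its manifest row
#'
#' @param layout a [plate_layout()].
#' @param manifest_row one row of [plate_manifest()].
#' @param geom a [field_geometry()].
#' @return as [render_field()].
#' @export
render_plate_field <- function(layout, manifest_row, geom = field_geometry()) {
  g <- layout$groups[[manifest_row$group]]
  if (is.null(g)) stop_ms("unknown group: ", manifest_row$group)
  lat <- sample_latents(g, g$cells_per_field, seed = manifest_row$field_seed)
  render_field(lat, geom, seed = manifest_row$field_seed)
}

#' Generate a synthetic plate on disk
#'
#' Writes one multi-page 16-bit TIFF per field (page order hoechst, ros,
#' mtros, mmp; channel names in the TIFF page descriptions), per-field
#' ground-truth CSV tables, and a JSON manifest recording the seed,
#' per-field group parameters and file paths. Deterministic under
#' `seed`.
#'
#' @param layout a [plate_layout()].
#' @param geom a [field_geometry()].
#' @param seed master seed.
#' @param out_dir output directory (created if missing).
#' @param write_truth also write ground-truth CSVs (default TRUE).
#' @return the manifest data.frame (invisibly), with `path` column.
#' @export
generate_plate <- function(layout, geom = field_geometry(), seed = 1L,
                           out_dir, write_truth = TRUE) {
  man <- plate_manifest(layout, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  if (write_truth)
    dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  man$path <- file.path(img_dir,
                        sprintf("%s_f%02d.tif", man$well, man$field))
  for (i in seq_len(nrow(man))) {
    fld <- render_plate_field(layout, man[i, ], geom)
    write_field_tiff(fld$stack, man$path[i])
    if (write_truth) {
      tc <- fld$truth$cells
      tc$well <- man$well[i]; tc$field <- man$field[i]
      write_table_csv(tc, file.path(out_dir, "truth",
                                    sprintf("%s_f%02d_cells.csv",
                                            man$well[i], man$field[i])))
    }
  }
  manifest <- list(pipeline = "mitoscreen",
                   version = as.character(utils::packageVersion("mitoscreen")),
                   seed = seed, plate_id = layout$plate_id,
                   geometry = unclass(geom),
                   channels = c("hoechst", "ros", "mtros", "mmp"),
                   fields = man)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}

#' Write a channel stack as a multi-page 16-bit TIFF
#'
#' @param stack a [channel_stack()].
#' @param path output file.
#' @export
write_field_tiff <- function(stack, path) {
  pages <- lapply(names(stack$channels), function(nm) {
    m <- t(stack$channels[[nm]]) / 65535 # tiff expects [0,1], row-major
    storage.mode(m) <- "double"
    attr(m, "description") <- nm
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' Read a multi-page field TIFF back into a channel stack
#'
#' Channel roles are taken from TIFF page descriptions when present,
#' otherwise assumed in the order hoechst, ros, mtros, mmp (bf first if
#' five pages).
#'
#' @param path TIFF written by [write_field_tiff()].
#' @return a [channel_stack()].
#' @export
read_field_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  nms <- vapply(pages, function(p) {
    d <- attr(p, "description")
    if (is.null(d) || !nzchar(d)) NA_character_ else d
  }, "")
  if (anyNA(nms))
    nms <- if (length(pages) == 5) c("bf", "hoechst", "ros", "mtros", "mmp")
           else c("hoechst", "ros", "mtros", "mmp")[seq_along(pages)]
  ch <- lapply(pages, function(p) {
    m <- t(round(p * 65535))
    attributes(m) <- list(dim = dim(m))
    m
  })
  names(ch) <- nms
  channel_stack(ch)
}
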