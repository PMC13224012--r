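#' Estimate the background level of one channel
#'
#' Default: the 5th percentile (sort-based, `type = 1`) of pixels
#' outside every cell; configurable to the background median.
#'
#' @param image numeric matrix.
#' @param cells cell label matrix (0 = background).
#' @param method `"p05"` (default) or `"median"`.
#' @param min_pixels minimum number of background pixels required.
#' @return scalar background estimate in counts.
#' @export
estimate_background <- function(image, cells, method = c("p05", "median"),
                                min_pixels = 100L) {
  method <- match.arg(method)
  bg <- image[cells == 0L]
  if (length(bg) < min_pixels)
    stop_ms("only ", length(bg), " background pixels (need ", min_pixels,
            "); configure a fixed background instead")
  if (method == "p05") quantile(bg, 0.05, type = 1, names = FALSE)
  else median(bg)
}

#' Measure per-cell background-corrected intensities
#'
#' One row per cell label with, per channel, the mean, median and
#' integrated intensity over the cell compartment plus the
#' background-corrected mean (`max(mean - background, 0)`), the
#' compartment areas, a nucleus-restricted Hoechst mean and
#' mitochondria-restricted means for the mmp and mtros channels.
#' `integrated = mean * area` holds exactly.
#'
#' @param stack a [channel_stack()].
#' @param cells,nuclei,mito label matrices from [segment_field()].
#' @param background named numeric vector of per-channel background
#'   counts, or `NULL` to estimate each via [estimate_background()].
#' @param meta optional one-row data.frame of plate metadata (`well`,
#'   `field`, `cell_line`, `compound`, `dose`, ...) replicated per cell.
#' @return `CellRecord` data.frame, one row per cell label.
#' @export
measure_cells <- function(stack, cells, nuclei, mito, background = NULL,
                          meta = NULL) {
  dims <- dim(stack$channels[[1]])
  if (!all(dim(cells) == dims) || !all(dim(nuclei) == dims) ||
      !all(dim(mito) == dims))
    stop_ms("label maps must match the channel stack dimensions")
  nlab <- max(cells)
  nuc_ids <- unique(nuclei[nuclei > 0L])
  if (length(setdiff(nuc_ids, seq_len(nlab))))
    stop_ms("nucleus labels present without a matching cell: broken pairing")
  chn <- c("hoechst", "ros", "mtros", "mmp")
  if (is.null(background))
    background <- vapply(chn, function(nm)
      estimate_background(stack$channels[[nm]], cells), 0)
  if (nlab == 0) return(.empty_cellrecord(meta))

  cell_area <- label_areas(cells, nlab)
  nuc_area <- label_areas(nuclei, nlab)
  mito_area <- label_areas(mito, nlab)
  out <- data.frame(cell_id = seq_len(nlab),
                    cell_px = cell_area, nucleus_px = nuc_area,
                    mito_px = mito_area)
  for (nm in chn) {
    img <- stack$channels[[nm]]
    s <- label_sums(img, cells, nlab)
    m <- s / cell_area
    med <- .label_medians(img, cells, nlab)
    out[[paste0(nm, "_mean")]] <- m
    out[[paste0(nm, "_median")]] <- med
    out[[paste0(nm, "_integrated")]] <- s
    out[[paste0(nm, "_corrected")]] <- pmax(m - background[[nm]], 0)
  }
  hn <- label_sums(stack$channels$hoechst, nuclei, nlab)
  out$hoechst_nuc_mean <- ifelse(nuc_area > 0, hn / nuc_area, NA_real_)
  for (nm in c("mmp", "mtros")) {
    sm <- label_sums(stack$channels[[nm]], mito, nlab)
    mm <- ifelse(mito_area > 0, sm / mito_area, NA_real_)
    out[[paste0(nm, "_mito_mean")]] <- mm
    out[[paste0(nm, "_mito_corrected")]] <- pmax(mm - background[[nm]], 0)
  }
  for (nm in chn)
    out[[paste0("background_", nm)]] <- background[[nm]]
  if (!is.null(meta))
    out <- cbind(meta[rep(1L, nrow(out)), , drop = FALSE], out,
                 row.names = NULL)
  out
}

.label_medians <- function(img, labels, nlab) {
  idx <- labels > 0L
  if (!any(idx)) return(numeric(0))
  sp <- split(img[idx], labels[idx])
  med <- numeric(nlab)
  med[as.integer(names(sp))] <- vapply(sp, median, 0)
  med
}

.empty_cellrecord <- function(meta = NULL) {
  cols <- c("cell_id", "cell_px", "nucleus_px", "mito_px",
            as.vector(outer(c("hoechst", "ros", "mtros", "mmp"),
                            c("_mean", "_median", "_integrated", "_corrected"),
                            paste0)),
            "hoechst_nuc_mean", "mmp_mito_mean", "mmp_mito_corrected",
            "mtros_mito_mean", "mtros_mito_corrected",
            paste0("background_", c("hoechst", "ros", "mtros", "mmp")))
  df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  if (!is.null(meta))
    df <- cbind(meta[integer(0), , drop = FALSE], df)
  df
}

#' Pool per-field cell tables into a screen-level table
#'
#' Concatenates per-field `CellRecord` tables, checks key uniqueness and
#' consistent columns, and adds an `experiment` column.
#'
#' @param tables list of data.frames from [measure_cells()], each
#'   carrying `well`, `field`, `cell_id` columns.
#' @param experiment experiment/replicate identifier (scalar or one per
#'   table).
#' @return single pooled data.frame.
#' @export
pool_screen <- function(tables, experiment = 1L) {
  tables <- Filter(function(t) nrow(t) > 0, tables)
  if (length(tables) == 0) stop_ms("no non-empty tables to pool")
  cols <- lapply(tables, names)
  if (length(unique(vapply(cols, paste, "", collapse = "|"))) != 1)
    stop_ms("inconsistent column sets across per-field tables")
  exp_id <- rep(experiment, length.out = length(tables))
  for (i in seq_along(tables)) tables[[i]]$experiment <- exp_id[i]
  out <- do.call(rbind, tables)
  rownames(out) <- NULL
  key <- paste(out$experiment, out$well, out$field, out$cell_id)
  if (anyDuplicated(key))
    stop_ms("duplicate (experiment, well, field, cell_id) keys in pooled table")
  ## one well must carry one metadata combination
  if (all(c("well", "compound", "cell_line") %in% names(out))) {
    per_well <- unique(out[, c("experiment", "well", "cell_line", "compound")])
    if (anyDuplicated(paste(per_well$experiment, per_well$well)))
      stop_ms("conflicting metadata for a well")
  }
  out
}
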