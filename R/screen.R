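#' Run a synthetic screen in memory (simulate, segment, quantify)
#'
#' Streams over every field of a plate layout: renders the field,
#' segments nuclei/cells/mitochondria, measures per-cell intensities
#' and (optionally) extracts morphological features, discarding the
#' images afterwards so that full plates fit in memory. Deterministic
#' under the master seed.
#'
#' @param layout a [plate_layout()].
#' @param geom a [field_geometry()].
#' @param seed master seed.
#' @param segment_params parameter list for [segment_field()].
#' @param features `FALSE`, `TRUE` (default 541-feature manifest) or a
#'   manifest data.frame.
#' @param experiment experiment identifier added to pooled tables.
#' @param keep_truth attach pooled ground-truth latents (`truth`
#'   element) for recovery checks.
#' @param progress print one line per field.
#' @return list with `cells` (pooled single-cell table), `profiles`
#'   (per-image mean feature profiles, or NULL), `features` (per-cell
#'   feature table, or NULL), `manifest` (field manifest), `truth`.
#' @export
run_screen <- function(layout, geom = field_geometry(), seed = 1L,
                       segment_params = list(), features = FALSE,
                       experiment = 1L, keep_truth = TRUE,
                       progress = FALSE) {
  man <- plate_manifest(layout, seed)
  fmanifest <- NULL
  if (isTRUE(features)) fmanifest <- feature_manifest()
  else if (is.data.frame(features)) fmanifest <- validate_manifest(features)
  cell_tabs <- vector("list", nrow(man))
  feat_tabs <- if (!is.null(fmanifest)) vector("list", nrow(man)) else NULL
  truth_tabs <- if (keep_truth) vector("list", nrow(man)) else NULL
  for (i in seq_len(nrow(man))) {
    if (progress)
      message(sprintf("[%d/%d] %s field %d", i, nrow(man), man$well[i],
                      man$field[i]))
    fld <- render_plate_field(layout, man[i, ], geom)
    seg <- segment_field(fld$stack, segment_params)
    meta <- man[i, c("cell_line", "compound", "dose", "well", "field"),
                drop = FALSE]
    cell_tabs[[i]] <- measure_cells(fld$stack, seg$cells, seg$nuclei,
                                    seg$mito, meta = meta)
    if (!is.null(fmanifest))
      feat_tabs[[i]] <- extract_features(fld$stack, seg, fmanifest,
                                         meta = meta)
    if (keep_truth) {
      tr <- fld$truth$cells
      if (nrow(tr) > 0) {
        tr$well <- man$well[i]; tr$field <- man$field[i]
        tr$cell_line <- man$cell_line[i]; tr$compound <- man$compound[i]
        tr$dose <- man$dose[i]
      }
      truth_tabs[[i]] <- tr
    }
  }
  cells <- pool_screen(cell_tabs, experiment = experiment)
  feats <- NULL; profiles <- NULL
  if (!is.null(fmanifest)) {
    feats <- do.call(rbind, feat_tabs)
    rownames(feats) <- NULL
    if (nrow(feats) > 0) profiles <- aggregate_image_profiles(feats)
  }
  truth <- if (keep_truth) do.call(rbind, truth_tabs) else NULL
  list(cells = cells, features = feats, profiles = profiles,
       manifest = man, truth = truth)
}
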