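## The paper-compat feature catalogue: exactly 541 named features.
## Family ledger (counts asserted in tests):
##   shape       15 stats x 3 compartments                      =  45
##   intensity   13 stats x 3 compartments x 4 channels         = 156
##   texture     13 Haralick x 3 compartments x 4 channels      = 156
##   correlation  3 metrics x 6 channel pairs x 2 compartments  =  36
##   granularity 16 radii x 4 channels (cell compartment)       =  64
##   radial       3 stats x 4 bins x 4 channels (cell)          =  48
##   neighbors    6 metrics x 2 compartments                    =  12
##   location     2 coords x 3 compartments x (1 + 3 channels)  =  24
##                                                        total = 541

.ms_channels <- c("hoechst", "ros", "mtros", "mmp")
.ms_compartments <- c("cell", "nucleus", "mito")

.shape_stats <- c("area", "perimeter", "form_factor", "eccentricity",
                  "solidity", "extent", "major_axis", "minor_axis",
                  "aspect_ratio", "orientation", "equiv_diameter",
                  "euler", "bbox_rows", "bbox_cols", "compactness")

.intensity_stats <- c("mean", "median", "sd", "mad", "min", "max",
                      "integrated", "q05", "q25", "q75", "q95",
                      "mass_displacement", "edge_mean")

.haralick_stats <- c("asm", "contrast", "correlation", "variance", "idm",
                     "sum_average", "sum_variance", "sum_entropy",
                     "entropy", "diff_variance", "diff_entropy",
                     "imc1", "imc2")

.corr_metrics <- c("pcc", "overlap", "manders")

.radial_stats <- c("fracatd", "meanfrac", "radialcv")

.neighbor_stats <- c("n_adjacent", "percent_touching", "first_closest",
                     "second_closest", "angle_closest", "n_within")

.channel_pairs <- function() {
  ch <- .ms_channels
  out <- list()
  for (i in 1:3) for (j in (i + 1):4) out[[length(out) + 1]] <- c(ch[i], ch[j])
  out
}

#' The default 541-feature manifest
#'
#' Ordered catalogue of the per-cell morphological features computed by
#' [extract_features()]: shape (45), intensity (156), Haralick texture
#' (156), cross-channel correlation (36), granularity (64), radial
#' distribution (48), neighbors (12) and location (24) families, 541
#' features in total. The manifest is the single source of truth for
#' the feature set; a versioned CSV copy ships in
#' `inst/extdata/feature_manifest_v1.csv`.
#'
#' @param families optional subset of families to retain (order kept).
#' @return data.frame with columns `name`, `family`, `compartment`,
#'   `channel` (channel, `"a|b"` pair, or `""`).
#' @export
feature_manifest <- function(families = NULL) {
  rows <- list()
  add <- function(name, family, compartment, channel = "")
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, family = family, compartment = compartment,
      channel = channel, stringsAsFactors = FALSE)

  for (comp in .ms_compartments)
    for (s in .shape_stats)
      add(paste("shape", comp, s, sep = "_"), "shape", comp)
  for (comp in .ms_compartments)
    for (ch in .ms_channels)
      for (s in .intensity_stats)
        add(paste("intensity", comp, ch, s, sep = "_"), "intensity",
            comp, ch)
  for (comp in .ms_compartments)
    for (ch in .ms_channels)
      for (s in .haralick_stats)
        add(paste("texture", comp, ch, s, sep = "_"), "texture", comp, ch)
  for (comp in c("cell", "nucleus"))
    for (pr in .channel_pairs())
      for (m in .corr_metrics)
        add(paste("corr", comp, pr[1], pr[2], m, sep = "_"), "correlation",
            comp, paste(pr, collapse = "|"))
  for (ch in .ms_channels)
    for (r in 1:16)
      add(sprintf("gran_cell_%s_r%02d", ch, r), "granularity", "cell", ch)
  for (ch in .ms_channels)
    for (s in .radial_stats)
      for (b in 1:4)
        add(sprintf("radial_cell_%s_%s_bin%d", ch, s, b), "radial",
            "cell", ch)
  for (comp in c("cell", "nucleus"))
    for (s in .neighbor_stats)
      add(paste("neigh", comp, s, sep = "_"), "neighbors", comp)
  for (comp in .ms_compartments) {
    add(paste("loc", comp, "center_row", sep = "_"), "location", comp)
    add(paste("loc", comp, "center_col", sep = "_"), "location", comp)
  }
  for (comp in .ms_compartments)
    for (ch in c("ros", "mtros", "mmp")) {
      add(paste("loc", comp, ch, "cmass_row", sep = "_"), "location",
          comp, ch)
      add(paste("loc", comp, ch, "cmass_col", sep = "_"), "location",
          comp, ch)
    }

  man <- do.call(rbind, rows)
  if (anyDuplicated(man$name)) stop_ms("duplicate feature names in manifest")
  if (!is.null(families)) man <- man[man$family %in% families, ]
  rownames(man) <- NULL
  man
}

#' Validate a feature manifest
#'
#' @param manifest data.frame as returned by [feature_manifest()].
#' @return the manifest, invisibly; errors on malformed input.
#' @export
validate_manifest <- function(manifest) {
  need <- c("name", "family", "compartment", "channel")
  if (!all(need %in% names(manifest)))
    stop_ms("manifest must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(manifest$name)) stop_ms("duplicate feature names")
  known <- c("shape", "intensity", "texture", "correlation", "granularity",
             "radial", "neighbors", "location")
  bad <- setdiff(unique(manifest$family), known)
  if (length(bad)) stop_ms("unknown feature families: ",
                           paste(bad, collapse = ", "))
  invisible(manifest)
}
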