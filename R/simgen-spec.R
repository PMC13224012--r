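#' Treatment-group specification for the synthetic screen
#'
#' A `GroupSpec` describes one (cell line, compound, dose) condition of a
#' synthetic plate: the latent log-normal model of per-cell
#' (MMP, ROS, mtROS) triples and the plate geometry of the group.
#'
#' The latent model is a trivariate log-normal: per cell,
#' `log(M, R, S) ~ N(mu, D rho D)` with `D = diag(sigma)`. `M` drives the
#' MMP (TMRE-like) channel amplitude, `R` the whole-cell ROS (DCFH-DA-like)
#' channel and `S` the mitochondrial-ROS (MitoSOX-like) channel.
#'
#' @param cell_line,compound character labels.
#' @param dose dose in micromolar (metadata only).
#' @param mu length-3 numeric, latent log-means for (M, R, S).
#' @param rho 3x3 latent correlation matrix over (M, R, S); must be
#'   symmetric with unit diagonal and positive semi-definite.
#' @param sigma length-3 positive numeric, latent log-SDs.
#' @param cells_per_field cells placed per field.
#' @param fields_per_well imaged fields per well.
#' @param wells character vector of 96-well IDs (A1--H12).
#' @return an object of class `GroupSpec`.
#' @examples
#' gs <- group_spec("HPFC", "control", 0, mu = log(c(3000, 1500, 2000)),
#'                  rho = coupling_rho(0.35, 0.75, 0.40))
#' @export
group_spec <- function(cell_line, compound, dose = 0,
                       mu = log(c(3000, 1500, 2000)),
                       rho = diag(3),
                       sigma = c(0.3, 0.3, 0.3),
                       cells_per_field = 30L,
                       fields_per_well = 4L,
                       wells = character(0)) {
  stopifnot(length(mu) == 3L, length(sigma) == 3L)
  if (any(sigma <= 0)) stop_ms("sigma must be strictly positive")
  if (cells_per_field < 0 || fields_per_well < 0)
    stop_ms("counts must be non-negative")
  check_corr_matrix(rho)
  dimnames(rho) <- list(c("M", "R", "S"), c("M", "R", "S"))
  bad <- wells[!grepl("^[A-H](1[0-2]|[1-9])$", wells)]
  if (length(bad)) stop_ms("invalid 96-well IDs: ", paste(bad, collapse = ", "))
  structure(list(cell_line = cell_line, compound = compound, dose = dose,
                 mu = setNames(as.numeric(mu), c("M", "R", "S")),
                 rho = rho,
                 sigma = setNames(as.numeric(sigma), c("M", "R", "S")),
                 cells_per_field = as.integer(cells_per_field),
                 fields_per_well = as.integer(fields_per_well),
                 wells = as.character(wells)),
            class = "GroupSpec")
}

#' Build a 3x3 (M, R, S) correlation matrix from its three couplings
#'
#' @param mr,ms,rs pairwise correlations for (M,R), (M,S) and (R,S).
#' @return 3x3 correlation matrix with dimnames M, R, S.
#' @export
coupling_rho <- function(mr, ms, rs) {
  rho <- matrix(c(1, mr, ms,
                  mr, 1, rs,
                  ms, rs, 1), 3, 3,
                dimnames = list(c("M", "R", "S"), c("M", "R", "S")))
  rho
}

#' Field rendering geometry
#'
#' Pixel-level parameters of a simulated microscope field. Radii are in
#' pixels; intensity parameters are detector counts. Noise is Poisson
#' shot noise (gain `poisson_gain` counts/photon) followed by additive
#' Gaussian read noise; either can be disabled by setting it to 0, in
#' which case the rendered image is the exact noise-free expectation.
#'
#' @param image_size square field size in pixels.
#' @param nucleus_radius,cell_radius length-2 ranges in px.
#' @param mito_count,mito_segment_length per-cell mitochondrial filament
#'   count and length ranges.
#' @param background_level constant background in counts.
#' @param poisson_gain counts per photon (0 disables shot noise).
#' @param read_noise_sd Gaussian read-noise SD in counts (0 disables).
#' @param bit_depth detector bit depth; images clipped to `2^bit_depth - 1`.
#' @param hoechst_level mean nuclear Hoechst amplitude in counts.
#' @param haze_fraction fraction of the mitochondrial amplitude leaking
#'   into the cytoplasm for the mmp and mtros channels.
#' @return an object of class `FieldGeometry`.
#' @export
field_geometry <- function(image_size = 512L,
                           nucleus_radius = c(8, 12),
                           cell_radius = c(16, 24),
                           mito_count = c(6, 12),
                           mito_segment_length = c(8, 20),
                           background_level = 100,
                           poisson_gain = 1,
                           read_noise_sd = 2,
                           bit_depth = 16L,
                           hoechst_level = 5000,
                           haze_fraction = 0.08) {
  stopifnot(length(nucleus_radius) == 2L, length(cell_radius) == 2L)
  if (min(nucleus_radius) < 2 || min(cell_radius) < 2)
    stop_ms("radii must be at least 2 px")
  if (min(cell_radius) <= max(nucleus_radius))
    stop_ms("cell radius range must exceed nucleus radius range")
  if (background_level < 0 || poisson_gain < 0 || read_noise_sd < 0)
    stop_ms("noise parameters must be non-negative")
  structure(list(image_size = as.integer(image_size),
                 nucleus_radius = as.numeric(nucleus_radius),
                 cell_radius = as.numeric(cell_radius),
                 mito_count = as.integer(mito_count),
                 mito_segment_length = as.numeric(mito_segment_length),
                 background_level = background_level,
                 poisson_gain = poisson_gain,
                 read_noise_sd = read_noise_sd,
                 bit_depth = as.integer(bit_depth),
                 hoechst_level = hoechst_level,
                 haze_fraction = haze_fraction),
            class = "FieldGeometry")
}

#' Plate layout: a set of group specs with disjoint well assignments
#'
#' @param groups list of [group_spec()] objects, each with a non-empty
#'   `wells` assignment.
#' @param plate_id plate identifier.
#' @return an object of class `PlateLayout`.
#' @export
plate_layout <- function(groups, plate_id = "plate1") {
  stopifnot(is.list(groups), length(groups) > 0)
  lapply(groups, function(g) {
    if (!inherits(g, "GroupSpec")) stop_ms("groups must be GroupSpec objects")
    if (length(g$wells) == 0) stop_ms("every group needs at least one well")
  })
  wells <- unlist(lapply(groups, `[[`, "wells"))
  dup <- wells[duplicated(wells)]
  if (length(dup))
    stop_ms("wells assigned to more than one group: ",
            paste(unique(dup), collapse = ", "))
  names(groups) <- vapply(groups, function(g)
    paste(g$cell_line, g$compound, g$dose, sep = "_"), "")
  structure(list(plate_id = plate_id, groups = groups),
            class = "PlateLayout")
}

## default latent parameters: the qualitative coupling structure of the
## study (MMP-mtROS coupling stronger than MMP-ROS; stronger in normal
## fibroblasts than in tumor cells; cisplatin depolarizes and floods ROS
## while halving coupling; G4 ligands depolarize tumor cells with mildly
## reduced ROS and spare normal cells; the inert control compound does
## nothing). Numeric values are package defaults, tunable per group.
.default_group_params <- function() {
  list(
    HeLa = list(rho = coupling_rho(0.30, 0.60, 0.40)),
    HPFC = list(rho = coupling_rho(0.35, 0.75, 0.40))
  )
}

.compound_effects <- function() {
  list(
    control  = list(mult = c(1, 1, 1),          rho_scale = 1, dose = 0,
                    lines = c("HeLa", "HPFC")),
    EDL21    = list(mult = c(1, 1, 1),          rho_scale = 1, dose = 10,
                    lines = c("HeLa", "HPFC")),
    `Pt-ttpy` = list(mult = c(0.5, 0.85, 0.85), rho_scale = 1, dose = 10,
                    lines = "HeLa"),
    `360A`   = list(mult = c(0.5, 0.85, 0.85),  rho_scale = 1, dose = 10,
                    lines = "HeLa"),
    `Phen-DC3` = list(mult = c(0.5, 0.85, 0.85), rho_scale = 1, dose = 10,
                    lines = "HeLa"),
    cisplatin = list(mult = c(0.4, 2, 2),       rho_scale = 0.5, dose = 10,
                    lines = c("HeLa", "HPFC"))
  )
}

#' Default synthetic screen layout
#'
#' Two cell lines (HeLa tumor line, HPFC normal fibroblasts) times six
#' treatment groups (control, EDL21, Pt-ttpy, 360A, Phen-DC3, cisplatin),
#' each with `wells_per_group` wells of `fields_per_well` fields and
#' `cells_per_field` cells, so that every group contributes at least 200
#' cells at the defaults (2 wells x 4 fields x 30 cells = 240).
#'
#' G4-ligand effects (MMP halved, (mt)ROS mildly suppressed) are applied
#' to the tumor line only; in the normal line those groups fall back to
#' control parameters, emulating cancer-selective mitochondrial toxicity.
#'
#' @param wells_per_group,fields_per_well,cells_per_field plate scale.
#' @param mu baseline latent log-means (M, R, S).
#' @param sigma latent log-SDs.
#' @return a [plate_layout()] with 12 groups over wells A1--B12.
#' @export
default_screen_layout <- function(wells_per_group = 2L,
                                  fields_per_well = 4L,
                                  cells_per_field = 30L,
                                  mu = log(c(3000, 1500, 2000)),
                                  sigma = c(0.3, 0.3, 0.3)) {
  lines <- .default_group_params()
  effects <- .compound_effects()
  all_wells <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))
  groups <- list()
  w <- 0L
  for (line in names(lines)) {
    for (cmp in names(effects)) {
      eff <- effects[[cmp]]
      active <- line %in% eff$lines
      mult <- if (active) eff$mult else c(1, 1, 1)
      rs <- if (active) eff$rho_scale else 1
      rho <- lines[[line]]$rho
      rho[upper.tri(rho) | lower.tri(rho)] <-
        rho[upper.tri(rho) | lower.tri(rho)] * rs
      wells <- all_wells[w + seq_len(wells_per_group)]
      w <- w + wells_per_group
      groups[[paste(line, cmp, sep = "_")]] <-
        group_spec(line, cmp, dose = eff$dose,
                   mu = mu + log(mult), rho = rho, sigma = sigma,
                   cells_per_field = cells_per_field,
                   fields_per_well = fields_per_well,
                   wells = wells)
    }
  }
  plate_layout(groups, plate_id = "default_screen")
}

#' @export
print.GroupSpec <- function(x, ...) {
  cat("GroupSpec:", x$cell_line, x$compound, paste0(x$dose, "uM"), "\n")
  cat("  mu:", paste(format(x$mu, digits = 4), collapse = " "),
      " sigma:", paste(format(x$sigma, digits = 3), collapse = " "), "\n")
  cat("  rho(M,R) =", format(x$rho["M", "R"], digits = 3),
      " rho(M,S) =", format(x$rho["M", "S"], digits = 3),
      " rho(R,S) =", format(x$rho["R", "S"], digits = 3), "\n")
  cat("  wells:", paste(x$wells, collapse = ", "),
      sprintf(" (%d fields x %d cells)\n",
              x$fields_per_well, x$cells_per_field))
  invisible(x)
}

#' @export
print.PlateLayout <- function(x, ...) {
  cat("PlateLayout", x$plate_id, "with", length(x$groups), "groups\n")
  for (g in x$groups)
    cat(sprintf("  %-6s %-10s %4.1f uM  wells %s\n", g$cell_line,
                g$compound, g$dose, paste(g$wells, collapse = ",")))
  invisible(x)
}
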