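test_that("Haralick features are exact on degenerate and closed-form cases", {
  ## constant region: contrast 0, homogeneity 1, correlation 0 by convention
  img <- matrix(5, 10, 10)
  mask <- matrix(TRUE, 10, 10)
  h <- glcm_texture(img, mask)
  expect_identical(h[["contrast"]], 0)
  expect_identical(h[["idm"]], 1)
  expect_identical(h[["correlation"]], 0)
  ## empty mask: all missing
  expect_true(all(is.na(glcm_texture(img, matrix(FALSE, 10, 10)))))
  ## perfect checkerboard, axial offsets, 2 levels: ASM = 0.5
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  h2 <- glcm_texture(cb, matrix(TRUE, 8, 8), levels = 2L, distance = 1L,
                     angles = c("0", "90"))
  expect_equal(h2[["asm"]], 0.5, tolerance = 1e-12)
})

test_that("Haralick features equal the brute-force co-occurrence oracle", {
  set.seed(7)
  for (rep in 1:10) {
    img <- matrix(runif(256, 0, 1000), 16, 16)
    mask <- matrix(runif(256) < 0.8, 16, 16)
    if (sum(mask) < 4) next
    got <- glcm_texture(img, mask, levels = 8L, distance = 1L)
    P <- oracle_glcm(img, mask, levels = 8L, distance = 1L)
    want <- oracle_haralick(P)
    expect_equal(unname(got), unname(want), tolerance = 1e-10)
  }
})

test_that("Haralick features are invariant to affine intensity rescaling", {
  set.seed(11)
  img <- matrix(runif(400, 0, 500), 20, 20)
  mask <- matrix(TRUE, 20, 20)
  a <- glcm_texture(img, mask)
  b <- glcm_texture(3.7 * img + 250, mask)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("shape descriptors match analytic fixtures", {
  ## digital disc of radius 10
  disc <- draw_disc(32, 16, 16, 10) > 0
  s <- shape_descriptors(disc)
  expect_equal(s[["area"]], 100 * pi, tolerance = 0.02)
  expect_gte(s[["form_factor"]], 0.85)
  expect_lte(s[["form_factor"]], 1.05)
  expect_lt(s[["eccentricity"]], 0.2)
  expect_equal(s[["solidity"]], 1, tolerance = 0.01)
  ## 10 x 20 filled rectangle
  rect <- matrix(FALSE, 32, 32); rect[6:15, 6:25] <- TRUE
  sr <- shape_descriptors(rect)
  expect_identical(sr[["area"]], 200)
  expect_identical(sr[["extent"]], 1)
  expect_equal(sr[["aspect_ratio"]], 2, tolerance = 0.05)
  expect_identical(sr[["bbox_rows"]], 10)
  expect_identical(sr[["bbox_cols"]], 20)
  ## single pixel
  px <- matrix(FALSE, 5, 5); px[3, 3] <- TRUE
  sp <- shape_descriptors(px)
  expect_identical(sp[["area"]], 1)
  expect_identical(sp[["euler"]], 1)
  ## a ring has Euler number 0
  ring <- draw_disc(32, 16, 16, 10) > 0 & !(draw_disc(32, 16, 16, 5) > 0)
  expect_identical(shape_descriptors(ring)[["euler"]], 0)
  ## empty mask: missing
  expect_true(all(is.na(shape_descriptors(matrix(FALSE, 4, 4)))))
})

test_that("intensity descriptors match sort-based statistics", {
  img <- matrix(0, 5, 5)
  vals <- c(3, 1, 4, 1, 5, 9, 2, 6, 5)
  img[1:3, 1:3] <- matrix(vals, 3, 3)
  mask <- matrix(FALSE, 5, 5); mask[1:3, 1:3] <- TRUE
  d <- intensity_descriptors(img, mask)
  sv <- sort(vals)
  expect_identical(d[["min"]], 1)
  expect_identical(d[["max"]], 9)
  expect_identical(d[["median"]], sv[5])
  expect_identical(d[["integrated"]], sum(vals))
  ## type-7 quantile: q25 of 9 values is the 3rd order statistic
  expect_identical(d[["q25"]], sv[3])
  expect_identical(d[["q75"]], sv[7])
  expect_equal(d[["q05"]], sv[1] + 0.4 * (sv[2] - sv[1]), tolerance = 1e-12)
  ## uniform region
  u <- intensity_descriptors(matrix(4, 5, 5), matrix(TRUE, 5, 5))
  expect_identical(u[["mean"]], 4)
  expect_identical(u[["sd"]], 0)
  expect_identical(u[["mass_displacement"]], 0)
  expect_true(all(is.na(intensity_descriptors(img, matrix(FALSE, 5, 5)))))
})

test_that("intensity features are linear under global intensity rescale", {
  set.seed(3)
  img <- matrix(runif(100, 10, 100), 10, 10)
  mask <- matrix(runif(100) < 0.7, 10, 10)
  a <- intensity_descriptors(img, mask)
  b <- intensity_descriptors(5 * img, mask)
  linear <- c("mean", "median", "sd", "mad", "min", "max", "integrated",
              "q05", "q25", "q75", "q95", "edge_mean")
  expect_equal(unname(b[linear]), unname(5 * a[linear]), tolerance = 1e-12)
  expect_equal(b[["mass_displacement"]], a[["mass_displacement"]],
               tolerance = 1e-12)
})

test_that("cross-channel metrics match the textbook formulas", {
  mask <- matrix(TRUE, 5, 5)
  set.seed(5)
  a <- matrix(runif(25, 1, 10), 5, 5)
  expect_equal(cross_channel_corr(a, 2 * a, mask)[["pcc"]], 1,
               tolerance = 1e-12)
  expect_equal(cross_channel_corr(a, -a + 20, mask)[["pcc"]], -1,
               tolerance = 1e-12)
  b <- matrix(runif(25, 1, 10), 5, 5)
  got <- cross_channel_corr(a, b, mask)
  va <- as.vector(a); vb <- as.vector(b)
  pcc <- sum((va - mean(va)) * (vb - mean(vb))) /
    sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
  expect_equal(got[["pcc"]], pcc, tolerance = 1e-12)
  expect_equal(got[["overlap"]], sum(va * vb) / sqrt(sum(va^2) * sum(vb^2)),
               tolerance = 1e-12)
  expect_equal(got[["manders"]], sum(va[vb > 0]) / sum(va),
               tolerance = 1e-12)
  ## zero variance: pcc missing
  expect_true(is.na(cross_channel_corr(matrix(1, 5, 5), b, mask)[["pcc"]]))
})

test_that("granularity spectrum is normalized and exhausts on large radii", {
  img <- draw_disc(40, 20, 20, 5, 800)
  mask <- matrix(TRUE, 40, 40)
  g <- granularity_spectrum(img, mask)
  expect_true(all(g >= 0))
  ## disc of radius 5 vanishes under openings of radius >= 5
  expect_equal(sum(g), 1, tolerance = 1e-9)
  expect_true(all(g[8:16] == 0))
  expect_true(all(is.na(granularity_spectrum(img, matrix(FALSE, 40, 40)))))
})

test_that("radial distribution localizes concentrated intensity", {
  mask <- draw_disc(41, 21, 21, 15) > 0
  img <- draw_disc(41, 21, 21, 3, 100) # all intensity in the innermost bin
  r <- radial_distribution(img, mask, center = c(21, 21))
  expect_equal(unname(r[sprintf("fracatd_bin%d", 1:4)]), c(1, 0, 0, 0),
               tolerance = 1e-12)
  ## fractions always sum to 1 for positive masked signal
  set.seed(9)
  img2 <- matrix(runif(41 * 41), 41, 41)
  r2 <- radial_distribution(img2, mask, center = c(21, 21))
  expect_equal(sum(r2[sprintf("fracatd_bin%d", 1:4)]), 1, tolerance = 1e-12)
})

test_that("neighbor features distinguish isolated and adjacent objects", {
  lab <- matrix(0L, 40, 40)
  lab[draw_disc(40, 20, 20, 6) > 0] <- 1L
  nf <- neighbor_features(lab)
  expect_identical(nf$n_adjacent, 0)
  expect_identical(nf$percent_touching, 0)
  expect_identical(nf$n_within, 0)
  ## two touching squares
  lab2 <- matrix(0L, 20, 20)
  lab2[5:10, 5:10] <- 1L; lab2[5:10, 11:16] <- 2L
  nf2 <- neighbor_features(lab2)
  expect_identical(nf2$n_adjacent, c(1, 1))
  expect_true(all(nf2$percent_touching > 0))
  expect_equal(nf2$first_closest, c(6, 6), tolerance = 1e-12)
})

test_that("the feature table matches the manifest exactly, in order", {
  man <- feature_manifest()
  expect_identical(nrow(man), 541L)
  expect_identical(as.integer(table(man$family)[c("shape", "intensity",
                                                  "texture", "correlation",
                                                  "granularity", "radial",
                                                  "neighbors", "location")]),
                   c(45L, 156L, 156L, 36L, 64L, 48L, 12L, 24L))
  ## shipped CSV is in sync with the code
  csv <- read.csv(system.file("extdata", "feature_manifest_v1.csv",
                              package = "mitoscreen"))
  expect_identical(csv$name, man$name)

  geom <- fixture_geom_small()
  gs <- fixture_group(cells_per_field = 4L)
  fld <- render_field(sample_latents(gs, 4, seed = 19), geom, seed = 19)
  seg <- segment_field(fld$stack)
  ft <- extract_features(fld$stack, seg)
  expect_identical(setdiff(names(ft), "cell_id"), man$name)
  expect_identical(nrow(ft), 4L)
  ## catalogue closure on a family subset (order preserved)
  sub <- feature_manifest(families = "shape")
  expect_identical(nrow(sub), 45L)
  fts <- extract_features(fld$stack, seg, sub)
  expect_identical(setdiff(names(fts), "cell_id"), sub$name)
  ## empty field yields an empty table with full header
  empty <- list(cells = matrix(0L, 64, 64), nuclei = matrix(0L, 64, 64),
                mito = matrix(0L, 64, 64))
  uni <- lapply(1:4, function(i) matrix(100, 64, 64))
  names(uni) <- c("hoechst", "ros", "mtros", "mmp")
  ft0 <- extract_features(channel_stack(uni), empty, man)
  expect_identical(nrow(ft0), 0L)
  expect_identical(setdiff(names(ft0), "cell_id"), man$name)
  ## unknown family rejected
  bad <- man[1:3, ]; bad$family <- "sparkles"
  expect_error(extract_features(fld$stack, seg, bad), "unknown")
})

test_that("image profiles are missing-aware feature means over cells", {
  ft <- data.frame(well = "A1", field = c(1L, 1L, 1L, 2L),
                   cell_id = c(1L, 2L, 3L, 1L),
                   f1 = c(1, 3, NA, 10), f2 = c(2, 2, 2, 4))
  pr <- aggregate_image_profiles(ft)
  expect_identical(nrow(pr), 2L)
  expect_identical(pr$f1[pr$field == 1], 2)      # mean of 1, 3; NA ignored
  expect_identical(pr$n_cells[pr$field == 1], 3L)
  ## random table vs direct group means
  set.seed(13)
  big <- data.frame(well = rep(c("A1", "B2"), each = 20),
                    field = rep(rep(1:2, each = 10), 2),
                    cell_id = rep(1:10, 4),
                    v = rnorm(40))
  pr2 <- aggregate_image_profiles(big)
  want <- aggregate(v ~ well + field, big, mean)
  got <- merge(pr2, want, by = c("well", "field"))
  expect_equal(got$v.x, got$v.y, tolerance = 1e-12)
})
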