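test_that("latent sampling realizes the requested correlation structure", {
  ## independence case: all pairwise log-scale correlations near 0
  gs0 <- group_spec("HeLa", "control", 0, rho = diag(3))
  lat <- sample_latents(gs0, 10000, seed = 11)
  lc <- cor(log(as.matrix(lat[, c("M", "R", "S")])))
  expect_lt(max(abs(lc[upper.tri(lc)])), 0.03)
  expect_true(all(as.matrix(lat[, c("M", "R", "S")]) > 0))

  ## coupled case vs an independent Cholesky-construction oracle
  rho <- coupling_rho(0.0, 0.75, 0.0)
  gs <- group_spec("HPFC", "control", 0, rho = rho)
  lat <- sample_latents(gs, 10000, seed = 12)
  expect_equal(cor(log(lat$M), log(lat$S)), 0.75, tolerance = 0.02 / 0.75)
  set.seed(12)
  z <- matrix(rnorm(2 * 10000), ncol = 2) %*% chol(matrix(c(1, .75, .75, 1), 2))
  expect_equal(cor(z[, 1], z[, 2]), 0.75, tolerance = 0.03 / 0.75)
})

test_that("latent sampling handles edge cases and is deterministic", {
  gs <- fixture_group()
  expect_identical(nrow(sample_latents(gs, 0)), 0L)
  expect_identical(sample_latents(gs, 50, seed = 3),
                   sample_latents(gs, 50, seed = 3))
  bad <- gs
  bad$rho <- matrix(c(1, .99, -.99, .99, 1, .99, -.99, .99, 1), 3)
  expect_error(sample_latents(bad, 5), "positive semi-definite")
})

test_that("group and layout validation rejects malformed specifications", {
  expect_error(group_spec("x", "y", sigma = c(0, 1, 1)), "positive")
  expect_error(group_spec("x", "y", wells = "Z9"), "invalid 96-well")
  g1 <- fixture_group(wells = c("A1", "A2"))
  g2 <- fixture_group(wells = c("A2", "A3"))
  expect_error(plate_layout(list(g1, g2)), "more than one group")
  expect_error(field_geometry(cell_radius = c(5, 8)), "exceed")
})

test_that("an empty field renders to background plus noise only", {
  geom <- fixture_geom_small()
  fld <- render_field(sample_latents(fixture_group(), 0), geom, seed = 1)
  expect_identical(nrow(fld$truth$cells), 0L)
  expect_identical(max(fld$truth$cell_mask), 0L)
  ## all pixels near the background level (Poisson + read noise)
  expect_lt(abs(mean(fld$stack$channels$mmp) - geom$background_level), 1)
  ## noiseless empty field is exactly the background
  geom0 <- fixture_geom_small(poisson_gain = 0, read_noise_sd = 0)
  fld0 <- render_field(sample_latents(fixture_group(), 0), geom0, seed = 1)
  expect_true(all(fld0$stack$channels$ros == geom0$background_level))
})

test_that("noise-free signal is exactly linear in the latent amplitude", {
  geom <- fixture_geom_small(poisson_gain = 0, read_noise_sd = 0,
                             background_level = 0)
  gs <- fixture_group(cells_per_field = 1L)
  lat <- sample_latents(gs, 1, seed = 5)
  lat2 <- lat
  lat2$M <- 2 * lat$M
  f1 <- render_field(lat, geom, seed = 5)
  f2 <- render_field(lat2, geom, seed = 5)
  mask <- f1$truth$mito_mask == 1
  expect_identical(f1$truth$mito_mask, f2$truth$mito_mask)
  ## integrated mmp signal over the true mito pixels doubles exactly
  expect_identical(2 * sum(f1$stack$channels$mmp[mask]),
                   sum(f2$stack$channels$mmp[mask]))
})

test_that("noise-free channel sums satisfy the conservation identity", {
  geom <- fixture_geom_small(poisson_gain = 0, read_noise_sd = 0)
  lat <- sample_latents(fixture_group(), 5, seed = 9)
  fld <- render_field(lat, geom, seed = 9)
  tr <- fld$truth
  npx <- geom$image_size^2
  cell_areas <- tabulate(tr$cell_mask[tr$cell_mask > 0], nbins = 5)
  mito_areas <- tabulate(tr$mito_mask[tr$mito_mask > 0], nbins = 5)
  expect_equal(sum(fld$stack$channels$ros),
               geom$background_level * npx + sum(lat$R * cell_areas),
               tolerance = 1e-12)
  expect_equal(sum(fld$stack$channels$mmp),
               geom$background_level * npx +
                 sum(geom$haze_fraction * lat$M * cell_areas) +
                 sum(lat$M * mito_areas),
               tolerance = 1e-12)
})

test_that("rendering is bit-identical under a fixed seed and masks nest", {
  geom <- fixture_geom_small()
  lat <- sample_latents(fixture_group(), 8, seed = 21)
  a <- render_field(lat, geom, seed = 21)
  b <- render_field(lat, geom, seed = 21)
  expect_identical(a, b)
  ## containment: nucleus and mito pixels lie inside their own cell
  nuc <- a$truth$nucleus_mask; cell <- a$truth$cell_mask
  mito <- a$truth$mito_mask
  expect_true(all(cell[nuc > 0] == nuc[nuc > 0]))
  expect_true(all(cell[mito > 0] == mito[mito > 0]))
})

test_that("overcrowded fields fail with a placement report", {
  geom <- field_geometry(image_size = 64L)
  lat <- sample_latents(fixture_group(), 60, seed = 2)
  expect_error(render_field(lat, geom, seed = 2), "placed")
})

test_that("plate generation writes one TIFF per field plus a manifest", {
  out <- withr::local_tempdir()
  g1 <- fixture_group(cells_per_field = 3L, wells = c("A1", "A2"),
                      fields_per_well = 4L)
  g2 <- group_spec("HeLa", "cisplatin", 10, cells_per_field = 3L,
                   fields_per_well = 4L, wells = c("B1", "B2"))
  lay <- plate_layout(list(g1, g2))
  geom <- fixture_geom_small()
  man <- generate_plate(lay, geom, seed = 4, out_dir = out)
  expect_identical(nrow(man), 16L)
  expect_true(all(file.exists(man$path)))
  js <- jsonlite::read_json(file.path(out, "manifest.json"),
                            simplifyVector = TRUE)
  expect_identical(nrow(js$fields), 16L)
  ## same seed reproduces the identical manifest
  out2 <- withr::local_tempdir()
  man2 <- generate_plate(lay, geom, seed = 4, out_dir = out2)
  expect_identical(man[setdiff(names(man), "path")],
                   man2[setdiff(names(man2), "path")])
  ## TIFF round trip preserves pixel data and channel roles
  st <- read_field_tiff(man$path[1])
  fld <- render_plate_field(lay, man[1, ], geom)
  expect_equal(st$channels, fld$stack$channels)
})
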