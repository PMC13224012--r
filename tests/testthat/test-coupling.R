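test_that("Pearson correlation follows the product-moment formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$r, -1, tolerance = 1e-12)
  y <- c(2.5, 1.0, 4.2, 3.3, 0.7)
  got <- pearson_r(x, y)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, hand, tolerance = 1e-12)
  expect_identical(got$n, 5L)
  ## missing pairs dropped from n
  expect_identical(pearson_r(c(x, NA), c(y, 1))$n, 5L)
  ## degenerate cases
  expect_error(pearson_r(1:2, 2:3), "3 complete pairs")
  r0 <- pearson_r(rep(1, 5), y)
  expect_true(is.na(r0$r))
  expect_identical(attr(r0$r, "reason"), "zero variance")
})

test_that("the Fisher transform is the closed-form odd map", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6 / 0.55)
  r <- seq(-0.9, 0.9, by = 0.3)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-12)
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_error(fisher_z(1), "\\|r\\| < 1")
})

test_that("independent-correlation comparison matches the normal theory", {
  ## equal correlations: Z = 0, one-sided p = 0.5
  eq <- compare_independent_correlations(0.4, 100, 0.4, 100)
  expect_identical(eq$Z, 0)
  expect_identical(eq$p_one_sided, 0.5)
  ## direct evaluation of the statistic
  got <- compare_independent_correlations(0.75, 500, 0.60, 500)
  want <- (atanh(0.75) - atanh(0.60)) / sqrt(1 / 497 + 1 / 497)
  expect_equal(got$Z, want, tolerance = 1e-12)
  expect_equal(got$p_one_sided, pnorm(-abs(want)), tolerance = 1e-12)
  ## antisymmetry under swapping sides
  sw <- compare_independent_correlations(0.60, 500, 0.75, 500)
  expect_identical(sw$Z, -got$Z)
  expect_identical(sw$p_two_sided, got$p_two_sided)
  expect_error(compare_independent_correlations(0.5, 3, 0.5, 10), ">= 4")
})

test_that("a one-sided tail for z = -2.131 prints as p = 0.017", {
  expect_identical(round(pnorm(-abs(-2.131)), 3), 0.017)
  got <- compare_independent_correlations(0.3, 500, 0.39, 500)
  ## sanity: the comparison's reported p is the same tail function
  expect_equal(got$p_one_sided, pnorm(-abs(got$Z)), tolerance = 1e-15)
})

test_that("Fisher confidence intervals contain r and shrink with n", {
  ci1 <- fisher_ci(0.6, 50)
  ci2 <- fisher_ci(0.6, 5000)
  expect_true(ci1[1] < 0.6 && 0.6 < ci1[2])
  expect_lt(diff(ci2), diff(ci1))
})

## build a single-cell-like table straight from latents (no imaging)
latents_as_cells <- function(spec, n_fields, cells_per_field, seed) {
  seeds <- child_seeds(seed, n_fields)
  do.call(rbind, lapply(seq_len(n_fields), function(f) {
    lat <- sample_latents(spec, cells_per_field, seed = seeds[f])
    data.frame(cell_line = spec$cell_line, compound = spec$compound,
               dose = spec$dose, well = "A1", field = f,
               cell_id = lat$cell_id,
               mmp_mito_corrected = lat$M, ros_corrected = lat$R,
               mtros_mito_corrected = lat$S)
  }))
}

test_that("coupling profiles recover the generating correlation ordering", {
  hpfc <- group_spec("HPFC", "control", 0,
                     rho = coupling_rho(0.35, 0.75, 0.40))
  hela <- group_spec("HeLa", "control", 0,
                     rho = coupling_rho(0.30, 0.60, 0.40))
  cells <- rbind(latents_as_cells(hpfc, 8, 60, 41),
                 latents_as_cells(hela, 8, 60, 42))
  cp <- coupling_profile(cells)
  res <- cp$results
  for (cl in c("HPFC", "HeLa")) {
    r_ms <- res$r[res$cell_line == cl & res$pair == "MMP-mtROS"]
    r_mr <- res$r[res$cell_line == cl & res$pair == "MMP-ROS"]
    expect_gt(r_ms, r_mr)
  }
  ## per-image scope: 8 images yield 8 r values per pair per group
  expect_true(all(res$n_images == 8L))
  expect_identical(lengths(cp$per_image),
                   setNames(rep(8L, 4), names(cp$per_image)))
  ## violin summaries are consistent with the stored per-image values
  k <- names(cp$per_image)[1]
  expect_equal(res$img_r_median[1], median(cp$per_image[[k]]),
               tolerance = 1e-12)
  ## the three contrast types are emitted
  expect_setequal(unique(cp$comparisons$contrast),
                  c("within_group_pair", "across_cell_lines"))
})

test_that("identically generated groups rarely differ significantly", {
  spec1 <- group_spec("HeLa", "control", 0,
                      rho = coupling_rho(0.35, 0.5, 0.35))
  spec2 <- group_spec("HeLa", "EDL21", 10,
                      rho = coupling_rho(0.35, 0.5, 0.35))
  seeds <- child_seeds(77, 40)
  p2 <- vapply(seq_len(20), function(i) {
    a <- sample_latents(spec1, 500, seed = seeds[2 * i - 1])
    b <- sample_latents(spec2, 500, seed = seeds[2 * i])
    r1 <- pearson_r(log(a$M), log(a$S))
    r2 <- pearson_r(log(b$M), log(b$S))
    compare_independent_correlations(r1$r, r1$n, r2$r, r2$n)$p_two_sided
  }, 0)
  expect_gte(mean(p2 > 0.01), 0.95)
})

test_that("underpowered groups are skipped with a message", {
  spec <- fixture_group()
  cells <- latents_as_cells(spec, 1, 3, 5)
  expect_message(cp <- coupling_profile(cells), "skipping")
  expect_null(cp$results)
})
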