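# synthetic-image generator: geometry, ground truth, determinism

test_that("dense annulus ground truth equals brute-force pixel counting", {
  res <- synthesize_cell(cell_spec(cell_radius = 100, nucleus_radius = 30,
                                   dense_band_fraction = 0.5, seed = 1),
                         noise = noise_params(enabled = FALSE))
  # independent pixel-count oracle on the same lattice
  D <- 2L * 100L + 7L
  c0 <- (D + 1) / 2
  dx <- matrix(seq_len(D) - c0, D, D); dy <- t(dx)
  r2 <- dx^2 + dy^2
  cyto <- r2 <= 100^2 & r2 > 30^2
  dense <- r2 > 30^2 & r2 <= (30 + 0.5 * 70)^2 & r2 <= 100^2
  expect_identical(res$truth$true_dense_fraction_pct,
                   100 * sum(dense & cyto) / sum(cyto))
})

test_that("degenerate specs give empty readouts and invalid specs error", {
  no_mesh <- synthesize_cell(cell_spec(tubule_spacing = Inf, seed = 2),
                             noise = noise_params(enabled = FALSE))
  expect_length(no_mesh$truth$true_polygon_areas, 0)
  no_band <- synthesize_cell(cell_spec(dense_band_fraction = 0, seed = 2),
                             noise = noise_params(enabled = FALSE))
  expect_identical(no_band$truth$true_dense_fraction_pct, 0)
  expect_error(cell_spec(cell_radius = 20, nucleus_radius = 25), "nucleus")
  expect_error(cell_spec(tubule_spacing = 2, tubule_width = 3), "spacing")
  expect_error(cell_spec(dense_band_fraction = 1.2), "dense_band_fraction")
})

test_that("identical specs and seeds reproduce fields byte for byte", {
  specs <- random_cell_specs(5, dim = c(416L, 416L), seed = 42,
                             strict = FALSE)
  f1 <- synthesize_field(specs, dim = c(416L, 416L), field_seed = 9L)
  f2 <- synthesize_field(specs, dim = c(416L, 416L), field_seed = 9L)
  expect_identical(f1$image$channels, f2$image$channels)
  expect_identical(f1$truth, f2$truth)
})

test_that("border cells are flagged and centered cells are not", {
  sp_border <- cell_spec(center = c(10, 200), seed = 3)
  sp_center <- cell_spec(center = c(200, 200), seed = 4)
  fld <- synthesize_field(list(sp_border, sp_center), dim = c(400L, 400L))
  expect_true(fld$truth[[1]]$border)
  expect_false(fld$truth[[2]]$border)
})

test_that("a single centered cell matches the stand-alone render", {
  sp <- cell_spec(seed = 5)
  solo <- synthesize_cell(sp, noise = noise_params(enabled = FALSE))
  D <- dim(solo$image$channels$er)
  fld <- synthesize_field(list(cell_spec(center = (D + 1) / 2, seed = 5)),
                          dim = D, noise = noise_params(enabled = FALSE))
  expect_equal(fld$image$channels$er, solo$image$channels$er)
  expect_equal(fld$truth[[1]]$true_dense_fraction_pct,
               solo$truth$true_dense_fraction_pct)
  expect_equal(sort(fld$truth[[1]]$true_polygon_areas),
               sort(solo$truth$true_polygon_areas))
})

test_that("construction is monotone in spacing and dense-band fraction", {
  big <- function(s, f) synthesize_cell(
    cell_spec(cell_radius = 110, nucleus_radius = 26,
              dense_band_fraction = f, tubule_spacing = s,
              mesh = "hex", seed = 11),
    noise = noise_params(enabled = FALSE))$truth
  means <- vapply(c(8, 12, 16), function(s)
    mean(big(s, 0.1)$true_polygon_areas), numeric(1))
  expect_true(all(diff(means) > 0))
  dense <- vapply(c(0.1, 0.3, 0.5, 0.7), function(f)
    big(12, f)$true_dense_fraction_pct, numeric(1))
  expect_true(all(diff(dense) > 0))
})

test_that("polygon areas never exceed the available peripheral area", {
  for (seed in 1:4) {
    res <- synthesize_cell(cell_spec(seed = seed),
                           noise = noise_params(enabled = FALSE))
    tr <- res$truth
    cyto_outside_dense <- sum(tr$cell_mask & !tr$nucleus_mask &
                                !tr$dense_mask) * tr$pixel_size_um^2
    expect_lte(sum(tr$true_polygon_areas), cyto_outside_dense)
  }
})

test_that("impossible placements raise a placement error", {
  expect_error(random_cell_specs(12, dim = c(200L, 200L), seed = 1),
               "placement")
  expect_warning(random_cell_specs(12, dim = c(200L, 200L), seed = 1,
                                   strict = FALSE), "placed only")
})

test_that("overlapping explicit placements are rejected", {
  sp1 <- cell_spec(center = c(100, 100), seed = 1)
  sp2 <- cell_spec(center = c(120, 100), seed = 2)
  expect_error(synthesize_field(list(sp1, sp2), dim = c(300L, 300L)),
               "overlap")
})

test_that("plate simulation honours roles, effects and the NTC requirement", {
  design <- demo_screen_design()
  sub <- c("B2", "D6", "G10", "B11", "G2", "B3", "B4")
  plate <- synthesize_screen_plate(design$layout, effects = design$effects,
                                   n_fields = 1L, incenp_fields = 1L,
                                   cells_per_field = 2L, seed = 3,
                                   dim = c(320L, 320L), wells = sub)
  expect_setequal(unique(plate$manifest$well), sub)
  expect_true(all(c("NTC", "INCENP") %in% plate$truth$condition))
  # wells filter without any NTC well must fail
  expect_error(
    synthesize_screen_plate(design$layout, wells = c("B3", "B4"),
                            n_fields = 1L, cells_per_field = 2L),
    "NTC")
})
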