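# ER morphometrics: perinuclear band, dense fraction, polygons, circularity

test_that("perinuclear band covers nothing, everything or the exact annulus", {
  cell <- disk_mask(24)
  nuc <- disk_mask(8, pad = 20)
  cyto <- cell & !nuc
  expect_identical(sum(perinuclear_band(cell, nuc, 0)), 0L)
  expect_identical(perinuclear_band(cell, nuc, 1), cyto)
  # brute-force per-pixel evaluation with an independent distance search
  band <- perinuclear_band(cell, nuc, 0.5)
  d_nuc <- brute_distance(nuc)
  d_mem <- brute_distance(!cell)
  oracle <- cyto & (d_nuc / (d_nuc + d_mem)) <= 0.5
  expect_identical(band, oracle)
  expect_error(perinuclear_band(nuc, cell, 0.5), "geometry")
})

test_that("uniform cytoplasmic ER yields zero dense fraction", {
  cell <- disk_mask(30)
  nuc <- disk_mask(10, pad = 24)
  er <- matrix(0, nrow(cell), ncol(cell))
  er[cell] <- 50
  res <- dense_er_fraction(er, cell, nuc)
  expect_identical(res$dense_fraction_pct, 0)
  # MAD variant too
  res2 <- dense_er_fraction(er, cell, nuc,
                            morph_config(dense_thresh_method = "mad"))
  expect_identical(res2$dense_fraction_pct, 0)
})

test_that("dense fraction is recovered within 3 points at default noise", {
  errs <- vapply(1:10, function(seed) {
    res <- synthesize_cell(cell_spec(dense_band_fraction = 0.3,
                                     seed = seed))
    m <- measure_from_truth(res)
    m$dense_fraction_pct - res$truth$true_dense_fraction_pct
  }, numeric(1))
  expect_lt(mean(abs(errs)), 3)
})

test_that("dense readout is robust to the dense-ER brightness", {
  deltas <- vapply(1:6, function(seed) {
    lo <- synthesize_cell(cell_spec(dense_intensity_ratio = 3, seed = seed))
    hi <- synthesize_cell(cell_spec(dense_intensity_ratio = 6, seed = seed))
    measure_from_truth(hi)$dense_fraction_pct -
      measure_from_truth(lo)$dense_fraction_pct
  }, numeric(1))
  expect_lt(mean(abs(deltas)), 2)
})

test_that("cells without peripheral tubules yield no polygons", {
  res <- synthesize_cell(cell_spec(tubule_spacing = Inf, seed = 9),
                         noise = noise_params(enabled = FALSE))
  m <- measure_from_truth(res)
  expect_length(m$polygon_areas, 0)
  expect_true(is.na(m$mean_polygon_area))
})

test_that("hexagonal-lattice polygons match the pixel-count oracle", {
  res <- synthesize_cell(cell_spec(cell_radius = 110, nucleus_radius = 26,
                                   dense_band_fraction = 0.1,
                                   tubule_spacing = 12, mesh = "hex",
                                   seed = 10),
                         noise = noise_params(enabled = FALSE))
  m <- measure_from_truth(res)
  truth <- res$truth$true_polygon_areas
  expect_gt(length(m$polygon_areas), 5)
  expect_lt(abs(mean(m$polygon_areas) - mean(truth)) / mean(truth), 0.10)
})

test_that("recovered polygon area increases with tubule spacing", {
  mean_rec <- vapply(c(8, 12, 16, 24), function(s) {
    vals <- vapply(1:8, function(seed) {
      res <- synthesize_cell(cell_spec(cell_radius = 110,
                                       nucleus_radius = 26,
                                       dense_band_fraction = 0.1,
                                       tubule_spacing = s, seed = seed))
      measure_from_truth(res)$mean_polygon_area
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_rec) > 0))
})

test_that("circularity matches shape oracles", {
  expect_gte(circularity(disk_mask(30)), 0.95)
  expect_gte(circularity(disk_mask(45)), 0.95)
  for (a in c(50L, 64L, 80L)) {
    expect_lt(abs(circularity(square_mask(a)) - pi / 4) / (pi / 4), 0.05)
  }
  lobed <- synthesize_cell(cell_spec(n_lobes = 3L, seed = 12),
                           noise = noise_params(enabled = FALSE))
  round_ <- synthesize_cell(cell_spec(n_lobes = 1L, seed = 12),
                            noise = noise_params(enabled = FALSE))
  c_lobed <- circularity(lobed$truth$nucleus_mask)
  c_round <- circularity(round_$truth$nucleus_mask)
  expect_lt(c_lobed, 0.8)
  expect_lt(c_lobed, c_round)
  expect_error(circularity(matrix(FALSE, 5, 5)), "empty")
})

test_that("readouts are invariant to the ER intensity scale", {
  res <- synthesize_cell(cell_spec(seed = 13))
  m1 <- measure_from_truth(res)
  res$image$channels$er <- res$image$channels$er * 7.3
  m2 <- measure_from_truth(res)
  expect_equal(m1$dense_fraction_pct, m2$dense_fraction_pct)
  expect_equal(m1$polygon_areas, m2$polygon_areas)
})

test_that("measuring a field is deterministic and refuses border cells", {
  specs <- random_cell_specs(3, dim = c(416L, 416L), seed = 31,
                             strict = FALSE)
  fld <- synthesize_field(specs, dim = c(416L, 416L), field_seed = 32L,
                          keep_masks = TRUE)
  seg <- truth_segmentation(fld)
  m1 <- measure_field(seg)
  m2 <- measure_field(seg)
  expect_identical(m1, m2)
  if (length(seg$border_excluded)) {
    expect_error(measure_cell(seg, seg$border_excluded[1]), "border")
    expect_true(all(is.na(
      m1$mean_polygon_area_um2[m1$border_excluded])))
  }
  kept <- m1[!m1$border_excluded, ]
  expect_true(all(kept$dense_fraction_pct >= 0 &
                    kept$dense_fraction_pct <= 100))
})
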